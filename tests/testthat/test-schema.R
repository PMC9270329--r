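test_that("schema hierarchy matches the published Level 1 structure", {
  s <- build_schema()
  expect_identical(schema_roots(s), c("Data", "Entity", "Utility"))
  expect_setequal(direct_subclasses(s, "Phenotype"),
                  c("Cellular_Appearances", "Product_or_Reserve",
                    "Architectural_Pattern"))
  expect_setequal(main_object_properties(s, "PhysicalEntity"),
                  c("entityReference", "hasAttribute", "hasProduct",
                    "hasComponent"))
  expect_setequal(subproperties_of(s, "hasComponent"),
                  c("hasCell", "hasCellularComponent", "hasAnatomicalEntity"))
  # multi-parentage: a neoplastic cell is both a cell and part of the tumor
  expect_true("NeoplasticCell" %in% subclass_closure(s, "Cell"))
  expect_true("NeoplasticCell" %in% subclass_closure(s, "Tumor"))
  # cross-classification of PhysicalEntity
  expect_setequal(
    intersect(direct_subclasses(s, "PhysicalEntity"),
              c("NormalEntity", "Tumor")),
    c("NormalEntity", "Tumor"))
})

test_that("subclass closure equals breadth-first reachability on the axiom graph", {
  s <- build_schema()
  bfs <- function(cl) {
    seen <- cl
    queue <- cl
    while (length(queue)) {
      head <- queue[[1]]; queue <- queue[-1]
      kids <- s$subclass_of$child[s$subclass_of$parent == head]
      for (k in kids) {
        if (!k %in% seen) { seen <- c(seen, k); queue <- c(queue, k) }
      }
    }
    sort(seen)
  }
  for (cl in s$classes) {
    expect_identical(subclass_closure(s, cl), bfs(cl))
  }
  # a leaf has a singleton closure
  expect_identical(subclass_closure(s, "Nucleolus"), "Nucleolus")
  expect_error(subclass_closure(s, "NotAClass"), "not declared")
})

test_that("schema export/import round-trips in both dialects", {
  s <- build_schema()
  for (dialect in c("turtle", "rdfxml")) {
    path <- withr::local_tempfile(fileext = if (dialect == "turtle") ".ttl"
                                            else ".owl")
    export_schema(s, path, dialect)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    expect_match(txt, "NeoplasticCell")
    expect_true(schemas_equal(s, import_schema(path)))
  }
})

test_that("exported Turtle triple count matches an independent RDF parser", {
  s <- build_schema()
  path <- withr::local_tempfile(fileext = ".ttl")
  export_schema(s, path, "turtle")
  lines <- readLines(path)
  n_lines <- sum(grepl(" \\.$", lines) & !grepl("^@prefix", lines))
  count <- tempfile()
  script <- sprintf(
    'import rdflib; g = rdflib.Graph(); g.parse(%s, format="turtle"); open(%s, "w").write(str(len(g)) + "\\n")',
    deparse(path), deparse(count))
  expect_identical(system2("python", c("-c", shQuote(script))), 0L)
  expect_identical(as.integer(readLines(count)), n_lines)
})

test_that("the shipped canonical schema file equals build_schema()", {
  shipped <- system.file("extdata", "histoml-level1.ttl", package = "histoml")
  expect_true(nzchar(shipped))
  expect_true(schemas_equal(build_schema(), import_schema(shipped)))
})

test_that("schema validation rejects extra roots and subclass cycles", {
  s <- build_schema()
  expect_error(
    new_schema(s$namespace, c(s$classes, "Orphan"), s$subclass_of,
               s$object_properties, s$datatype_properties),
    "rooted at exactly")
  cyc <- rbind(s$subclass_of,
               data.frame(child = "Cell", parent = "NeoplasticCell"))
  expect_error(
    new_schema(s$namespace, s$classes, cyc, s$object_properties,
               s$datatype_properties),
    "cycle")
})
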