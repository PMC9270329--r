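test_that("SPARQL retrieves the individuals the fixtures created", {
  b <- make_rhabdoid_fixture(3, seed = 7)
  doc <- b$document
  res <- run_sparql(doc, paste0(
    "PREFIX histo: <", HISTOML_NS, ">\n",
    "SELECT ?cell WHERE { ?cell a histo:NeoplasticCell }"))
  expect_identical(res$cell, individual_iris(doc, "NeoplasticCell"))
  # joins across two patterns: cells and their segmentation ids
  res2 <- run_sparql(doc, paste0(
    "PREFIX histo: <", HISTOML_NS, ">\n",
    "SELECT ?cell ?sid WHERE { ?cell a histo:NeoplasticCell ; ",
    "histo:segmentation ?sid }"))
  expect_identical(nrow(res2), 3L)
  expect_setequal(res2$sid, paste0("seg:cell_", 1:3))
})

test_that("queries over documents without matches return zero rows", {
  doc <- new_document(slide_metadata(10, 10, 40))
  res <- run_sparql(doc, paste0(
    "PREFIX histo: <", HISTOML_NS, ">\n",
    "SELECT ?x WHERE { ?x a histo:Lymphocyte }"))
  expect_identical(nrow(res), 0L)
  expect_identical(names(res), "x")
})

test_that("malformed SPARQL raises a syntax error with a position", {
  doc <- new_document(slide_metadata(10, 10, 40))
  expect_error(run_sparql(doc, "SELECT WHERE { ?x }"),
               "syntax error at character")
  expect_error(run_sparql(doc, "SELECT ?x WHERE { ?x histo:name ?y }"),
               "undeclared prefix")
})

test_that("results agree with an independent SPARQL engine on exported Turtle", {
  b <- make_tils_fixture(3000, 0.3, 8, seed = 8)
  path <- tempfile(fileext = ".ttl")
  write_document(b$document, path, dialect = "turtle")
  queries <- c(
    paste0("PREFIX histo: <", HISTOML_NS, ">\n",
           "SELECT ?x WHERE { ?x a histo:Lymphocyte }"),
    paste0("PREFIX histo: <", HISTOML_NS, ">\n",
           "SELECT ?s ?c WHERE { ?s histo:hasCell ?c }"),
    paste0("PREFIX histo: <", HISTOML_NS, ">\n",
           "SELECT ?e ?sid WHERE { ?e histo:segmentation ?sid }"))
  for (q in queries) {
    mine <- as.data.frame(run_sparql(b$document, q))
    theirs <- rdflib_select(path, q)
    expect_identical(unname(as.list(mine)), unname(as.list(theirs)))
  }
})

test_that("phenotype decomposition equals the pure traversal oracle", {
  for (seed in 101:115) {
    doc <- random_document(seed)
    for (ph in individual_iris(doc, "Phenotype")) {
      expect_identical(components_of_phenotype(doc, ph),
                       oracle_components_of_phenotype(doc, ph))
      expect_identical(components_of_phenotype(doc, ph,
                                               include_contained = TRUE),
                       oracle_components_of_phenotype(doc, ph,
                                                      include_contained = TRUE))
    }
  }
  b <- make_alveolar_fixture(1, seed = 9)
  ph <- individual_iris(b$document, "Architectural_Pattern")[[1]]
  closure <- components_of_phenotype(b$document, ph,
                                     include_contained = TRUE)
  expect_true(any(grepl("Parenchyma", closure)))
  expect_true(any(grepl("Capillary", closure)))
  expect_error(components_of_phenotype(b$document,
                                       individual_iris(b$document, "Stroma")[[1]]),
               "not a Phenotype")
})

test_that("containment-scoped class retrieval honours the subclass closure", {
  b <- make_tils_fixture(3000, 0.25, 6, seed = 10)
  doc <- b$document
  stroma <- individual_iris(doc, "Stroma")[[1]]
  lymphs <- entities_within(doc, stroma, "Lymphocyte")
  expect_identical(lymphs, individual_iris(doc, "Lymphocyte"))
  expect_identical(entities_within(doc, stroma, "Erythrocyte"), character(0))
  # querying the parent cell class returns the lymphocytes too
  expect_true(all(lymphs %in% entities_within(doc, stroma, "Cell")))
  expect_error(entities_within(doc, stroma, "NotAClass"), "not declared")
  for (seed in 121:130) {
    rdoc <- random_document(seed)
    containers <- individual_iris(rdoc, "Tissue")
    for (ct in containers) {
      for (cl in c("Cell", "Lymphocyte", "PhysicalEntity")) {
        expect_identical(entities_within(rdoc, ct, cl),
                         oracle_entities_within(rdoc, ct, cl))
      }
    }
  }
})

test_that("segmentation lookups cover exactly the ids the generator emitted", {
  b <- make_rhabdoid_fixture(2, seed = 11)
  doc <- b$document
  cells <- individual_iris(doc, "NeoplasticCell")
  segs <- segmentations_of(doc, cells)
  expect_identical(segs[[cells[[1]]]], "seg:cell_1")
  # an entity without segmentation maps to an empty vector
  ph <- individual_iris(doc, "Cellular_Appearances")
  expect_identical(segmentations_of(doc, ph)[[ph[[1]]]], character(0))
  # union over all entities covers every id in the mask
  all_segs <- unlist(segmentations_of(doc, individual_iris(doc)))
  expect_setequal(unique(all_segs), names(b$mask$id_map))
  for (seed in 131:135) {
    rdoc <- random_document(seed)
    iris <- individual_iris(rdoc)
    expect_identical(segmentations_of(rdoc, iris),
                     oracle_segmentations(rdoc, iris))
  }
})
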