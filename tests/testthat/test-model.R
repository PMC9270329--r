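md <- function() slide_metadata(1000, 1200, 40)

test_that("documents start empty and reject invalid slide metadata", {
  doc <- new_document(md())
  # only the WholeSlideImage metadata individual is present
  expect_identical(n_individuals(doc), 1L)
  expect_identical(length(individual_iris(doc, "PhysicalEntity")), 0L)
  m <- document_metadata(doc)
  expect_identical(m$height, 1000L)
  expect_identical(m$magnification, 40)
  expect_error(slide_metadata(0, 100, 40), "height")
  expect_error(slide_metadata(100, 100, 40, microns_per_pixel = -1),
               "microns_per_pixel")
})

test_that("physical entities carry segmentations and shared entity references", {
  doc <- new_document(md())
  ref <- add_entity_reference(doc, "rhabdoid cell", xrefs = "NCIt:C36908")
  c1 <- add_physical_entity(doc, "NeoplasticCell", entity_reference = ref,
                            segmentation_ids = "seg:cell_1")
  c2 <- add_physical_entity(doc, "NeoplasticCell", entity_reference = ref,
                            segmentation_ids = "seg:cell_2")
  expect_identical(c1$values$segmentation, "seg:cell_1")
  # both concrete forms resolve to the same generic entity
  ref_targets <- vapply(list(c1, c2), function(x) {
    x$links$target[x$links$property == "entityReference"]
  }, character(1))
  expect_identical(ref_targets[[1]], ref_targets[[2]])
  expect_error(add_physical_entity(doc, "Cellular_Appearances"),
               "not a PhysicalEntity subclass")
  # deterministic IRI scheme
  expect_match(c1$iri, "/NeoplasticCell_1$")
  expect_match(c2$iri, "/NeoplasticCell_2$")
})

test_that("attributes hold opaque CURIEs and quantifications", {
  doc <- new_document(md())
  cell <- add_physical_entity(doc, "NeoplasticCell",
                              segmentation_ids = "seg:c")
  at <- attach_attribute(doc, cell, "large", xrefs = "PATO:0000587",
                         quantifications = list(
                           quantification("area", 812, "um^2")))
  qs <- at$links$target[at$links$property == "hasQuantification"]
  expect_length(qs, 1L)
  q <- get_individual(doc, qs)
  expect_identical(q$values$parameterName, "area")
  expect_identical(q$values$value, 812)
  # the CURIE is stored verbatim on the Xref individual
  x <- get_individual(doc, at$links$target[at$links$property == "hasXref"])
  expect_identical(x$values$xrefId, "PATO:0000587")
  expect_error(attach_attribute(doc, cell, "bad", xrefs = "not a curie"),
               "malformed CURIE")
  expect_error(quantification("area", Inf, "px"), "finite")
  # an empty attribute is a warning-level flag, not an error
  attach_attribute(doc, cell, "eosinophilic")
  rep <- validate_document(doc)
  expect_identical(sum(rep$severity == "error"), 0L)
  expect_identical(sum(rep$severity == "warning" &
                         rep$rule == "empty-attribute"), 1L)
})

test_that("containment stays acyclic and transitive closure matches reachability", {
  doc <- new_document(md())
  stroma <- add_physical_entity(doc, "Stroma", segmentation_ids = "seg:s")
  lymph <- add_physical_entity(doc, "Lymphocyte", segmentation_ids = "seg:l")
  nuc <- add_physical_entity(doc, "Nucleus", segmentation_ids = "seg:n")
  link_component(doc, stroma, lymph, "hasCell")
  link_component(doc, lymph, nuc, "hasCellularComponent")
  edges <- doc_edges(doc, c("hasComponent", "hasCell", "hasCellularComponent",
                            "hasAnatomicalEntity"))
  expect_identical(oracle_reachable(edges, stroma$iri),
                   sort(c(lymph$iri, nuc$iri)))
  expect_error(link_component(doc, nuc, stroma, "hasComponent"),
               "containment cycle")
  expect_error(link_component(doc, stroma, stroma, "hasComponent"),
               "containment cycle")
  # sub-property ranges are enforced
  tissue <- add_physical_entity(doc, "Parenchyma", segmentation_ids = "seg:p")
  expect_error(link_component(doc, stroma, tissue, "hasCell"),
               "requires a Cell")
})

test_that("products and reserves link cells to substances only", {
  doc <- new_document(md())
  cell <- add_physical_entity(doc, "NeoplasticCell")
  mucin <- add_physical_entity(doc, "Mucin", name = "mucin")
  add_product_or_reserve(doc, cell, mucin, "hasProduct")
  updated <- get_individual(doc, cell$iri)
  expect_identical(updated$links$target[updated$links$property == "hasProduct"],
                   mucin$iri)
  expect_error(add_product_or_reserve(doc, mucin, cell, "hasProduct"),
               "belong to Cell")
})

test_that("phenotypes require components and materialize relationships", {
  doc <- new_document(md())
  expect_error(add_phenotype(doc, "Architectural_Pattern",
                             components = list()),
               "at least one component")
  tumor <- add_physical_entity(doc, "Tumor", name = "tumor")
  sinus <- add_physical_entity(doc, "RenalSinus", name = "renal sinus")
  ph <- add_phenotype(doc, "Architectural_Pattern",
                      components = list(tumor, sinus),
                      relationships = list(
                        relationship_spec("NCIt:C20625", tumor, sinus)))
  rels <- individual_iris(doc, "Relationship")
  expect_length(rels, 1L)
  rel <- get_individual(doc, rels)
  expect_identical(rel$values$movementType, "NCIt:C20625")
  expect_identical(rel$links$target[rel$links$property == "movingObject"],
                   tumor$iri)
  expect_identical(rel$links$target[rel$links$property == "towards"],
                   sinus$iri)
  expect_identical(sum(ph$links$property == "present_Entity"), 2L)
})

test_that("validator counts agree with the naive triple-by-triple oracle", {
  for (seed in c(11L, 12L, 13L, 14L, 15L)) {
    doc <- random_document(seed)
    rep <- validate_document(doc)
    expect_identical(sum(rep$severity == "error"),
                     oracle_validation_errors(doc))
  }
  # a manufactured violation is seen by both routes
  doc <- random_document(16L)
  ph_iri <- individual_iris(doc, "Phenotype")[[1]]
  ind <- doc$individuals[[ph_iri]]
  ind$links <- ind$links[ind$links$property != "present_Entity", ,
                         drop = FALSE]
  doc$individuals[[ph_iri]] <- ind
  rep <- validate_document(doc)
  expect_identical(sum(rep$severity == "error"), 1L)
  expect_identical(rep$rule[rep$severity == "error"],
                   "phenotype-without-component")
  expect_identical(oracle_validation_errors(doc), 1L)
})

test_that("randomized builder sequences always produce schema-valid documents", {
  for (seed in 21:40) {
    doc <- random_document(seed)
    rep <- validate_document(doc)
    expect_identical(sum(rep$severity == "error"), 0L)
  }
})
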