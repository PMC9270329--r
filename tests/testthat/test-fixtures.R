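test_that("TILs fixtures hit their pixel budgets exactly", {
  b <- make_tils_fixture(10000, 0.3, 25, seed = 1)
  expect_identical(sum(b$mask$labels %in% b$mask$id_map[["seg:stroma"]]),
                   10000L)
  expect_identical(b$manifest$lymphocyte_px, 3000L)
  expect_equal(stromal_tils(b$document, b$mask), 0.3, tolerance = 1 / 10000)
  # every lymphocyte region is a pixel-subset of the stroma region
  stroma_px <- b$mask$labels %in% b$mask$id_map[["seg:stroma"]]
  for (i in seq_len(b$manifest$n_lymphocytes)) {
    lp <- b$mask$labels %in% b$mask$id_map[[paste0("seg:lymphocyte_", i)]]
    expect_true(all(stroma_px[lp]))
  }
  # zero infiltrate leaves no lymphocyte individuals
  b0 <- make_tils_fixture(5000, 0, 10, seed = 2)
  expect_length(individual_iris(b0$document, "Lymphocyte"), 0L)
  # infeasible packings are refused with guidance
  expect_error(make_tils_fixture(1000, 0.3, 0, seed = 3), "packing error")
  expect_error(make_tils_fixture(1000, 1.2, 5, seed = 3), "til_fraction")
})

test_that("identical parameters and seed reproduce bit-identical bundles", {
  a <- make_tils_fixture(4000, 0.35, 12, seed = 5)
  b <- make_tils_fixture(4000, 0.35, 12, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$manifest, b$manifest)
  expect_true(documents_equal(a$document, b$document))
  r1 <- make_rhabdoid_fixture(3, seed = 6)
  r2 <- make_rhabdoid_fixture(3, seed = 6)
  expect_identical(r1$mask, r2$mask)
  expect_true(documents_equal(r1$document, r2$document))
  # a different seed perturbs the imagery
  r3 <- make_rhabdoid_fixture(3, seed = 7)
  expect_false(identical(r1$image, r3$image))
})

test_that("rhabdoid bundles carry the four quantified characteristics", {
  b <- make_rhabdoid_fixture(4, seed = 8)
  doc <- b$document
  ph <- individual_iris(doc, "Cellular_Appearances")
  expect_length(ph, 1L)
  cells <- components_of_phenotype(doc, ph[[1]])
  expect_length(cells, 4L)
  for (i in seq_along(cells)) {
    expect_identical(
      quantification_parameters(doc, cells[[i]]),
      c("area", "circularity", "eccentricity", "image_entropy"))
  }
  # measured areas stay within the manifest-declared bounds and are
  # recomputable from the emitted mask
  for (i in seq_len(b$manifest$n_cells)) {
    ci <- b$manifest$cells[[i]]
    expect_gte(ci$cell_area_px, ci$area_bounds[[1]])
    expect_lte(ci$cell_area_px, ci$area_bounds[[2]])
    expect_identical(ci$cell_area_px,
                     region_area(b$mask, paste0("seg:cell_", i)))
    expect_equal(ci$nucleus_eccentricity,
                 region_eccentricity(b$mask, paste0("seg:nucleus_", i)))
  }
  expect_error(make_rhabdoid_fixture(0, seed = 1), "at least one cell")
})

test_that("alveolar nests nest erythrocytes at depth three or more", {
  b <- make_alveolar_fixture(3, seed = 9)
  doc <- b$document
  for (cp in individual_iris(doc, "Capillary")) {
    expect_gt(length(entities_within(doc, cp, "Erythrocyte")), 0L)
  }
  # phenotype -> nest -> stroma -> capillary -> erythrocyte
  ph <- individual_iris(doc, "Architectural_Pattern")[[1]]
  nests <- components_of_phenotype(doc, ph)
  expect_length(nests, 3L)
  depth_chain <- function(iri, depth) {
    if (get_individual(doc, iri)$class == "Erythrocyte") return(depth)
    edges <- get_individual(doc, iri)$links
    kids <- edges$target[edges$property %in%
                           c("hasComponent", "hasCell",
                             "hasCellularComponent", "hasAnatomicalEntity")]
    if (!length(kids)) return(-Inf)
    max(vapply(kids, depth_chain, numeric(1), depth = depth + 1L))
  }
  expect_gte(max(vapply(nests, depth_chain, numeric(1), depth = 1L)), 3L)
  # manifest areas are recomputable from the mask by brute force
  for (i in seq_len(b$manifest$n_nests)) {
    pn <- b$manifest$per_nest[[i]]
    expect_identical(pn$capillary_px,
                     region_area(b$mask, paste0("seg:capillary_", i)))
    expect_identical(pn$parenchyma_px,
                     region_area(b$mask, paste0("seg:parenchyma_", i)))
  }
})

test_that("every fixture bundle document validates with an empty report", {
  bundles <- list(make_tils_fixture(3000, 0.3, 8, seed = 10),
                  make_tils_fixture(3000, 0.6, 8, seed = 10),
                  make_rhabdoid_fixture(2, seed = 10),
                  make_alveolar_fixture(2, seed = 10))
  for (b in bundles) {
    rep <- validate_document(b$document)
    expect_identical(nrow(rep[rep$severity == "error", ]), 0L)
    # every document segmentation resolves in the mask
    segs <- unlist(segmentations_of(b$document,
                                    individual_iris(b$document)))
    expect_true(all(segs %in% names(b$mask$id_map)))
  }
  expect_identical(nrow(validate_document(build_extension_exemplar())), 0L)
})

test_that("the extension exemplar records one movement and round-trips", {
  doc <- build_extension_exemplar()
  rels <- individual_iris(doc, "Relationship")
  expect_length(rels, 1L)
  sinus <- individual_iris(doc, "RenalSinus")[[1]]
  res <- run_sparql(doc, paste0(
    "PREFIX histo: <", HISTOML_NS, ">\n",
    "SELECT ?r WHERE { ?r a histo:Relationship ; histo:towards <",
    sinus, "> }"))
  expect_identical(nrow(res), 1L)
  path <- withr::local_tempfile(fileext = ".ttl")
  write_document(doc, path, dialect = "turtle")
  expect_true(documents_equal(doc, read_document(path)))
})
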