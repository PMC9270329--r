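test_that("morphometry matches closed forms on canonical shapes", {
  mk <- label_mask(disk_matrix(50), list(d = 1))
  expect_equal(region_circularity(mk, "d"), 1.0, tolerance = 0.1)
  expect_lt(abs(region_eccentricity(mk, "d")), 0.05)
  # 10x10 solid square
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  msq <- label_mask(sq, list(s = 1))
  expect_identical(region_area(msq, "s"), 100L)
  # physical units
  msq2 <- label_mask(sq, list(s = 1), microns_per_pixel = 0.5)
  expect_equal(region_area(msq2, "s", unit = "um2"), 25)
  # thin bar is far from circular
  bar <- matrix(0L, 3, 102); bar[2, 2:101] <- 1L
  mbar <- label_mask(bar, list(b = 1))
  expect_lt(region_circularity(mbar, "b"), 0.5)
  # 2:1 axis-ratio ellipse: e = sqrt(1 - 1/4)
  mell <- label_mask(ellipse_matrix(60, 30), list(e = 1))
  expect_equal(region_eccentricity(mell, "e"), sqrt(3) / 2, tolerance = 0.05)
  # entropy closed forms
  img_const <- intensity_image(matrix(100L, 3, 102))
  expect_identical(region_entropy(img_const, mbar, "b"), 0)
  img_coin <- intensity_image(matrix(c(0L, 255L), 3, 102))
  expect_equal(region_entropy(img_coin, mbar, "b"), 1)
  # uniform noise approaches the 8-bit maximum
  set.seed(1)
  big <- matrix(1L, 100, 100)
  mbig <- label_mask(big, list(r = 1))
  img_noise <- intensity_image(matrix(sample(0:255, 1e4, TRUE), 100, 100))
  expect_equal(region_entropy(img_noise, mbig, "r"), 8, tolerance = 0.05)
})

test_that("circularity decreases along increasingly elongated ellipses", {
  circs <- vapply(seq(1, 3, by = 0.25), function(k) {
    m <- label_mask(ellipse_matrix(round(30 * k), round(30 / k)), list(x = 1))
    region_circularity(m, "x")
  }, numeric(1))
  expect_true(all(diff(circs) < 0))
})

test_that("all metrics equal the naive pixel-loop oracles on random blobs", {
  set.seed(42)
  for (rep in 1:12) {
    m <- random_blob(sample(30:220, 1))
    mask <- label_mask(m, list(blob = 1))
    img <- intensity_image(matrix(sample(0:255, length(m), TRUE), nrow(m)))
    expect_identical(region_area(mask, "blob"), oracle_area(m, 1L))
    expect_equal(region_eccentricity(mask, "blob"),
                 oracle_eccentricity(m, 1L), tolerance = 1e-12)
    expect_equal(region_entropy(img, mask, "blob"),
                 oracle_entropy(img$pixels, m, 1L), tolerance = 1e-12)
    expect_equal(region_circularity(mask, "blob"), oracle_circularity(m),
                 tolerance = 1e-12)
  }
})

test_that("metrics are translation-invariant and area is additive", {
  set.seed(7)
  m <- random_blob(120, dims = c(40L, 40L))
  big <- matrix(0L, 64, 64)
  big[1:40, 1:40] <- m
  shifted <- matrix(0L, 64, 64)
  shifted[21:60, 19:58] <- m
  img_big <- matrix(rep(seq(0L, 249L, length.out = 64), 64), 64)
  storage.mode(img_big) <- "integer"
  img_shift <- matrix(0L, 64, 64)
  img_shift[21:60, 19:58] <- img_big[1:40, 1:40]
  ma <- label_mask(big, list(x = 1)); mb <- label_mask(shifted, list(x = 1))
  expect_identical(region_area(ma, "x"), region_area(mb, "x"))
  expect_equal(region_circularity(ma, "x"), region_circularity(mb, "x"))
  expect_equal(region_eccentricity(ma, "x"), region_eccentricity(mb, "x"))
  expect_equal(region_entropy(intensity_image(img_big), ma, "x"),
               region_entropy(intensity_image(img_shift), mb, "x"))
  # eccentricity is invariant under 90-degree rotation
  rot <- label_mask(t(big[nrow(big):1, ]), list(x = 1))
  expect_equal(region_eccentricity(ma, "x"), region_eccentricity(rot, "x"),
               tolerance = 1e-12)
  # area is additive over disjoint regions
  two <- matrix(0L, 30, 30)
  two[2:10, 2:10] <- 1L
  two[15:25, 15:25] <- 2L
  mtwo <- label_mask(two, list(a = 1, b = 2, both = c(1, 2)))
  expect_identical(region_area(mtwo, "both"),
                   region_area(mtwo, "a") + region_area(mtwo, "b"))
  # circularity refuses disconnected regions
  expect_error(region_circularity(mtwo, "both"), "disconnected")
})

test_that("degenerate and erroneous mask inputs are caught", {
  m <- matrix(0L, 8, 8); m[4, 2:7] <- 1L
  mask <- label_mask(m, list(line = 1))
  # collinear region: eccentricity approaches 1, no error
  expect_equal(region_eccentricity(mask, "line"), 1)
  expect_error(region_area(mask, "nope"), "unknown segmentation id")
  expect_error(label_mask(m, list(line = 2)), "absent from the mask")
  img_small <- intensity_image(matrix(0L, 4, 4))
  expect_error(region_entropy(img_small, mask, "line"), "shapes differ")
})

test_that("quantify_entity attaches one node per parameter and matches direct calls", {
  b <- make_rhabdoid_fixture(1, seed = 13)
  doc <- b$document
  cell <- individual_iris(doc, "NeoplasticCell")[[1]]
  nodes <- quantify_entity(doc, cell, b$mask, b$image)
  expect_length(nodes, 4L)
  vals <- stats::setNames(vapply(nodes, `[[`, numeric(1), "value"),
                          vapply(nodes, `[[`, character(1), "parameter_name"))
  expect_identical(unname(vals["area"]),
                   as.numeric(region_area(b$mask, "seg:cell_1")))
  expect_identical(unname(vals["circularity"]),
                   region_circularity(b$mask, "seg:cell_1"))
  expect_identical(unname(vals["eccentricity"]),
                   region_eccentricity(b$mask, "seg:cell_1"))
  expect_identical(unname(vals["image_entropy"]),
                   region_entropy(b$image, b$mask, "seg:cell_1"))
  # empty parameter set is a no-op
  before <- n_individuals(doc)
  expect_identical(quantify_entity(doc, cell, b$mask, b$image,
                                   parameters = character(0)),
                   list())
  expect_identical(n_individuals(doc), before)
  # unresolvable segmentation ids name the offender
  doc2 <- new_document(slide_metadata(10, 10, 40))
  ghost <- add_physical_entity(doc2, "Lymphocyte",
                               segmentation_ids = "seg:ghost")
  expect_error(quantify_entity(doc2, ghost$iri, b$mask, b$image),
               "seg:ghost")
})

test_that("stromal TILs handles the no-infiltrate and full-coverage poles", {
  b0 <- make_tils_fixture(2000, 0, 5, seed = 14)
  expect_identical(stromal_tils(b0$document, b0$mask), 0)
  b1 <- make_tils_fixture(2000, 1, 5, seed = 14)
  expect_identical(stromal_tils(b1$document, b1$mask), 1)
  bm <- make_tils_fixture(2000, 0.3, 5, seed = 14)
  expect_equal(stromal_tils(bm$document, bm$mask), 0.3,
               tolerance = 1 / 2000)
  expect_identical(stromal_tils(bm$document, bm$mask, clip_to_stroma = TRUE),
                   stromal_tils(bm$document, bm$mask))
  # a document without stromal components cannot be scored
  doc <- new_document(slide_metadata(10, 10, 40))
  expect_error(stromal_tils(doc, bm$mask), "no stromal component")
  # a stroma without segmentation has zero (undefined) stromal area
  add_physical_entity(doc, "Stroma", name = "bare stroma")
  expect_error(stromal_tils(doc, bm$mask), "stromal area is zero")
  # lymphocytes must carry segmentations
  doc3 <- new_document(slide_metadata(200, 200, 40))
  st <- add_physical_entity(doc3, "Stroma", segmentation_ids = "seg:stroma")
  ly <- add_physical_entity(doc3, "Lymphocyte")
  link_component(doc3, st, ly, "hasCell")
  expect_error(stromal_tils(doc3, bm$mask), "without segmentation")
})
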