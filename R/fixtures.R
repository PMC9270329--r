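# Synthetic fixture generators: paired (image, label mask, document) bundles
# emulating canonical renal-cancer and breast-cancer exemplars with exact,
# programmatically known ground truth. Images are synthetic cartoons (flat
# tints plus Gaussian noise), not stain simulations: the bundles exercise
# representation and measurement, not H&E realism.

# run code under a temporary RNG state so generators are deterministic
# without clobbering the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_fixture_bundle <- function(image, mask, document, manifest) {
  structure(list(image = image, mask = mask, document = document,
                 manifest = manifest),
            class = "histoml_fixture_bundle")
}

#' @export
print.histoml_fixture_bundle <- function(x, ...) {
  cat("fixture bundle: ", nrow(x$mask$labels), "x", ncol(x$mask$labels),
      " px, ", length(x$mask$id_map), " segmentations, ",
      n_individuals(x$document), " individuals (seed ",
      x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

# flat tint + rounded Gaussian noise, clipped to [0, 255]
tinted <- function(base, labels, tints, noise_sd) {
  img <- matrix(base, nrow(labels), ncol(labels))
  for (lv in names(tints)) img[labels == as.integer(lv)] <- tints[[lv]]
  img <- img + round(stats::rnorm(length(img), 0, noise_sd))
  img[img < 0] <- 0; img[img > 255] <- 255
  intensity_image(img)
}

#' Generate a stromal-TILs fixture
#'
#' Builds a tumor-immune exemplar: a parenchyma block and a stromal region
#' of exactly `stroma_area_px` pixels in which lymphocyte regions are
#' disjoint pixel-subsets totalling exactly
#' `round(til_fraction * stroma_area_px)` pixels, so the true stromal TILs
#' fraction is known to within the rounding of that product. The document
#' encodes the phenotype, parenchyma, stroma and lymphocytes with
#' containment links and segmentation ids; the stroma's segmentation owns
#' the lymphocyte labels too, so its area includes the cells it hosts.
#'
#' Lymphocytes are placed by seeded region growing: each starts from a
#' random free stromal pixel and annexes the free neighbour closest to its
#' seed until its exact pixel budget is met, which yields disjoint
#' quasi-disk regions at sparse densities and space-filling cells at dense
#' ones (up to full coverage).
#'
#' @param stroma_area_px exact stromal area in pixels.
#' @param til_fraction target fraction in `[0, 1]`.
#' @param n_lymphocytes number of lymphocyte regions (ignored when
#'   `til_fraction` is 0).
#' @param seed RNG seed recorded in the manifest.
#' @return a `histoml_fixture_bundle`.
#' @export
make_tils_fixture <- function(stroma_area_px = 10000, til_fraction = 0.3,
                              n_lymphocytes = 25, seed = 1) {
  if (til_fraction < 0 || til_fraction > 1) {
    stop("til_fraction must lie in [0, 1]")
  }
  if (stroma_area_px < 1) stop("stroma_area_px must be positive")
  target <- as.integer(round(til_fraction * stroma_area_px))
  if (target > 0L && n_lymphocytes < 1L) {
    stop("packing error: need at least one lymphocyte to place ", target,
         " pixels; increase n_lymphocytes")
  }
  with_seed(seed, {
    A <- as.integer(stroma_area_px)
    w <- as.integer(ceiling(sqrt(A)))
    h_full <- A %/% w
    rem <- A %% w
    sh <- h_full + (rem > 0L)
    par_w <- 20L
    r0 <- 11L; c0 <- par_w + 21L      # stroma origin
    H <- sh + 20L; W <- c0 + w + 9L
    labels <- matrix(0L, H, W)
    # parenchyma strip
    labels[r0:(r0 + sh - 1L), 6L:(5L + par_w)] <- 2L
    # stroma: full rows then a partial row, exactly A pixels
    if (h_full > 0L) {
      labels[r0:(r0 + h_full - 1L), c0:(c0 + w - 1L)] <- 1L
    }
    if (rem > 0L) labels[r0 + h_full, c0:(c0 + rem - 1L)] <- 1L
    stopifnot(sum(labels == 1L) == A)

    lymph_labels <- integer(0)
    lymph_areas <- integer(0)
    if (target > 0L) {
      n <- as.integer(n_lymphocytes)
      budgets <- rep(target %/% n, n)
      extra <- target %% n
      if (extra > 0L) budgets[seq_len(extra)] <- budgets[seq_len(extra)] + 1L
      budgets <- budgets[budgets > 0L]
      n <- length(budgets)
      lymph_labels <- 10L + seq_len(n)
      rows <- row(labels); cols <- col(labels)
      nrl <- nrow(labels)
      # grow each lymphocyte as a quasi-disk: from a random free seed,
      # repeatedly annex the free 4-neighbour closest to the seed. This
      # yields connected, pairwise-disjoint regions of exactly the budgeted
      # pixel counts at any infiltrate density; when the remaining free
      # space is too fragmented for a connected region, the budget is
      # filled from the leftover free pixels in raster order.
      grow_region <- function(labels, seed_px, a_i) {
        cr <- rows[seed_px]; cc <- cols[seed_px]
        region <- integer(0)
        frontier <- seed_px
        fdist <- 0
        while (length(region) < a_i && length(frontier)) {
          k <- which.min(fdist)
          px <- frontier[k]
          frontier <- frontier[-k]; fdist <- fdist[-k]
          region <- c(region, px)
          labels[px] <- -1L  # claimed
          nbr <- c(px - 1L, px + 1L, px - nrl, px + nrl)
          nbr <- nbr[nbr >= 1L & nbr <= length(labels)]
          nbr <- nbr[labels[nbr] == 1L & !nbr %in% frontier]
          # guard against wrapping across matrix columns
          nbr <- nbr[abs(rows[nbr] - rows[px]) + abs(cols[nbr] - cols[px]) == 1L]
          if (length(nbr)) {
            frontier <- c(frontier, nbr)
            fdist <- c(fdist, (rows[nbr] - cr)^2 + (cols[nbr] - cc)^2)
          }
        }
        list(labels = labels, region = region)
      }
      for (i in seq_len(n)) {
        a_i <- budgets[i]
        free <- which(labels == 1L)
        if (length(free) < a_i) {
          stop("packing error: ", length(free), " free stromal pixels left ",
               "but lymphocyte ", i, " needs ", a_i,
               "; lower til_fraction or n_lymphocytes")
        }
        region <- integer(0)
        for (try in seq_len(25L)) {
          seed_px <- free[[sample.int(length(free), 1L)]]
          g <- grow_region(labels, seed_px, a_i)
          if (length(g$region) == a_i) {
            labels <- g$labels
            region <- g$region
            break
          }
        }
        if (!length(region)) {
          # fragmented leftovers: fill in raster order, exactness first
          region <- free[seq_len(a_i)]
          labels[region] <- -1L
        }
        labels[region] <- lymph_labels[i]
      }
      lymph_areas <- vapply(lymph_labels,
                            function(lv) sum(labels == lv), integer(1))
      stopifnot(sum(lymph_areas) == target)
    }

    id_map <- list("seg:parenchyma" = 2L,
                   "seg:stroma" = c(1L, lymph_labels))
    # when the infiltrate covers everything the plain stroma label vanishes
    if (!any(labels == 1L)) id_map[["seg:stroma"]] <- lymph_labels
    for (i in seq_along(lymph_labels)) {
      id_map[[paste0("seg:lymphocyte_", i)]] <- lymph_labels[i]
    }
    tints <- stats::setNames(as.list(c(170, 210, rep(90, length(lymph_labels)))),
                             c("2", "1", as.character(lymph_labels)))
    if (!any(labels == 1L)) tints[["1"]] <- NULL
    image <- tinted(235, labels, tints, noise_sd = 6)
    mask <- label_mask(labels, id_map)

    doc <- new_document(slide_metadata(H, W, 40), slide_id = "tils")
    par_ind <- add_physical_entity(doc, "Parenchyma",
                                   segmentation_ids = "seg:parenchyma",
                                   name = "parenchyma")
    stroma <- add_physical_entity(doc, "Stroma",
                                  segmentation_ids = "seg:stroma",
                                  name = "stroma")
    if (length(lymph_labels)) {
      ref <- add_entity_reference(doc, "lymphocyte", xrefs = "NCIt:C12535")
      for (i in seq_along(lymph_labels)) {
        ly <- add_physical_entity(doc, "Lymphocyte", entity_reference = ref,
                                  segmentation_ids = paste0("seg:lymphocyte_", i))
        link_component(doc, stroma, ly, "hasCell")
      }
    }
    add_phenotype(doc, "Architectural_Pattern",
                  components = list(par_ind, stroma),
                  name = "tumor-immune phenotype")

    manifest <- list(kind = "tils", seed = seed,
                     stroma_area_px = A,
                     lymphocyte_px = as.integer(target),
                     til_fraction = target / A,
                     n_lymphocytes = length(lymph_labels),
                     per_lymphocyte_px = as.integer(lymph_areas),
                     height = H, width = W)
    new_fixture_bundle(image, mask, doc, manifest)
  })
}

# pixels of a (possibly rotated, modulated) ellipse of centre (cr, cc)
ellipse_pixels <- function(rows, cols, cr, cc, a, b, theta = 0,
                           wobble = NULL) {
  u <- (rows - cr) * cos(theta) + (cols - cc) * sin(theta)
  v <- -(rows - cr) * sin(theta) + (cols - cc) * cos(theta)
  q <- (u / a)^2 + (v / b)^2
  lim <- 1
  if (!is.null(wobble)) {
    phi <- atan2(v, u)
    lim <- (1 + wobble$a1 * sin(3 * phi + wobble$p1) +
              wobble$a2 * sin(5 * phi + wobble$p2))^2
  }
  which(q <= lim)
}

#' Generate a rhabdoid-cells fixture
#'
#' Draws `n_cells` large elliptical neoplastic cells, each containing an
#' off-centre irregular nucleus with a bright nucleolus spot. The document
#' is a `Cellular_Appearances` phenotype whose cells carry the four
#' characteristic attributes -- cell size, nucleus shape, nucleus position
#' and nucleolus prominence -- quantified by area, circularity,
#' eccentricity and image entropy measured on the bundle's own mask.
#'
#' @param n_cells number of cells (>= 1; a phenotype needs components).
#' @param size_range_px range of cell areas in pixels.
#' @param eccentricity_range range of nucleus ellipse eccentricities in
#'   `[0, 1)`.
#' @param seed RNG seed.
#' @return a `histoml_fixture_bundle`.
#' @export
make_rhabdoid_fixture <- function(n_cells = 4,
                                  size_range_px = c(1500, 3000),
                                  eccentricity_range = c(0.5, 0.8),
                                  seed = 1) {
  if (n_cells < 1) {
    stop("a Cellular_Appearances phenotype needs at least one cell component")
  }
  if (length(size_range_px) != 2L || any(size_range_px < 200) ||
      size_range_px[1] > size_range_px[2]) {
    stop("size_range_px must be an increasing range of areas >= 200 px")
  }
  if (length(eccentricity_range) != 2L || any(eccentricity_range < 0) ||
      any(eccentricity_range >= 1) ||
      eccentricity_range[1] > eccentricity_range[2]) {
    stop("eccentricity_range must be an increasing range within [0, 1)")
  }
  with_seed(seed, {
    e_cell <- 0.35
    a_max <- sqrt(max(size_range_px) / (pi * sqrt(1 - e_cell^2)))
    box <- as.integer(2 * ceiling(a_max) + 10)
    ncol_grid <- as.integer(ceiling(sqrt(n_cells)))
    nrow_grid <- as.integer(ceiling(n_cells / ncol_grid))
    H <- nrow_grid * box; W <- ncol_grid * box
    labels <- matrix(0L, H, W)
    rows <- row(labels); cols <- col(labels)
    cell_info <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      gi <- (i - 1L) %/% ncol_grid; gj <- (i - 1L) %% ncol_grid
      cr <- gi * box + box / 2; cc <- gj * box + box / 2
      A_c <- stats::runif(1, size_range_px[1], size_range_px[2])
      a_c <- sqrt(A_c / (pi * sqrt(1 - e_cell^2)))
      b_c <- a_c * sqrt(1 - e_cell^2)
      th <- stats::runif(1, 0, pi)
      cyto <- i * 10L + 1L; nuc <- i * 10L + 2L; nucl <- i * 10L + 3L
      cell_px <- ellipse_pixels(rows, cols, cr, cc, a_c, b_c, th)
      labels[cell_px] <- cyto
      # eccentric (off-centre) irregular nucleus
      e_n <- stats::runif(1, eccentricity_range[1], eccentricity_range[2])
      A_n <- 0.30 * A_c
      a_n <- sqrt(A_n / (pi * sqrt(1 - e_n^2)))
      b_n <- a_n * sqrt(1 - e_n^2)
      off_ang <- stats::runif(1, 0, 2 * pi)
      off <- 0.45 * (b_c - b_n)
      ncr <- cr + off * sin(off_ang); ncc <- cc + off * cos(off_ang)
      wob <- list(a1 = 0.10, p1 = stats::runif(1, 0, 2 * pi),
                  a2 = 0.05, p2 = stats::runif(1, 0, 2 * pi))
      nuc_px <- intersect(ellipse_pixels(rows, cols, ncr, ncc, a_n, b_n,
                                         th, wob),
                          cell_px)
      labels[nuc_px] <- nuc
      # bright nucleolus spot near the nucleus centre
      nucl_px <- intersect(which((rows - ncr)^2 + (cols - ncc)^2 <= 2.5^2),
                           nuc_px)
      if (!length(nucl_px)) nucl_px <- nuc_px[[1]]
      labels[nucl_px] <- nucl
      cell_info[[i]] <- list(cyto = cyto, nuc = nuc, nucl = nucl,
                             target_area = A_c, target_ecc = e_n)
    }
    id_map <- list()
    for (i in seq_len(n_cells)) {
      ci <- cell_info[[i]]
      id_map[[paste0("seg:cell_", i)]] <- c(ci$cyto, ci$nuc, ci$nucl)
      id_map[[paste0("seg:nucleus_", i)]] <- c(ci$nuc, ci$nucl)
      id_map[[paste0("seg:nucleolus_", i)]] <- ci$nucl
    }
    tints <- list()
    for (i in seq_len(n_cells)) {
      ci <- cell_info[[i]]
      tints[[as.character(ci$cyto)]] <- 180
      tints[[as.character(ci$nuc)]] <- 100
      tints[[as.character(ci$nucl)]] <- 225
    }
    image <- tinted(240, labels, tints, noise_sd = 12)
    mask <- label_mask(labels, id_map)

    doc <- new_document(slide_metadata(H, W, 40), slide_id = "rhabdoid")
    ref <- add_entity_reference(doc, "rhabdoid cell", xrefs = "NCIt:C36908")
    cells <- list()
    measured <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      sid_cell <- paste0("seg:cell_", i)
      sid_nuc <- paste0("seg:nucleus_", i)
      cell <- add_physical_entity(doc, "NeoplasticCell",
                                  entity_reference = ref,
                                  segmentation_ids = sid_cell,
                                  name = paste0("Rhabdoid_Cell", i))
      nucleus <- add_physical_entity(doc, "Nucleus",
                                     segmentation_ids = sid_nuc,
                                     name = paste0("Nucleus", i))
      nucleolus <- add_physical_entity(
        doc, "Nucleolus",
        segmentation_ids = paste0("seg:nucleolus_", i),
        name = paste0("Nucleolus", i))
      link_component(doc, cell, nucleus, "hasCellularComponent")
      link_component(doc, nucleus, nucleolus, "hasCellularComponent")
      area_px <- region_area(mask, sid_cell)
      circ <- region_circularity(mask, sid_nuc)
      ecc <- region_eccentricity(mask, sid_nuc)
      ent <- region_entropy(image, mask, sid_nuc)
      attach_attribute(doc, cell, "large", xrefs = "PATO:0000586",
                       quantifications = list(
                         quantification("area", area_px, "px",
                                        formula = morphometry_formula[["area"]])))
      attach_attribute(doc, nucleus, "irregularly-shaped",
                       xrefs = "PATO:0000944",
                       quantifications = list(
                         quantification("circularity", circ, "dimensionless",
                                        formula = morphometry_formula[["circularity"]])))
      attach_attribute(doc, nucleus, "eccentric", xrefs = "PATO:0000617",
                       quantifications = list(
                         quantification("eccentricity", ecc, "dimensionless",
                                        formula = morphometry_formula[["eccentricity"]])))
      attach_attribute(doc, nucleolus, "prominent", xrefs = "PATO:0001482",
                       quantifications = list(
                         quantification("image_entropy", ent, "bit",
                                        formula = morphometry_formula[["image_entropy"]])))
      cells[[i]] <- cell
      measured[[i]] <- list(cell_area_px = area_px,
                            area_bounds = c(floor(size_range_px[1] * 0.8),
                                            ceiling(size_range_px[2] * 1.1)),
                            nucleus_circularity = circ,
                            nucleus_eccentricity = ecc,
                            nucleus_entropy_bits = ent,
                            target_area = cell_info[[i]]$target_area,
                            target_eccentricity = cell_info[[i]]$target_ecc)
    }
    add_phenotype(doc, "Cellular_Appearances", components = cells,
                  name = "rhabdoid feature", xrefs = "NCIt:C121927")
    manifest <- list(kind = "rhabdoid", seed = seed, n_cells = n_cells,
                     size_range_px = as.numeric(size_range_px),
                     eccentricity_range = as.numeric(eccentricity_range),
                     cells = measured, height = H, width = W)
    new_fixture_bundle(image, mask, doc, manifest)
  })
}

#' Generate an alveolar-pattern fixture
#'
#' Lays out `n_nests` alveolar nests: a parenchyma core full of neoplastic
#' cells, ringed by a capillary (the stroma of the nest) containing
#' erythrocytes and endothelia. The document is an `Architectural_Pattern`
#' with the nested containment (nest -> stroma/parenchyma -> capillary ->
#' cells) and per-region segmentation ids.
#'
#' @param n_nests number of nests (>= 1).
#' @param seed RNG seed.
#' @return a `histoml_fixture_bundle`.
#' @export
make_alveolar_fixture <- function(n_nests = 2, seed = 1) {
  if (n_nests < 1) stop("n_nests must be at least 1")
  with_seed(seed, {
    rp <- 18; rc <- 24   # parenchyma radius, capillary outer radius
    box <- as.integer(2 * rc + 8)
    ncol_grid <- as.integer(ceiling(sqrt(n_nests)))
    nrow_grid <- as.integer(ceiling(n_nests / ncol_grid))
    H <- nrow_grid * box; W <- ncol_grid * box
    labels <- matrix(0L, H, W)
    rows <- row(labels); cols <- col(labels)
    nest_info <- vector("list", n_nests)
    for (i in seq_len(n_nests)) {
      gi <- (i - 1L) %/% ncol_grid; gj <- (i - 1L) %% ncol_grid
      cr <- gi * box + box / 2; cc <- gj * box + box / 2
      d2 <- (rows - cr)^2 + (cols - cc)^2
      base <- i * 100L
      cap <- base + 1L; par <- base + 2L
      labels[d2 <= rc^2 & d2 > rp^2] <- cap
      labels[d2 <= rp^2] <- par
      rmid <- (rp + rc) / 2
      n_ery <- 3L; n_endo <- 2L; n_ncell <- 5L
      ery <- base + 10L + seq_len(n_ery)
      endo <- base + 20L + seq_len(n_endo)
      ncell <- base + 30L + seq_len(n_ncell)
      angs <- stats::runif(n_ery + n_endo, 0, 2 * pi)
      for (k in seq_len(n_ery)) {
        pr <- cr + rmid * sin(angs[k]); pc <- cc + rmid * cos(angs[k])
        px <- which((rows - pr)^2 + (cols - pc)^2 <= 2^2 & labels == cap)
        if (!length(px)) px <- which(labels == cap)[k]
        labels[px] <- ery[k]
      }
      for (k in seq_len(n_endo)) {
        a <- angs[n_ery + k]
        pr <- cr + rmid * sin(a); pc <- cc + rmid * cos(a)
        px <- which((rows - pr)^2 + (cols - pc)^2 <= 2^2 & labels == cap)
        if (!length(px)) px <- which(labels == cap)[n_ery + k]
        labels[px] <- endo[k]
      }
      cangs <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_ncell) / n_ncell
      for (k in seq_len(n_ncell)) {
        pr <- cr + 0.55 * rp * sin(cangs[k]); pc <- cc + 0.55 * rp * cos(cangs[k])
        px <- which((rows - pr)^2 + (cols - pc)^2 <= 3^2 & labels == par)
        if (!length(px)) px <- which(labels == par)[k]
        labels[px] <- ncell[k]
      }
      nest_info[[i]] <- list(cap = cap, par = par, ery = ery, endo = endo,
                             ncell = ncell)
    }
    id_map <- list()
    for (i in seq_len(n_nests)) {
      ni <- nest_info[[i]]
      all_lab <- c(ni$cap, ni$par, ni$ery, ni$endo, ni$ncell)
      id_map[[paste0("seg:nest_", i)]] <- all_lab
      id_map[[paste0("seg:capillary_", i)]] <- c(ni$cap, ni$ery, ni$endo)
      id_map[[paste0("seg:parenchyma_", i)]] <- c(ni$par, ni$ncell)
      for (k in seq_along(ni$ery)) {
        id_map[[paste0("seg:erythrocyte_", i, "_", k)]] <- ni$ery[k]
      }
      for (k in seq_along(ni$endo)) {
        id_map[[paste0("seg:endothelium_", i, "_", k)]] <- ni$endo[k]
      }
      for (k in seq_along(ni$ncell)) {
        id_map[[paste0("seg:neoplastic_cell_", i, "_", k)]] <- ni$ncell[k]
      }
    }
    tints <- list()
    for (i in seq_len(n_nests)) {
      ni <- nest_info[[i]]
      tints[[as.character(ni$cap)]] <- 210
      tints[[as.character(ni$par)]] <- 190
      for (lv in ni$ery) tints[[as.character(lv)]] <- 120
      for (lv in ni$endo) tints[[as.character(lv)]] <- 150
      for (lv in ni$ncell) tints[[as.character(lv)]] <- 160
    }
    image <- tinted(235, labels, tints, noise_sd = 6)
    mask <- label_mask(labels, id_map)

    doc <- new_document(slide_metadata(H, W, 20), slide_id = "alveolar")
    ery_ref <- add_entity_reference(doc, "erythrocyte", xrefs = "NCIt:C12521")
    nests <- list()
    for (i in seq_len(n_nests)) {
      ni <- nest_info[[i]]
      nest <- add_physical_entity(doc, "NeoplasticArea",
                                  segmentation_ids = paste0("seg:nest_", i),
                                  name = paste0("alveolar_nest_", i))
      stroma <- add_physical_entity(
        doc, "Stroma", segmentation_ids = paste0("seg:capillary_", i),
        name = paste0("stroma_", i))
      parn <- add_physical_entity(
        doc, "Parenchyma", segmentation_ids = paste0("seg:parenchyma_", i),
        name = paste0("parenchyma_", i))
      capillary <- add_physical_entity(
        doc, "Capillary", segmentation_ids = paste0("seg:capillary_", i),
        name = paste0("capillary_", i))
      link_component(doc, nest, stroma, "hasComponent")
      link_component(doc, nest, parn, "hasComponent")
      link_component(doc, stroma, capillary, "hasAnatomicalEntity")
      for (k in seq_along(ni$ery)) {
        e <- add_physical_entity(
          doc, "Erythrocyte", entity_reference = ery_ref,
          segmentation_ids = paste0("seg:erythrocyte_", i, "_", k))
        link_component(doc, capillary, e, "hasCell")
      }
      for (k in seq_along(ni$endo)) {
        e <- add_physical_entity(
          doc, "Endothelium",
          segmentation_ids = paste0("seg:endothelium_", i, "_", k))
        link_component(doc, capillary, e, "hasCell")
      }
      for (k in seq_along(ni$ncell)) {
        e <- add_physical_entity(
          doc, "NeoplasticCell",
          segmentation_ids = paste0("seg:neoplastic_cell_", i, "_", k))
        link_component(doc, parn, e, "hasCell")
      }
      nests[[i]] <- nest
    }
    add_phenotype(doc, "Architectural_Pattern", components = nests,
                  name = "alveolar pattern", xrefs = "NCIt:C121918")
    manifest <- list(kind = "alveolar", seed = seed, n_nests = n_nests,
                     per_nest = lapply(nest_info, function(ni) {
                       list(capillary_px = sum(labels %in% c(ni$cap, ni$ery,
                                                             ni$endo)),
                            parenchyma_px = sum(labels %in% c(ni$par,
                                                              ni$ncell)),
                            n_erythrocytes = length(ni$ery),
                            n_endothelia = length(ni$endo),
                            n_neoplastic_cells = length(ni$ncell))
                     }),
                     height = H, width = W)
    new_fixture_bundle(image, mask, doc, manifest)
  })
}

#' Build the tumor-extension exemplar document
#'
#' A mask-free document representing tumors extending into the renal sinus:
#' an `Architectural_Pattern` phenotype presenting a tumor and a renal
#' sinus, with one `Relationship` individual recording the movement type
#' (an invasion CURIE), the moving object (the tumor) and the subject the
#' movement is towards (the renal sinus).
#'
#' @return a `histoml_document`.
#' @export
build_extension_exemplar <- function() {
  doc <- new_document(slide_metadata(2400, 3200, 10), slide_id = "extension")
  tumor <- add_physical_entity(doc, "Tumor", name = "tumor",
                               segmentation_ids = "seg:tumor")
  sinus <- add_physical_entity(doc, "RenalSinus", name = "renal sinus",
                               segmentation_ids = "seg:renal_sinus")
  add_phenotype(doc, "Architectural_Pattern",
                components = list(tumor, sinus),
                relationships = list(
                  relationship_spec("NCIt:C20625", tumor, sinus)),
                name = "tumor extension into renal sinus")
  doc
}

#' Collect the quantification parameter names describing an entity
#'
#' Gathers the `parameterName` values of every quantification attached to
#' the entity's attributes, including (by default) the attributes of the
#' components it contains -- e.g. a rhabdoid cell's four characteristic
#' parameters live partly on its nucleus and nucleolus.
#'
#' @param doc a `histoml_document`.
#' @param entity_iri entity IRI.
#' @param include_components descend through containment links.
#' @return sorted character vector of distinct parameter names.
#' @export
quantification_parameters <- function(doc, entity_iri,
                                      include_components = TRUE) {
  entity_iri <- iri_of(entity_iri)
  iris <- entity_iri
  if (include_components) {
    iris <- union(iris, contained_entities(doc, entity_iri))
  }
  out <- character(0)
  for (iri in iris) {
    ind <- get_individual(doc, iri)
    for (at in ind$links$target[ind$links$property == "hasAttribute"]) {
      ai <- get_individual(doc, at)
      for (qt in ai$links$target[ai$links$property == "hasQuantification"]) {
        qi <- get_individual(doc, qt)
        out <- union(out, qi$values$parameterName)
      }
    }
  }
  sort(out)
}

#' Write a fixture bundle to a directory
#'
#' Emits `image.png`, `mask.png` + `mask.json` (sidecar), `document.ttl`
#' and `manifest.json`.
#'
#' @param bundle a `histoml_fixture_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_image(bundle$image, file.path(dir, "image.png"))
  write_mask(bundle$mask, file.path(dir, "mask.png"),
             file.path(dir, "mask.json"))
  write_document(bundle$document, file.path(dir, "document.ttl"),
                 dialect = "turtle")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
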