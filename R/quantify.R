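# Quantitative histomorphometry on label-mask regions: the four parameters
# used to objectify cellular characteristics (area, circularity,
# eccentricity, image entropy) and the stromal TILs fraction.

#' Region area
#'
#' Pixel count of a segmentation's region; with `unit = "um2"` the count is
#' scaled by `microns_per_pixel^2`.
#'
#' @param mask a [label_mask()].
#' @param seg_id segmentation id string.
#' @param unit `"px"` or `"um2"` (requires `microns_per_pixel` on the mask).
#' @return numeric area.
#' @export
region_area <- function(mask, seg_id, unit = c("px", "um2")) {
  unit <- match.arg(unit)
  a <- sum(region_pixels(mask, seg_id))
  if (unit == "um2") {
    if (is.null(mask$microns_per_pixel)) {
      stop("mask has no microns_per_pixel; cannot convert area to um^2")
    }
    a <- a * mask$microns_per_pixel^2
  }
  a
}

# 8-connected connectivity check by iterative dilation restricted to the
# region; returns TRUE when all region pixels are reachable from the first.
region_connected <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(TRUE)
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[idx[1, 1], idx[1, 2]] <- TRUE
  total <- sum(m)
  repeat {
    grown <- shift_or(reach)
    grown <- grown & m
    if (sum(grown) == sum(reach)) break
    reach <- grown
    if (sum(reach) == total) break
  }
  sum(reach) == total
}

# dilate a logical matrix by its 8-neighbourhood (plus itself)
shift_or <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  pad <- function(dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc]
    res
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) out <- out | pad(dr, dc)
  }
  out
}

# Moore-neighbour boundary tracing of an 8-connected region. Returns the
# sequence of chain moves (dr, dc); perimeter uses Kulpa's corrected
# chain-code weights (0.948 per straight move, 1.340 per diagonal move),
# which keeps the digital perimeter of a disk within about 1% of 2*pi*r.
KULPA_STRAIGHT <- 0.948
KULPA_DIAGONAL <- 1.340

# clockwise Moore neighbourhood starting east
MOORE <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
                ncol = 2, byrow = TRUE)  # (dr, dc): E SE S SW W NW N NE

region_perimeter <- function(m) {
  n <- sum(m)
  if (n == 1L) return(4 * KULPA_STRAIGHT)
  idx <- which(m, arr.ind = TRUE)
  # start: topmost of the leftmost region pixels, so its west neighbour is
  # guaranteed to lie outside the region
  ord <- order(idx[, 2], idx[, 1])
  s <- as.integer(idx[ord[1], ])
  at <- function(p) p[1] >= 1 && p[2] >= 1 && p[1] <= nrow(m) &&
    p[2] <= ncol(m) && m[p[1], p[2]]
  b <- c(s[1], s[2] - 1L)  # backtrack: last background pixel visited
  cur <- s
  n_straight <- 0L; n_diagonal <- 0L
  first_next <- NULL
  guard <- 0L; max_steps <- 8L * n + 16L
  repeat {
    guard <- guard + 1L
    if (guard > max_steps) stop("boundary tracing failed to terminate")
    start_j <- moore_index(b[1] - cur[1], b[2] - cur[2])
    nxt <- NULL
    b_new <- b
    for (k in 1:8) {
      j <- ((start_j - 1L + k) %% 8L) + 1L
      cand <- c(cur[1] + MOORE[j, 1], cur[2] + MOORE[j, 2])
      if (at(cand)) { nxt <- cand; break }
      b_new <- cand
    }
    if (is.null(nxt)) return(4 * KULPA_STRAIGHT)  # lone pixel; n > 1 never hits
    # stop when the walk leaves the start pixel the same way a second time
    if (all(cur == s)) {
      if (is.null(first_next)) {
        first_next <- nxt
      } else if (all(nxt == first_next)) {
        break
      }
    }
    move <- nxt - cur
    if (move[1] != 0L && move[2] != 0L) n_diagonal <- n_diagonal + 1L
    else n_straight <- n_straight + 1L
    b <- b_new
    cur <- nxt
  }
  KULPA_STRAIGHT * n_straight + KULPA_DIAGONAL * n_diagonal
}

moore_index <- function(dr, dc) {
  for (j in 1:8) if (MOORE[j, 1] == dr && MOORE[j, 2] == dc) return(j)
  stop("not a Moore neighbour offset: ", dr, ",", dc)
}

#' Region circularity
#'
#' `4 * pi * A / P^2` with `A` the pixel area and `P` a corrected digital
#' perimeter (Moore boundary chain code with Kulpa weights: 0.948 per
#' straight move, 1.340 per diagonal move). A rasterized disk scores close
#' to 1; thin elongated shapes score near 0. Values slightly above 1 can
#' occur for small regions because the perimeter estimate is stochastic in
#' the digitization.
#'
#' @param mask a [label_mask()].
#' @param seg_id segmentation id of an 8-connected region.
#' @return dimensionless circularity.
#' @export
region_circularity <- function(mask, seg_id) {
  m <- region_pixels(mask, seg_id)
  if (!region_connected(m)) {
    stop("segmentation id '", seg_id, "' maps to a disconnected region; ",
         "split it into connected components first")
  }
  a <- sum(m)
  p <- region_perimeter(m)
  4 * pi * a / p^2
}

#' Region eccentricity
#'
#' Eccentricity of the ellipse with the same second central moments as the
#' region: `sqrt(1 - lambda2/lambda1)` over the eigenvalues of the pixel
#' covariance matrix. 0 for a disk, approaching 1 for elongated or
#' degenerate (collinear) regions.
#'
#' @param mask a [label_mask()].
#' @param seg_id segmentation id of a region with at least 2 pixels.
#' @return eccentricity in `[0, 1]`.
#' @export
region_eccentricity <- function(mask, seg_id) {
  m <- region_pixels(mask, seg_id)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    stop("eccentricity requires a region of at least 2 pixels")
  }
  r <- idx[, 1] - mean(idx[, 1])
  c <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Region image entropy
#'
#' Shannon entropy (base 2) of the 256-bin intensity histogram over the
#' region's pixels: 0 bits for a constant region, 1 bit for a 50/50
#' two-level region, approaching 8 bits for uniform noise.
#'
#' @param image a [intensity_image()] paired with the mask (same shape).
#' @param mask a [label_mask()].
#' @param seg_id segmentation id string.
#' @return entropy in bits.
#' @export
region_entropy <- function(image, mask, seg_id) {
  if (!identical(dim(image$pixels), dim(mask$labels))) {
    stop("image and mask shapes differ: ",
         paste(dim(image$pixels), collapse = "x"), " vs ",
         paste(dim(mask$labels), collapse = "x"))
  }
  m <- region_pixels(mask, seg_id)
  vals <- image$pixels[m]
  counts <- tabulate(vals + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(vals)
  -sum(p * log2(p))
}

MORPHOMETRY_PARAMETERS <- c("area", "circularity", "eccentricity",
                            "image_entropy")

morphometry_formula <- c(
  area = "A = pixel count (x mpp^2 for um^2)",
  circularity = "4*pi*A/P^2, P = Kulpa chain-code perimeter",
  eccentricity = "sqrt(1 - lambda2/lambda1) of second central moments",
  image_entropy = "-sum p_i log2 p_i over the 256-bin intensity histogram")

#' Measure a document entity and attach the results as quantifications
#'
#' Computes the requested morphometric parameters for each segmentation id
#' of the entity and attaches one [quantification()] per parameter per
#' segmentation under an `EntityAttribute` named after the parameter
#' (reused if the entity already has one of that name).
#'
#' @param doc a `histoml_document`.
#' @param entity_iri IRI of an entity with at least one `segmentation`
#'   value resolvable in `mask`.
#' @param mask a [label_mask()].
#' @param image an [intensity_image()]; required for `image_entropy`.
#' @param parameters subset of `area`, `circularity`, `eccentricity`,
#'   `image_entropy`.
#' @return list of `histoml_quantification` objects attached (empty for an
#'   empty parameter set).
#' @export
quantify_entity <- function(doc, entity_iri, mask, image = NULL,
                            parameters = MORPHOMETRY_PARAMETERS) {
  entity_iri <- iri_of(entity_iri)
  if (length(parameters) == 0L) return(list())
  parameters <- match.arg(parameters, MORPHOMETRY_PARAMETERS,
                          several.ok = TRUE)
  ind <- get_individual(doc, entity_iri)
  seg_ids <- ind$values$segmentation
  if (is.null(seg_ids) || !length(seg_ids)) {
    stop("entity has no segmentation values: ", entity_iri)
  }
  missing_ids <- setdiff(seg_ids, names(mask$id_map))
  if (length(missing_ids)) {
    stop("segmentation id(s) not resolvable in mask: ",
         paste(missing_ids, collapse = ", "))
  }
  if ("image_entropy" %in% parameters && is.null(image)) {
    stop("image_entropy requires an intensity image")
  }
  area_unit <- if (is.null(mask$microns_per_pixel)) "px" else "um2"
  nodes <- list()
  for (sid in seg_ids) {
    for (par in parameters) {
      q <- switch(par,
        area = quantification("area", region_area(mask, sid, area_unit),
                              if (area_unit == "px") "px" else "um^2",
                              formula = morphometry_formula[["area"]]),
        circularity = quantification("circularity",
                                     region_circularity(mask, sid),
                                     "dimensionless",
                                     formula = morphometry_formula[["circularity"]]),
        eccentricity = quantification("eccentricity",
                                      region_eccentricity(mask, sid),
                                      "dimensionless",
                                      formula = morphometry_formula[["eccentricity"]]),
        image_entropy = quantification("image_entropy",
                                       region_entropy(image, mask, sid),
                                       "bit",
                                       formula = morphometry_formula[["image_entropy"]]))
      attach_quantification(doc, entity_iri, par, q)
      nodes[[length(nodes) + 1L]] <- q
    }
  }
  nodes
}

# find or create the entity's attribute named `name`, then hang `q` off it
attach_quantification <- function(doc, entity_iri, name, q) {
  ind <- get_individual(doc, entity_iri)
  attr_iri <- NULL
  for (t in ind$links$target[ind$links$property == "hasAttribute"]) {
    ti <- get_individual(doc, t)
    if (!is.null(ti$values$name) && ti$values$name[[1]] == name) {
      attr_iri <- t
      break
    }
  }
  if (is.null(attr_iri)) {
    at <- attach_attribute(doc, entity_iri, name, quantifications = list(q))
  } else {
    qi <- new_individual(doc, "Quantification")
    set_value(doc, qi$iri, "parameterName", q$parameter_name)
    set_value(doc, qi$iri, "value", q$value)
    set_value(doc, qi$iri, "unit", q$unit)
    if (!is.null(q$formula)) set_value(doc, qi$iri, "formula", q$formula)
    if (!is.null(q$source)) set_value(doc, qi$iri, "source", q$source)
    add_link(doc, attr_iri, "hasQuantification", qi$iri)
  }
  invisible(NULL)
}

#' Stromal tumor-infiltrating lymphocyte fraction
#'
#' The stromal TILs score: the fraction of the stromal area covered by the
#' lymphocytes it contains. Lymphocyte membership is semantic -- taken from
#' the document's containment links (the [entities_within()] query), not
#' from pixel geometry -- and the areas come from the segmentations. A
#' stroma's region is expected to cover its lymphocytes' pixels (the mask
#' convention lets a stroma segmentation own its lymphocytes' labels); with
#' `clip_to_stroma = TRUE` lymphocyte pixels falling outside the stromal
#' region are discarded instead of counted.
#'
#' @param doc a `histoml_document` with at least one stromal component.
#' @param mask a [label_mask()] resolving the relevant segmentation ids.
#' @param clip_to_stroma intersect lymphocyte pixels with the stromal
#'   region before counting.
#' @return fraction in `[0, 1]`.
#' @export
stromal_tils <- function(doc, mask, clip_to_stroma = FALSE) {
  stroma_iris <- individual_iris(doc, "Stroma")
  if (!length(stroma_iris)) {
    stop("document contains no stromal component individual")
  }
  dims <- dim(mask$labels)
  stroma_px <- matrix(FALSE, dims[1], dims[2])
  lymph_px <- matrix(FALSE, dims[1], dims[2])
  segs <- segmentations_of(doc, stroma_iris)
  lymph_iris <- character(0)
  for (s in stroma_iris) {
    for (sid in segs[[s]]) stroma_px <- stroma_px | region_pixels(mask, sid)
    lymph_iris <- union(lymph_iris, entities_within(doc, s, "Lymphocyte"))
  }
  if (!sum(stroma_px)) stop("stromal area is zero; TILs fraction undefined")
  lsegs <- segmentations_of(doc, lymph_iris)
  for (l in lymph_iris) {
    if (!length(lsegs[[l]])) {
      stop("lymphocyte without segmentation: ", l)
    }
    for (sid in lsegs[[l]]) lymph_px <- lymph_px | region_pixels(mask, sid)
  }
  if (clip_to_stroma) lymph_px <- lymph_px & stroma_px
  sum(lymph_px) / sum(stroma_px)
}
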