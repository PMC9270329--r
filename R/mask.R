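# Label masks and intensity images.
#
# Coordinates are row-major with origin at the top-left, 0-based in the
# on-disk convention; in R the natural 1-based matrix indexing is used
# internally. A label mask is a 2D integer matrix (0 = background) plus an
# id_map from segmentation identifier strings to one or more positive label
# values: the region of a segmentation id is the union of the pixels of its
# label values. Allowing an id to own several labels lets nested
# segmentations share pixels (a stroma that contains lymphocytes covers
# their pixels too) while keeping a single label plane.

#' Construct a label mask
#'
#' @param labels integer matrix, 0 = background, positive values label
#'   regions.
#' @param id_map named list (or vector) mapping segmentation id strings to
#'   positive label values; an id may map to several labels, whose union
#'   forms its region. Every mapped label must occur in `labels`.
#' @param microns_per_pixel optional physical resolution (um/px).
#' @return a `histoml_label_mask` list.
#' @export
label_mask <- function(labels, id_map, microns_per_pixel = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop("labels must be nonnegative")
  id_map <- lapply(id_map, function(v) sort(unique(as.integer(v))))
  if (is.null(names(id_map)) || any(!nzchar(names(id_map)))) {
    stop("id_map must be named by segmentation id")
  }
  present <- sort(unique(labels[labels > 0L]))
  for (sid in names(id_map)) {
    v <- id_map[[sid]]
    if (!length(v) || any(v <= 0L)) {
      stop("id_map['", sid, "'] must contain positive label values")
    }
    if (!all(v %in% present)) {
      stop("segmentation id '", sid, "' maps to label(s) absent from the ",
           "mask: ", paste(setdiff(v, present), collapse = ", "))
    }
  }
  if (!is.null(microns_per_pixel) &&
      (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)) {
    stop("microns_per_pixel must be positive")
  }
  structure(list(labels = labels, id_map = id_map,
                 microns_per_pixel = microns_per_pixel),
            class = "histoml_label_mask")
}

#' @export
print.histoml_label_mask <- function(x, ...) {
  cat("label mask ", nrow(x$labels), "x", ncol(x$labels), " px, ",
      length(x$id_map), " segmentation id(s)\n", sep = "")
  invisible(x)
}

#' Construct an intensity image
#'
#' @param pixels numeric/integer matrix of 8-bit grayscale values (0--255).
#'   RGB arrays are converted by Rec. 601 luminance.
#' @return a `histoml_intensity_image` list.
#' @export
intensity_image <- function(pixels) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
      0.114 * pixels[, , 3]
  }
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  pixels <- round(pixels)
  if (any(pixels < 0 | pixels > 255)) {
    stop("intensity values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "histoml_intensity_image")
}

# logical matrix of the region owned by a segmentation id
region_pixels <- function(mask, seg_id) {
  v <- mask$id_map[[seg_id]]
  if (is.null(v)) {
    stop("unknown segmentation id: '", seg_id, "' (known: ",
         paste(names(mask$id_map), collapse = ", "), ")")
  }
  m <- mask$labels %in% v
  dim(m) <- dim(mask$labels)
  if (!any(m)) stop("segmentation id '", seg_id, "' maps to an empty region")
  m
}

# ---- file I/O --------------------------------------------------------------

#' Write a label mask as PNG plus sidecar JSON
#'
#' The PNG stores the raw 16-bit label values packed into two 8-bit
#' channels (red = high byte, green = low byte); the sidecar JSON holds
#' `id_map` and `microns_per_pixel`.
#'
#' @param mask a `histoml_label_mask`.
#' @param png_path,sidecar_path output paths.
#' @return invisibly, `png_path`.
#' @export
write_mask <- function(mask, png_path,
                       sidecar_path = paste0(tools::file_path_sans_ext(png_path),
                                             ".json")) {
  if (any(mask$labels > 65535L)) stop("labels exceed 16-bit range")
  # 16-bit labels packed into two 8-bit channels: red = high byte,
  # green = low byte (the png writer emits 8 bits per channel)
  arr <- array(0, dim = c(nrow(mask$labels), ncol(mask$labels), 3L))
  arr[, , 1] <- (mask$labels %/% 256L) / 255
  arr[, , 2] <- (mask$labels %% 256L) / 255
  png::writePNG(arr, png_path)
  jsonlite::write_json(
    list(id_map = mask$id_map,
         microns_per_pixel = mask$microns_per_pixel),
    sidecar_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(png_path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param png_path,sidecar_path input paths.
#' @return a `histoml_label_mask`.
#' @export
read_mask <- function(png_path,
                      sidecar_path = paste0(tools::file_path_sans_ext(png_path),
                                            ".json")) {
  raw <- png::readPNG(png_path)
  if (length(dim(raw)) == 3L) {
    labels <- round(raw[, , 1] * 255) * 256L + round(raw[, , 2] * 255)
  } else {
    labels <- round(raw * 255)
  }
  storage.mode(labels) <- "integer"
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  mpp <- side$microns_per_pixel
  if (is.null(mpp) || (length(mpp) == 1L && is.na(mpp))) mpp <- NULL
  label_mask(labels, as.list(side$id_map), mpp)
}

#' Write an intensity image as 8-bit PNG
#' @param image a `histoml_intensity_image`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_image <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read an intensity image from PNG
#' @param path input path.
#' @return a `histoml_intensity_image` (RGB converted by luminance).
#' @export
read_image <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) {
    intensity_image(raw[, , 1:3] * 255)
  } else {
    intensity_image(raw * 255)
  }
}
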