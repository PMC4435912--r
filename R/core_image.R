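#' Construct a calibrated grayscale core image
#'
#' A `core_image` holds the single-channel intensity matrix of one tissue
#' microarray (TMA) core together with its physical pixel calibration and
#' the quality-control metadata used to admit or exclude the core from
#' analysis (focus, tissue folding, tumor cell count).
#'
#' @param pixels integer matrix (>= 2 x 2) of non-negative intensities.
#'   Values must fit the declared bit depth.
#' @param pixel_size_um physical size of one pixel in micrometres
#'   (default 0.468, i.e. a 20x acquisition).
#' @param core_id,patient_id identifiers carried through the pipeline.
#' @param in_focus,not_folded logical QC flags.
#' @param tumor_cell_count non-negative integer; cores with fewer than 100
#'   tumor cells are excluded downstream by [qc_filter()].
#' @param bit_depth 8 or 16; inferred from the data when `NULL`.
#'
#' @return an object of class `core_image`.
#' @export
core_image <- function(pixels, pixel_size_um = 0.468,
                       core_id = "core", patient_id = "patient",
                       in_focus = TRUE, not_folded = TRUE,
                       tumor_cell_count = NA_integer_,
                       bit_depth = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) < 2L || ncol(pixels) < 2L) {
    abort_nfdim("`pixels` must be a matrix with at least 2 rows and 2 columns",
                "nfdim_invalid_parameter")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    abort_nfdim("intensities must be non-negative and non-missing",
                "nfdim_invalid_parameter")
  }
  if (any(pixels != round(pixels))) {
    abort_nfdim("intensities must be integers", "nfdim_invalid_parameter")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort_nfdim("`pixel_size_um` must be a positive number",
                "nfdim_invalid_parameter")
  }
  storage.mode(pixels) <- "integer"
  if (is.null(bit_depth)) bit_depth <- if (max(pixels) <= 255L) 8L else 16L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    abort_nfdim("`bit_depth` must be 8 or 16", "nfdim_invalid_parameter")
  }
  if (max(pixels) > 2^bit_depth - 1L) {
    abort_nfdim("intensities exceed the declared bit depth",
                "nfdim_invalid_parameter")
  }
  structure(
    list(pixels = pixels,
         pixel_size_um = pixel_size_um,
         core_id = as.character(core_id),
         patient_id = as.character(patient_id),
         bit_depth = bit_depth,
         qc = list(in_focus = isTRUE(in_focus),
                   not_folded = isTRUE(not_folded),
                   tumor_cell_count = as.integer(tumor_cell_count))),
    class = "core_image"
  )
}

#' @export
print.core_image <- function(x, ...) {
  cat(sprintf("<core_image> %s (patient %s): %d x %d px, %.3f um/px, %d-bit\n",
              x$core_id, x$patient_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' Read a single-channel grayscale TIFF as a core image
#'
#' Multi-channel images (RGB, alpha) are rejected rather than converted:
#' a color core image indicates an acquisition error. The pixel size is
#' taken from the caller, never from TIFF tags; a conflicting resolution
#' tag is reported with a message.
#'
#' @param path TIFF file path.
#' @inheritParams core_image
#' @param ... passed to [core_image()] (QC flags).
#' @return a `core_image`.
#' @export
read_core_tiff <- function(path, pixel_size_um = 0.468,
                           core_id = NULL, patient_id = NULL, ...) {
  if (!file.exists(path)) {
    abort_nfdim(sprintf("no such file: %s", path), "nfdim_invalid_parameter")
  }
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) != 2L) {
    abort_nfdim(sprintf("%s has %d channels; expected single-channel grayscale",
                        basename(path), dim(img)[3L]),
                "nfdim_invalid_parameter")
  }
  bits <- attr(img, "bits.per.sample")
  xres <- attr(img, "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    tag_um <- 1e4 / xres  # TIFF resolution is usually pixels per cm
    if (abs(tag_um - pixel_size_um) / pixel_size_um > 0.05) {
      message(sprintf("%s: TIFF resolution tag implies %.4f um/px; using supplied %.4f",
                      basename(path), tag_um, pixel_size_um))
    }
  }
  stem <- sub("\\.[^.]+$", "", basename(path))
  if (is.null(core_id)) core_id <- stem
  if (is.null(patient_id)) patient_id <- strsplit(stem, "_", fixed = TRUE)[[1L]][1L]
  m <- matrix(as.integer(img), nrow = nrow(img), ncol = ncol(img))
  core_image(m, pixel_size_um = pixel_size_um, core_id = core_id,
             patient_id = patient_id,
             bit_depth = if (is.null(bits)) NULL else as.integer(bits), ...)
}

#' Write a core image as an uncompressed grayscale TIFF
#'
#' @param image a `core_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_core_tiff <- function(image, path) {
  stopifnot(inherits(image, "core_image"))
  scale <- 2^image$bit_depth - 1L
  tiff::writeTIFF(image$pixels / scale, path,
                  bits.per.sample = image$bit_depth, compression = "none")
  invisible(path)
}
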