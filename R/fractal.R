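#' Threshold a core image into a binary mask
#'
#' A pixel is foreground iff its intensity is greater than or equal to the
#' threshold (inclusive comparison, fixed for bit-exact reproducibility).
#'
#' @param image a [core_image()].
#' @param threshold integer intensity within the image's representable
#'   range (`0 .. 2^bit_depth - 1`).
#' @return a `binary_mask`: list with `bits` (logical matrix, same shape)
#'   and `threshold`.
#' @export
binarize <- function(image, threshold) {
  stopifnot(inherits(image, "core_image"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold != round(threshold)) {
    abort_nfdim("`threshold` must be a single integer", "nfdim_invalid_parameter")
  }
  top <- 2^image$bit_depth - 1
  if (threshold < 0 || threshold > top) {
    abort_nfdim(sprintf("threshold %d outside representable range [0, %d]",
                        as.integer(threshold), as.integer(top)),
                "nfdim_invalid_parameter")
  }
  structure(list(bits = image$pixels >= threshold,
                 threshold = as.integer(threshold)),
            class = "binary_mask")
}

#' Extract the inner boundary of a binary mask
#'
#' The outline is the set of foreground pixels with at least one background
#' 4-neighbor; pixels beyond the image border count as background, so
#' foreground touching the border is part of the outline. The outline is a
#' subset of the mask.
#'
#' @param mask a `binary_mask`.
#' @return a `binary_mask` of the outline (threshold carried over).
#' @export
extract_outline <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  f <- mask$bits
  nr <- nrow(f); nc <- ncol(f)
  bg <- !f
  up    <- rbind(rep(TRUE, nc), bg[-nr, , drop = FALSE])
  down  <- rbind(bg[-1L, , drop = FALSE], rep(TRUE, nc))
  left  <- cbind(rep(TRUE, nr), bg[, -nc, drop = FALSE])
  right <- cbind(bg[, -1L, drop = FALSE], rep(TRUE, nr))
  structure(list(bits = f & (up | down | left | right),
                 threshold = mask$threshold),
            class = "binary_mask")
}

#' Count occupied boxes of an axis-aligned grid over an outline
#'
#' For each box size `s` the image is partitioned into an s x s grid
#' anchored at the image origin (single placement), and the number of grid
#' cells containing at least one outline pixel is recorded. With
#' `offset_min = TRUE` the minimum count over the four grid offsets
#' `{0, floor(s/2)}^2` is taken instead (an optional refinement; the
#' origin-anchored single placement is the default).
#'
#' @param outline a `binary_mask` with at least one foreground pixel.
#' @param box_sizes_px strictly increasing positive integers, each no
#'   larger than the smaller image dimension. Dyadic sizes guarantee the
#'   nested-grid monotonicity of the counts.
#' @param pixel_size_um physical pixel size, used to report box sizes in
#'   micrometres.
#' @param offset_min take the minimum count over four grid offsets.
#' @return a `box_count_curve`: box sizes (px and um), occupied-box counts,
#'   and unset fit fields (`slope`, `intercept`, `r_squared`); pass to
#'   [fit_fd()].
#' @export
box_count <- function(outline, box_sizes_px, pixel_size_um = 0.468,
                      offset_min = FALSE) {
  stopifnot(inherits(outline, "binary_mask"))
  s <- as.integer(box_sizes_px)
  if (length(s) == 0L || any(is.na(s)) || any(s < 1L) || is.unsorted(s, strictly = TRUE)) {
    abort_nfdim("`box_sizes_px` must be strictly increasing positive integers",
                "nfdim_invalid_parameter")
  }
  nr <- nrow(outline$bits); nc <- ncol(outline$bits)
  if (max(s) > min(nr, nc)) {
    abort_nfdim("box sizes must not exceed the smaller image dimension",
                "nfdim_invalid_parameter")
  }
  idx <- which(outline$bits)
  if (length(idx) == 0L) {
    abort_nfdim("outline has no foreground pixels", "nfdim_empty_structure")
  }
  r0 <- (idx - 1L) %% nr   # 0-based row
  c0 <- (idx - 1L) %/% nr  # 0-based column
  count_at <- function(sz, or, oc) {
    ncell_r <- (nr + sz - 1L) %/% sz + 1L  # +1 headroom for offset grids
    cell <- (r0 + or) %/% sz + ((c0 + oc) %/% sz) * ncell_r
    length(unique(cell))
  }
  counts <- vapply(s, function(sz) {
    if (offset_min) {
      offs <- unique(c(0L, sz %/% 2L))
      min(vapply(offs, function(or)
        min(vapply(offs, function(oc) count_at(sz, or, oc), integer(1L))),
        integer(1L)))
    } else {
      count_at(sz, 0L, 0L)
    }
  }, integer(1L))
  if (is.unsorted(rev(counts))) {
    abort_nfdim("occupied-box counts are not non-increasing; use nested (dyadic) box sizes",
                "nfdim_invalid_parameter")
  }
  structure(list(box_sizes_px = s,
                 box_sizes_um = s * pixel_size_um,
                 counts = counts,
                 slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_),
            class = "box_count_curve")
}

#' Fit the box-counting dimension to a count curve
#'
#' Ordinary least squares of `log N(s)` on `log(1/s)` (natural logarithms);
#' the slope is the fractal dimension estimate. At least four scales are
#' required for a meaningful fit.
#'
#' @param curve a `box_count_curve` from [box_count()].
#' @return the curve with `slope`, `intercept` and `r_squared` populated.
#' @export
fit_fd <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  if (length(curve$box_sizes_px) < 4L) {
    abort_nfdim("need at least 4 (size, count) pairs for the log-log fit",
                "nfdim_insufficient_scales")
  }
  if (any(curve$counts < 1L)) {
    abort_nfdim("all counts must be >= 1", "nfdim_invalid_parameter")
  }
  x <- log(1 / curve$box_sizes_px)
  y <- log(curve$counts)
  fit <- stats::lm(y ~ x)
  curve$slope <- unname(stats::coef(fit)[2L])
  curve$intercept <- unname(stats::coef(fit)[1L])
  # summary.lm warns on exact power-law input ("essentially perfect fit")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  curve$r_squared <- if (is.finite(r2)) r2 else 0
  curve
}

#' Default box sizes for a given pixel calibration
#'
#' Returns all power-of-two pixel sizes whose physical extent lies in the
#' 3.5-62 um band appropriate for nuclear-scale structures. At the default
#' calibration of 0.468 um/px this is `{8, 16, 32, 64, 128}` px
#' (3.74-59.9 um).
#'
#' @param pixel_size_um positive pixel size in micrometres.
#' @param band_um physical band (um) the box sizes must span.
#' @return increasing integer vector of box sizes in pixels.
#' @export
default_box_sizes <- function(pixel_size_um = 0.468, band_um = c(3.5, 62)) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort_nfdim("`pixel_size_um` must be positive", "nfdim_invalid_parameter")
  }
  s <- 2^(0:15)
  s <- s[s * pixel_size_um >= band_um[1L] & s * pixel_size_um <= band_um[2L]]
  if (length(s) < 4L) {
    abort_nfdim(sprintf(
      "only %d power-of-two box sizes fit the %.1f-%.1f um band at %.3f um/px; need >= 4",
      length(s), band_um[1L], band_um[2L], pixel_size_um),
      "nfdim_insufficient_scales")
  }
  as.integer(s)
}

#' Estimate the background-noise ceiling of a core image
#'
#' TMA core images place a circular tissue core on a dark field, so the
#' image corners contain pure background. The ceiling is the corner median
#' plus `k` robust standard deviations (MAD-based, falling back to the
#' corner sd for heavily quantized backgrounds): intensities at or below it
#' are indistinguishable from sensor noise.
#'
#' @param image a `core_image`.
#' @param k sigma multiplier (default 5).
#' @param frac corner patch side as a fraction of the image side.
#' @return the ceiling intensity (numeric scalar).
#' @export
noise_ceiling <- function(image, k = 5, frac = 0.05) {
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  m <- max(4L, round(frac * min(nr, nc)))
  corners <- c(px[1:m, 1:m], px[1:m, (nc - m + 1L):nc],
               px[(nr - m + 1L):nr, 1:m], px[(nr - m + 1L):nr, (nc - m + 1L):nc])
  b <- stats::median(corners)
  s <- stats::mad(corners)
  if (s == 0) s <- stats::sd(corners)
  b + k * s
}

#' Default intensity-threshold series for a core image
#'
#' 64 equally spaced integer levels strictly between the image's 1st and
#' 99th intensity percentiles (duplicates removed); percentile anchoring
#' adapts to 8- and 16-bit dynamic ranges. Two amendments keep the series
#' usable on real material: (i) the lower anchor is raised to the
#' background [noise_ceiling()] whenever that still leaves at least 8
#' levels -- thresholds inside the sensor-noise band binarize pure speckle,
#' whose outline is space-filling at every scale and would dominate the
#' global maximum regardless of tissue structure; (ii) when the percentile
#' band is degenerate (e.g. sparse binary fixtures where both percentiles
#' equal the background level) the band falls back to the full observed
#' intensity range. A constant image has no usable thresholds.
#'
#' @param image a `core_image`.
#' @param n number of levels requested (default 64).
#' @return increasing integer vector of thresholds.
#' @export
default_thresholds <- function(image, n = 64L) {
  stopifnot(inherits(image, "core_image"))
  px <- image$pixels
  band <- stats::quantile(px, c(0.01, 0.99), names = FALSE, type = 1)
  levels_in <- function(lo, hi) {
    if (hi - lo < 2) return(integer(0L))
    v <- unique(as.integer(round(seq(lo, hi, length.out = n + 2L))))
    v[v > lo & v < hi]
  }
  pick <- function(lo, hi) {
    floor_lo <- noise_ceiling(image)
    if (floor_lo > lo) {
      raised <- levels_in(floor_lo, hi)
      if (length(raised) >= 8L) return(raised)
    }
    levels_in(lo, hi)
  }
  th <- pick(band[1L], band[2L])
  if (length(th) == 0L) th <- pick(min(px), max(px))
  if (length(th) == 0L) {
    abort_nfdim("image has no usable intensity range (constant image?)",
                "nfdim_no_signal")
  }
  th
}

#' Sweep intensity thresholds and score the nuclear fractal dimension
#'
#' For each threshold the image is binarized, the nuclear outlines are
#' extracted, and the box-counting dimension of the outline image is
#' fitted. The nFD score of the core is the global maximum of the
#' fractal-dimension-versus-threshold curve; at ties the smallest
#' threshold attaining the maximum is reported. Thresholds producing an
#' empty outline, or a flat count curve (the occupied count at the largest
#' box size equals the count at the smallest), carry no scaling information
#' and are skipped. Thresholds yielding identical foreground sets are
#' evaluated once and share their fit.
#'
#' @param image a `core_image`.
#' @param thresholds integer thresholds; default [default_thresholds()].
#' @param box_sizes_px box sizes; default [default_box_sizes()] filtered to
#'   the image extent (at least 4 must remain).
#' @param offset_min see [box_count()].
#' @return a `threshold_sweep`: `thresholds` and `fd_values` for every
#'   fitted threshold, `curves` (one `box_count_curve` each), `skipped`
#'   (data frame of threshold and reason), `nfd`, `argmax_threshold`, and
#'   `min_r_squared`.
#' @export
sweep_nfd <- function(image, thresholds = NULL, box_sizes_px = NULL,
                      offset_min = FALSE) {
  stopifnot(inherits(image, "core_image"))
  if (is.null(thresholds)) thresholds <- default_thresholds(image)
  thresholds <- sort(unique(as.integer(thresholds)))
  if (length(thresholds) == 0L) {
    abort_nfdim("empty threshold series", "nfdim_invalid_parameter")
  }
  if (is.null(box_sizes_px)) {
    box_sizes_px <- default_box_sizes(image$pixel_size_um)
    box_sizes_px <- box_sizes_px[box_sizes_px <= min(dim(image$pixels))]
  }
  if (length(box_sizes_px) < 4L) {
    abort_nfdim("fewer than 4 box sizes fit inside the image",
                "nfdim_insufficient_scales")
  }

  # thresholds with equal foreground counts produce identical masks
  # (masks are nested along the threshold axis), so fit each mask once
  sorted_px <- sort(as.vector(image$pixels))
  n_px <- length(sorted_px)
  n_fg <- n_px - findInterval(thresholds - 0.5, sorted_px)
  groups <- split(seq_along(thresholds), n_fg)

  fit_thr <- integer(0L); fds <- numeric(0L); curves <- list()
  skip_thr <- integer(0L); skip_reason <- character(0L)
  skip_all <- function(idx, reason) {
    skip_thr <<- c(skip_thr, thresholds[idx])
    skip_reason <<- c(skip_reason, rep(reason, length(idx)))
  }
  for (g in groups) {
    t_rep <- thresholds[g[1L]]
    if (n_fg[g[1L]] == 0L) { skip_all(g, "empty mask"); next }
    outline <- extract_outline(binarize(image, t_rep))
    if (!any(outline$bits)) { skip_all(g, "empty outline"); next }
    curve <- box_count(outline, box_sizes_px, image$pixel_size_um,
                       offset_min = offset_min)
    k <- length(curve$counts)
    if (curve$counts[1L] == curve$counts[k]) {
      skip_all(g, "degenerate counts"); next
    }
    curve <- fit_fd(curve)
    fit_thr <- c(fit_thr, thresholds[g])
    fds <- c(fds, rep(curve$slope, length(g)))
    curves <- c(curves, rep(list(curve), length(g)))
  }
  if (length(fit_thr) == 0L) {
    abort_nfdim("no threshold yields a valid box-counting fit",
                "nfdim_no_signal")
  }
  ord <- order(fit_thr)
  fit_thr <- fit_thr[ord]; fds <- fds[ord]; curves <- curves[ord]
  nfd <- max(fds)
  if (nfd < 0 || nfd > 2.2) {
    abort_nfdim(sprintf("nFD %.3f outside the planar-outline sanity band [0, 2.2]",
                        nfd), "nfdim_no_signal")
  }
  min_r2 <- min(vapply(curves, `[[`, numeric(1L), "r_squared"))
  if (min_r2 < 0.95) {
    message(sprintf("core %s: weakest log-log fit has r^2 = %.3f (< 0.95)",
                    image$core_id, min_r2))
  }
  structure(
    list(thresholds = fit_thr,
         fd_values = fds,
         nfd = nfd,
         argmax_threshold = fit_thr[which.max(fds)],
         curves = curves,
         skipped = data.frame(threshold = skip_thr, reason = skip_reason,
                              stringsAsFactors = FALSE),
         min_r_squared = min_r2,
         core_id = image$core_id,
         patient_id = image$patient_id),
    class = "threshold_sweep"
  )
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> core %s: nFD = %.4f at threshold %d (%d fitted, %d skipped)\n",
              x$core_id, x$nfd, x$argmax_threshold,
              length(x$thresholds), nrow(x$skipped)))
  invisible(x)
}

#' Nuclear fractal dimension of a core image
#'
#' Convenience wrapper: [sweep_nfd()] with default thresholds and box
#' sizes, returning only the nFD score.
#'
#' @param image a `core_image`.
#' @param ... passed to [sweep_nfd()].
#' @return the nFD score (numeric scalar).
#' @export
core_nfd <- function(image, ...) {
  sweep_nfd(image, ...)$nfd
}
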