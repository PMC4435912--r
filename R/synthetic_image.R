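#' Configuration for a synthetic DAPI-like core image
#'
#' Defaults emulate the acquisition geometry of a fluorescently imaged
#' 0.6 mm TMA core at 20x: a 1280 px field at 0.468 um/px, a circular core
#' footprint of 0.94 x the field width, elliptical nuclei with ~3.5 um mean
#' semi-axes, optical blur and additive sensor noise.
#'
#' @param size_px square field side in pixels (>= 256).
#' @param pixel_size_um pixel calibration (um/px).
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param placement `"thomas_cluster"` (Gaussian clusters around Poisson
#'   parents -- the default, emulating tumor nests and stromal bands),
#'   `"uniform_poisson"` (uniform in the footprint), or
#'   `"prefractal_support"` (nucleus centres restricted to a Sierpinski
#'   carpet support, giving the nucleus point set a controllable support
#'   dimension).
#' @param nucleus_axes_um mean and sd of the nucleus ellipse semi-axes (um).
#' @param peak_intensity,background_level integer intensity levels
#'   (`peak_intensity > background_level >= 0`).
#' @param blur_sigma_px Gaussian optical blur sigma (px; 0 disables).
#' @param noise_sd additive truncated-Gaussian noise sd (intensity units).
#' @param cluster_sd_um Thomas-process cluster spread (um).
#' @param nuclei_per_cluster mean offspring per Thomas parent.
#' @param support_iterations carpet iteration depth for
#'   `prefractal_support`.
#' @param seed integer RNG seed; identical configs render bit-identical
#'   images.
#' @return a validated `synthetic_image_config` list.
#' @export
synthetic_image_config <- function(size_px = 1280L, pixel_size_um = 0.468,
                                   n_nuclei = 1500L,
                                   placement = c("thomas_cluster",
                                                 "uniform_poisson",
                                                 "prefractal_support"),
                                   nucleus_axes_um = c(3.5, 0.8),
                                   peak_intensity = 220L,
                                   background_level = 8L,
                                   blur_sigma_px = 1.2,
                                   noise_sd = 2,
                                   cluster_sd_um = 15,
                                   nuclei_per_cluster = 25,
                                   support_iterations = 3L,
                                   seed = 1L) {
  placement <- match.arg(placement)
  cfg <- list(size_px = as.integer(size_px), pixel_size_um = pixel_size_um,
              n_nuclei = as.integer(n_nuclei), placement = placement,
              nucleus_axes_um = as.numeric(nucleus_axes_um),
              peak_intensity = as.integer(peak_intensity),
              background_level = as.integer(background_level),
              blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
              cluster_sd_um = cluster_sd_um,
              nuclei_per_cluster = nuclei_per_cluster,
              support_iterations = as.integer(support_iterations),
              seed = as.integer(seed))
  if (cfg$size_px < 256L) {
    abort_nfdim("`size_px` must be >= 256", "nfdim_invalid_parameter")
  }
  if (cfg$n_nuclei < 0L) {
    abort_nfdim("`n_nuclei` must be >= 0", "nfdim_invalid_parameter")
  }
  if (!(cfg$peak_intensity > cfg$background_level &&
        cfg$background_level >= 0L)) {
    abort_nfdim("need peak_intensity > background_level >= 0",
                "nfdim_invalid_parameter")
  }
  if (cfg$pixel_size_um <= 0 || cfg$nucleus_axes_um[1L] <= 0) {
    abort_nfdim("pixel size and nucleus axes must be positive",
                "nfdim_invalid_parameter")
  }
  structure(cfg, class = "synthetic_image_config")
}

# carpet membership test in the unit square (continuous coordinates)
in_carpet <- function(u, v, iterations) {
  keep <- rep(TRUE, length(u))
  for (k in seq_len(iterations)) {
    du <- floor(u * 3^k) %% 3
    dv <- floor(v * 3^k) %% 3
    keep <- keep & !(du == 1 & dv == 1)
  }
  keep
}

#' Render a synthetic DAPI-like core image
#'
#' Nuclei are placed by the configured point process inside the circular
#' core footprint, rendered as intensity ellipses with Gaussian falloff
#' (max-composited, so touching nuclei overlap like real DAPI cores),
#' blurred, and corrupted with additive truncated-Gaussian noise. Pixels
#' outside the footprint are set to the background level. The same config
#' (including seed) renders a bit-identical image.
#'
#' @param config a [synthetic_image_config()].
#' @param core_id,patient_id identifiers for the resulting image.
#' @return a list with `image` (a `core_image`) and `truth` (placement
#'   type, nucleus centres, and the support dimension of the placement
#'   process where defined). The truth object is for generator-side
#'   validation only and is never consumed by the analysis modules.
#' @export
render_core <- function(config = synthetic_image_config(),
                        core_id = "synthetic_core",
                        patient_id = "synthetic_patient") {
  stopifnot(inherits(config, "synthetic_image_config"))
  n <- config$size_px
  ctr <- (n + 1) / 2
  R <- 0.47 * n
  a_px <- config$nucleus_axes_um[1L] / config$pixel_size_um
  if (config$n_nuclei * pi * a_px^2 > 1.5 * pi * R^2) {
    abort_nfdim("requested nuclei exceed the 50% overlap budget of the core footprint",
                "nfdim_placement_failure")
  }

  with_seed(config$seed, {
    k <- config$n_nuclei
    if (k > 0L) {
      draw_uniform <- function(m) {
        # uniform in the footprint disk
        r <- R * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        cbind(ctr + r * cos(th), ctr + r * sin(th))
      }
      if (config$placement == "uniform_poisson") {
        pts <- draw_uniform(k)
      } else if (config$placement == "thomas_cluster") {
        n_par <- max(1L, round(k / config$nuclei_per_cluster))
        parents <- draw_uniform(n_par)
        sd_px <- config$cluster_sd_um / config$pixel_size_um
        pts <- matrix(NA_real_, 0L, 2L)
        while (nrow(pts) < k) {
          pid <- sample.int(n_par, k, replace = TRUE)
          cand <- parents[pid, , drop = FALSE] +
            matrix(stats::rnorm(2L * k, 0, sd_px), ncol = 2L)
          ok <- (cand[, 1L] - ctr)^2 + (cand[, 2L] - ctr)^2 <= R^2
          pts <- rbind(pts, cand[ok, , drop = FALSE])
        }
        pts <- pts[seq_len(k), , drop = FALSE]
      } else { # prefractal_support: carpet membership + footprint
        pts <- matrix(NA_real_, 0L, 2L)
        while (nrow(pts) < k) {
          u <- stats::runif(k); v <- stats::runif(k)
          ok <- in_carpet(u, v, config$support_iterations)
          cand <- cbind(1 + u * (n - 1), 1 + v * (n - 1))
          ok <- ok & (cand[, 1L] - ctr)^2 + (cand[, 2L] - ctr)^2 <= R^2
          pts <- rbind(pts, cand[ok, , drop = FALSE])
        }
        pts <- pts[seq_len(k), , drop = FALSE]
      }
    } else {
      pts <- matrix(NA_real_, 0L, 2L)
    }

    img <- matrix(0, n, n)
    if (k > 0L) {
      ax <- pmax(config$nucleus_axes_um[2L] *
                   stats::rnorm(k) + config$nucleus_axes_um[1L], 1.2) /
        config$pixel_size_um
      bx <- pmax(config$nucleus_axes_um[2L] *
                   stats::rnorm(k) + config$nucleus_axes_um[1L], 1.2) /
        config$pixel_size_um
      phi <- stats::runif(k, 0, pi)
      for (i in seq_len(k)) {
        w <- ceiling(2.2 * max(ax[i], bx[i]))
        r0 <- round(pts[i, 1L]); c0 <- round(pts[i, 2L])
        rr <- max(1L, r0 - w):min(n, r0 + w)
        cc <- max(1L, c0 - w):min(n, c0 + w)
        dr <- rr - pts[i, 1L]; dc <- cc - pts[i, 2L]
        xr <- outer(dr, dc * 0, "+") * cos(phi[i]) +
          outer(dr * 0, dc, "+") * sin(phi[i])
        yr <- -outer(dr, dc * 0, "+") * sin(phi[i]) +
          outer(dr * 0, dc, "+") * cos(phi[i])
        m2 <- (xr / ax[i])^2 + (yr / bx[i])^2
        patch <- config$peak_intensity * exp(-m2 / 0.36)
        img[rr, cc] <- pmax(img[rr, cc], patch)
      }
    }
    img <- img + config$background_level
    if (config$blur_sigma_px > 0) {
      img <- EBImage::gblur(img, sigma = config$blur_sigma_px)
    }
    # no tissue outside the circular core footprint; sensor noise covers
    # the whole field
    outside <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") > R^2
    img[outside] <- config$background_level
    if (config$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, config$noise_sd)
    }
    top <- if (config$peak_intensity <= 255L) 255L else 65535L
    img <- matrix(pmin(pmax(round(img), 0), top), n, n)

    truth <- list(placement = config$placement,
                  n_nuclei = k,
                  centers = pts,
                  support_dimension = switch(
                    config$placement,
                    prefractal_support = log(8) / log(3),
                    uniform_poisson = 2,
                    thomas_cluster = NA_real_),
                  seed = config$seed)
    image <- core_image(matrix(as.integer(img), n, n),
                        pixel_size_um = config$pixel_size_um,
                        core_id = core_id, patient_id = patient_id,
                        tumor_cell_count = k)
    list(image = image, truth = truth)
  })
}
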