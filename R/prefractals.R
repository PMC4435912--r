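#' Render an analytic prefractal calibration fixture
#'
#' Deterministic binary images (foreground 255, background 0) of structures
#' with known limiting box-counting dimension, used to calibrate the nFD
#' estimator: a straight line (dimension 1), a circle (`disk_outline`,
#' dimension 1), a Koch curve (log 4 / log 3 ~ 1.2619) and a Sierpinski
#' carpet (log 8 / log 3 ~ 1.8928).
#'
#' @param kind one of `"line"`, `"koch_curve"`, `"sierpinski_carpet"`,
#'   `"disk_outline"`.
#' @param iterations prefractal iteration depth (ignored for line and
#'   disk). The carpet requires `size_px` divisible by `3^iterations`.
#' @param size_px image side length in pixels.
#' @param pixel_size_um pixel calibration carried into the image.
#' @return a `core_image` with an attribute `target_dimension` giving the
#'   limiting dimension of the rendered structure.
#' @export
render_prefractal <- function(kind = c("line", "koch_curve",
                                       "sierpinski_carpet", "disk_outline"),
                              iterations = 4L, size_px = 729L,
                              pixel_size_um = 0.468) {
  kind <- match.arg(kind)
  n <- as.integer(size_px)
  if (n < 64L) abort_nfdim("`size_px` must be >= 64", "nfdim_invalid_parameter")
  iterations <- as.integer(iterations)
  if (iterations < 0L) {
    abort_nfdim("`iterations` must be >= 0", "nfdim_invalid_parameter")
  }
  m <- matrix(0L, n, n)
  target <- 1

  if (kind == "line") iterations <- 0L
  if (kind == "disk_outline") {
    ctr <- (n + 1) / 2
    r <- 0.42 * n
    d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
    m[abs(d - r) <= 0.75] <- 255L
  } else if (kind == "sierpinski_carpet") {
    if (iterations > 0L && n %% 3L^iterations != 0L) {
      abort_nfdim(sprintf("carpet needs size_px divisible by 3^%d", iterations),
                  "nfdim_invalid_parameter")
    }
    hole <- matrix(FALSE, n, n)
    pos <- 0:(n - 1L)
    for (k in seq_len(iterations)) {
      dig <- (pos * 3L^k) %/% n %% 3L
      mid <- dig == 1L
      hole <- hole | outer(mid, mid, "&")
    }
    m[!hole] <- 255L
    target <- log(8) / log(3)
  } else { # koch_curve; a line is a Koch curve at iteration 0
    pts <- c(0 + 0i, 1 + 0i)
    rot <- exp(1i * pi / 3)
    for (k in seq_len(iterations)) {
      a <- pts[-length(pts)]; b <- pts[-1L]
      d <- (b - a) / 3
      seg <- rbind(a, a + d, a + d + d * rot, a + 2 * d)
      pts <- c(as.vector(seg), pts[length(pts)])
    }
    if (iterations > 0L) target <- log(4) / log(3)
    margin <- max(6L, round(0.04 * n))
    scale <- n - 2L * margin
    x <- margin + Re(pts) * scale
    # bump points "up" (towards row 1); baseline sits low in the image
    y <- round(0.78 * n) - Im(pts) * scale
    a <- complex(real = x[-length(x)], imaginary = y[-length(y)])
    b <- complex(real = x[-1L], imaginary = y[-1L])
    for (i in seq_along(a)) {
      len <- Mod(b[i] - a[i])
      t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4) + 1L))
      xi <- pmin(pmax(round(Re(a[i]) + t * Re(b[i] - a[i])), 1L), n)
      yi <- pmin(pmax(round(Im(a[i]) + t * Im(b[i] - a[i])), 1L), n)
      m[cbind(yi, xi)] <- 255L
    }
  }
  img <- core_image(m, pixel_size_um = pixel_size_um,
                    core_id = paste0("prefractal_", kind),
                    patient_id = "fixture", tumor_cell_count = 1000L)
  attr(img, "target_dimension") <- target
  img
}
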