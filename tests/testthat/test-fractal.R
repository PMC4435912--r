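make_image <- function(m, psz = 0.468) {
  core_image(m, pixel_size_um = psz, core_id = "t", patient_id = "t",
             tumor_cell_count = 500L)
}

test_that("binarize is inclusive at the threshold and validates its range", {
  img <- make_image(matrix(10L, 4, 4))
  expect_true(all(binarize(img, 10L)$bits))
  expect_false(any(binarize(img, 11L)$bits))

  chk <- matrix(0L, 8, 8)
  chk[(row(chk) + col(chk)) %% 2L == 0L] <- 255L
  imgc <- make_image(chk)
  expect_identical(binarize(imgc, 128L)$bits, chk == 255L)

  expect_error(binarize(img, 300L), class = "nfdim_invalid_parameter")
  expect_error(binarize(img, -1L), class = "nfdim_invalid_parameter")
})

test_that("outline is the inner 4-connected boundary and a subset of the mask", {
  img <- make_image(matrix(0L, 6, 6))
  expect_false(any(extract_outline(binarize(img, 1L))$bits))

  one <- matrix(0L, 6, 6); one[3, 4] <- 255L
  o <- extract_outline(binarize(make_image(one), 1L))
  expect_identical(o$bits, one == 255L)

  sq <- matrix(0L, 12, 12); sq[2:11, 2:11] <- 255L
  o <- extract_outline(binarize(make_image(sq), 1L))
  expect_equal(sum(o$bits), 36L)  # 4 * 10 - 4 perimeter pixels
  inner <- o$bits[3:10, 3:10]
  expect_false(any(inner))

  set.seed(11)
  for (i in 1:5) {
    m <- matrix(as.integer(runif(400) > 0.6) * 255L, 20, 20)
    msk <- binarize(make_image(m), 1L)
    o <- extract_outline(msk)
    expect_true(all(msk$bits[o$bits]))
  }
})

test_that("box counting matches the definition on closed-form cases", {
  full <- binarize(make_image(matrix(255L, 64, 64)), 1L)
  expect_equal(box_count(full, c(8L, 16L, 32L, 64L))$counts[1], 64L)

  one <- matrix(0L, 64, 64); one[17, 42] <- 255L
  expect_equal(box_count(binarize(make_image(one), 1L),
                         c(4L, 8L, 16L, 32L))$counts,
               rep(1L, 4))

  ln <- matrix(0L, 64, 64); ln[10, 1:64] <- 255L
  expect_equal(box_count(binarize(make_image(ln), 1L),
                         c(8L, 16L, 32L, 64L))$counts,
               c(8L, 4L, 2L, 1L))

  empty <- binarize(make_image(matrix(0L, 8, 8)), 1L)
  expect_error(box_count(empty, c(1L, 2L, 4L, 8L)),
               class = "nfdim_empty_structure")
})

test_that("box counts equal a brute-force double-loop oracle on small images", {
  set.seed(42)
  shapes <- list(c(64L, 64L), c(40L, 64L), c(33L, 57L))
  for (sh in shapes) {
    for (dens in c(0.02, 0.3, 0.9)) {
      m <- matrix(as.integer(runif(prod(sh)) < dens) * 255L, sh[1], sh[2])
      if (!any(m > 0)) m[1, 1] <- 255L
      msk <- binarize(make_image(m), 1L)
      sizes <- c(1L, 2L, 4L, 8L, 16L, 32L)
      sizes <- sizes[sizes <= min(sh)]
      got <- box_count(msk, sizes)$counts
      want <- vapply(sizes, function(s) box_count_oracle(msk$bits, s),
                     integer(1))
      expect_identical(got, want)
      # grid bound
      expect_true(all(got <= ceiling(sh[1] / sizes) * ceiling(sh[2] / sizes)))
    }
  }
})

test_that("log-log fit recovers exact power laws and matches a closed-form OLS oracle", {
  s <- c(8L, 16L, 32L, 64L)
  c1 <- structure(list(box_sizes_px = s, box_sizes_um = s * 0.468,
                       counts = as.integer(64 / s), slope = NA_real_,
                       intercept = NA_real_, r_squared = NA_real_),
                  class = "box_count_curve")
  f1 <- fit_fd(c1)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)

  c2 <- c1; c2$counts <- as.integer((64 / s)^2)
  expect_equal(fit_fd(c2)$slope, 2, tolerance = 1e-12)

  c3 <- c1; c3$counts <- c(100L, 37L, 14L, 5L)
  want <- ols_oracle(log(1 / s), log(c3$counts))
  f3 <- fit_fd(c3)
  expect_equal(f3$slope, want$slope, tolerance = 1e-12)
  expect_equal(f3$intercept, want$intercept, tolerance = 1e-12)
  expect_equal(f3$r_squared, want$r_squared, tolerance = 1e-12)

  c4 <- c1; c4$box_sizes_px <- s[1:3]; c4$counts <- c(8L, 4L, 2L)
  expect_error(fit_fd(c4), class = "nfdim_insufficient_scales")
})

test_that("default box sizes span the physical band and scale with calibration", {
  expect_identical(default_box_sizes(0.468), c(8L, 16L, 32L, 64L, 128L))
  expect_identical(default_box_sizes(0.936), c(4L, 8L, 16L, 32L, 64L))
  expect_error(default_box_sizes(10), class = "nfdim_insufficient_scales")
})

test_that("default thresholds sit strictly inside the intensity band", {
  grad <- matrix(rep(0:255, length.out = 256 * 256), 256, 256)
  img <- make_image(grad)
  th <- default_thresholds(img)
  q <- quantile(grad, c(0.01, 0.99), type = 1)
  expect_true(all(th > q[1] & th < q[2]))
  expect_true(all(diff(th) > 0))

  # core-like image with dark corners: the series clears the noise band
  rc <- render_core(synthetic_image_config(size_px = 320L, n_nuclei = 90L,
                                           seed = 2L))
  thc <- default_thresholds(rc$image)
  expect_true(all(thc > noise_ceiling(rc$image)))

  # sparse binary image: percentile band is degenerate, falls back to range
  sp <- matrix(0L, 128, 128); sp[64, 10:110] <- 255L
  th2 <- default_thresholds(make_image(sp))
  expect_true(length(th2) > 0 && all(th2 > 0 & th2 < 255))

  expect_error(default_thresholds(make_image(matrix(7L, 16, 16))),
               class = "nfdim_no_signal")
})

test_that("sweep satisfies its structural invariants on a synthetic core", {
  rc <- render_core(synthetic_image_config(size_px = 384L, n_nuclei = 150L,
                                           seed = 5L))
  sw <- suppressMessages(sweep_nfd(rc$image))
  expect_equal(sw$nfd, max(sw$fd_values))
  expect_equal(sw$argmax_threshold, min(sw$thresholds[sw$fd_values == sw$nfd]))
  expect_true(sw$nfd > 1.0 && sw$nfd < 2.2)
  for (cv in sw$curves) {
    expect_true(all(diff(cv$counts) <= 0))
    dims <- dim(rc$image$pixels)
    expect_true(all(cv$counts <= ceiling(dims[1] / cv$box_sizes_px) *
                      ceiling(dims[2] / cv$box_sizes_px)))
  }
  expect_error(sweep_nfd(make_image(matrix(0L, 256, 256))),
               class = "nfdim_no_signal")
})

test_that("nFD is robust to small translations and exact under 90-degree rotation", {
  for (img in list(render_prefractal("disk_outline", size_px = 512L),
                   render_prefractal("sierpinski_carpet", iterations = 5L,
                                     size_px = 486L))) {
    base <- core_nfd(img)
    n <- nrow(img$pixels)
    shifted <- matrix(0L, n, n)
    shifted[4:n, 6:n] <- img$pixels[1:(n - 3), 1:(n - 5)]
    expect_lt(abs(core_nfd(make_image(shifted)) - base), 0.05)
  }

  # 512 is divisible by every default box size, so the origin-anchored
  # grid maps onto itself under 90-degree rotation
  disk <- render_prefractal("disk_outline", size_px = 512L)
  rot <- t(disk$pixels)[, 512:1]
  expect_lt(abs(core_nfd(make_image(rot)) - core_nfd(disk)), 1e-9)
})

test_that("estimator is calibrated on structures of known dimension", {
  expect_lt(abs(core_nfd(render_prefractal("line", size_px = 729L)) - 1.0),
            0.05)
  expect_lt(abs(core_nfd(render_prefractal("disk_outline", size_px = 729L)) - 1.0),
            0.07)
  expect_lt(abs(core_nfd(render_prefractal("koch_curve", iterations = 5L,
                                           size_px = 729L)) - log(4) / log(3)),
            0.08)
  # carpet rendered deep enough that its finest holes resolve below the
  # smallest box size (see the methods vignette on truncation)
  expect_lt(abs(core_nfd(render_prefractal("sierpinski_carpet", iterations = 5L,
                                           size_px = 729L)) - log(8) / log(3)),
            0.08)
})
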