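test_that("5-year DSS preparation caps time and censors correctly", {
  p <- data.frame(patient_id = c("a", "b", "c"),
                  time_months = c(70, 12, 30),
                  dss_event = c(TRUE, TRUE, FALSE))
  d <- prepare_dss(p)
  expect_equal(d$time_months, c(60, 12, 30))
  expect_equal(d$event, c(FALSE, TRUE, FALSE))  # disease death at 70 -> censored at 60

  bad <- data.frame(patient_id = "x", time_months = 0, dss_event = TRUE)
  expect_error(prepare_dss(bad), class = "nfdim_invalid_record")
})

test_that("Kaplan-Meier estimator matches hand computations", {
  k1 <- km_estimate(dss_frame(5, TRUE))
  expect_equal(k1$survival, c(1, 0))
  expect_equal(k1$time, c(0, 5))

  k2 <- km_estimate(dss_frame(c(5, 10), c(TRUE, TRUE)))
  expect_equal(k2$survival, c(1, 0.5, 0))

  # censoring at 4 leaves a risk set of 1 at the event time 5
  k3 <- km_estimate(dss_frame(c(4, 5), c(FALSE, TRUE)))
  expect_equal(k3$survival[k3$time == 5], 0)

  expect_error(km_estimate(dss_frame(numeric(0), logical(0))),
               class = "nfdim_empty_input")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  t <- sort(round(rexp(40, 0.05), 1))
  k <- km_estimate(dss_frame(t, TRUE))
  for (i in seq_along(k$time)) {
    expect_equal(k$survival[i], mean(t > k$time[i]))
  }
})

test_that("log-rank matches an explicit O-E tabulation and is symmetric", {
  a <- dss_frame(c(1, 2, 3), TRUE)
  b <- dss_frame(c(11, 12, 13), TRUE)
  lr <- logrank(a, b)
  expect_equal(lr$chi_square,
               logrank_oracle(a$time_months, rep(1, 3), b$time_months, rep(1, 3)),
               tolerance = 1e-9)
  expect_equal(lr$chi_square, logrank(b, a)$chi_square, tolerance = 1e-12)

  same <- dss_frame(c(3, 8, 15, 20), c(TRUE, FALSE, TRUE, TRUE))
  lr0 <- logrank(same, same)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  set.seed(8)
  for (i in 1:5) {
    a <- dss_frame(round(rexp(25, 0.03), 2), runif(25) < 0.7)
    b <- dss_frame(round(rexp(30, 0.05), 2), runif(30) < 0.7)
    lr <- logrank(a, b)
    expect_equal(lr$chi_square,
                 logrank_oracle(a$time_months, a$event, b$time_months, b$event),
                 tolerance = 1e-9)
    expect_true(lr$p_value > 0 && lr$p_value <= 1)
  }

  expect_error(logrank(a, dss_frame(numeric(0), logical(0))),
               class = "nfdim_degenerate_group")
})

test_that("Cox fit: null effect, coding inversion, and score/log-rank agreement", {
  set.seed(4)
  base <- dss_frame(round(rexp(60, 0.02), 3), runif(60) < 0.8)
  two <- rbind(cbind(base, g = 0), cbind(base, g = 1))
  fit <- cox_fit(two, "g")
  expect_equal(fit$table$hazard_ratio, 1, tolerance = 1e-6)

  d <- dss_frame(round(rexp(80, 0.02), 4), TRUE)
  d$x <- rep(0:1, 40)
  d$time_months <- d$time_months * ifelse(d$x == 1, 2, 1)
  hr_x <- cox_fit(d, "x")$table$hazard_ratio
  d$xr <- 1 - d$x
  expect_equal(cox_fit(d, "xr")$table$hazard_ratio, 1 / hr_x,
               tolerance = 1e-6)

  # no tied event times: Cox score test equals the log-rank chi-square
  sc <- summary(cox_fit(d, "x")$model)$sctest[["test"]]
  lr <- logrank(d[d$x == 0, ], d[d$x == 1, ])$chi_square
  expect_equal(sc, lr, tolerance = 1e-6)
})

test_that("Cox fit recovers a binary HR 0.5 with nominal CI coverage", {
  set.seed(12)
  one_rep <- function() {
    n <- 1000L
    x <- rep(0:1, n / 2)
    t_event <- rexp(n, 0.01 * 0.5^x)
    cens <- pmin(rexp(n, 0.002), 60)
    d <- dss_frame(pmin(t_event, cens), t_event <= cens)
    d$x <- x
    cox_fit(d, "x")$table
  }
  first <- one_rep()
  expect_gte(first$hazard_ratio, 0.42)
  expect_lte(first$hazard_ratio, 0.60)

  cover <- replicate(100, {
    tb <- one_rep()
    tb$ci_low <= 0.5 && 0.5 <= tb$ci_high
  })
  expect_gte(mean(cover), 0.90)
})

test_that("multivariate Cox recovers three independent binary effects", {
  set.seed(9)
  n <- 1500L
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5); x3 <- rbinom(n, 1, 0.5)
  rate <- 0.01 * 0.2^x1 * 2^x2 * 2^x3
  t_event <- rexp(n, rate)
  d <- dss_frame(pmin(t_event, 60), t_event <= 60)
  d$x1 <- x1; d$x2 <- x2; d$x3 <- x3
  tab <- cox_fit(d, c("x1", "x2", "x3"))$table
  truth <- c(0.2, 2, 2)
  expect_true(all(abs(tab$hazard_ratio - truth) / truth <= 0.25))
  expect_true(all(tab$ci_low <= tab$hazard_ratio &
                    tab$hazard_ratio <= tab$ci_high))
})

test_that("Cox fit raises classed errors on degenerate inputs", {
  few <- dss_frame(c(1:5), c(TRUE, rep(FALSE, 4)))
  few$x <- rep(0:1, length.out = 5)
  expect_error(cox_fit(few, "x"), class = "nfdim_invalid_parameter")

  # complete separation: all events in one group, before any censoring
  sep <- dss_frame(c(1:20, 41:60), c(rep(TRUE, 20), rep(FALSE, 20)))
  sep$x <- rep(0:1, each = 20)
  expect_error(cox_fit(sep, "x"), class = "nfdim_monotone_likelihood")

  expect_error(cox_fit(few, "nope"), class = "nfdim_invalid_name")
})

test_that("hazard reduction percentage is 100 * (1 - HR)", {
  expect_equal(hazard_reduction_percent(0.09), 91)
  expect_equal(hazard_reduction_percent(1), 0)
  expect_error(hazard_reduction_percent(0), class = "nfdim_invalid_parameter")
})
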