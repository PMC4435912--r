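cores_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("QC drops out-of-focus, folded and tumor-poor cores with reasons", {
  cores <- cores_df(
    core_id = c("a", "b", "c", "d"),
    patient_id = "p1",
    nfd = c(1.5, 1.6, 1.4, 1.7),
    in_focus = c(TRUE, FALSE, TRUE, TRUE),
    not_folded = c(TRUE, TRUE, FALSE, TRUE),
    tumor_cell_count = c(99L, 500L, 500L, 100L)
  )
  r <- qc_filter(cores)
  expect_identical(r$kept$core_id, "d")  # count 100 is the kept boundary
  expect_setequal(r$dropped$core_id, c("a", "b", "c"))
  expect_match(r$dropped$qc_reason[r$dropped$core_id == "a"], "insufficient tumor")
  expect_match(r$dropped$qc_reason[r$dropped$core_id == "b"], "out of focus")
  expect_match(r$dropped$qc_reason[r$dropped$core_id == "c"], "folded")

  e <- qc_filter(cores[0, ])
  expect_equal(nrow(e$kept), 0L)
  expect_equal(nrow(e$dropped), 0L)
})

test_that("patient aggregation means nFD, maxes LI, and is permutation-invariant", {
  cores <- cores_df(core_id = c("a", "b", "c"), patient_id = "p1",
                    nfd = c(1.4, 1.5, 1.6), li_grade = c(1L, 3L, 2L))
  a <- aggregate_patient(cores)
  expect_equal(a$mean_nfd, 1.5)
  expect_equal(a$li_max, 3L)
  expect_equal(a, aggregate_patient(cores[c(3, 1, 2), ]))

  single <- cores_df(core_id = "a", patient_id = "p1", nfd = 1.52,
                     li_grade = NA_integer_)
  expect_equal(aggregate_patient(single)$mean_nfd, 1.52)
  expect_true(is.na(aggregate_patient(single)$li_max))

  mixed <- cores_df(core_id = c("a", "b"), patient_id = c("p1", "p2"),
                    nfd = c(1.4, 1.5), li_grade = c(0L, 0L))
  expect_error(aggregate_patient(mixed), class = "nfdim_inconsistent_input")
})

test_that("optimal cut-point recovers a hazard change-point in a simulated cohort", {
  set.seed(1)
  n <- 300L
  mean_nfd <- c(rnorm(n / 2, 1.40, 0.06), rnorm(n / 2, 1.70, 0.06))
  rate <- 0.012 * ifelse(mean_nfd > 1.55, 0.5, 1)
  t_event <- rexp(n, rate)
  patients <- data.frame(patient_id = as.character(seq_len(n)),
                         mean_nfd = mean_nfd,
                         time_months = pmin(t_event, 60),
                         dss_event = t_event <= 60)
  ct <- optimal_cutpoint(patients)
  expect_gte(ct$cut_value, 1.50)
  expect_lte(ct$cut_value, 1.60)
  expect_equal(ct$chi_square, max(ct$scanned$chi_square))
  expect_equal(ct$n_low + ct$n_high, n)
})

test_that("optimal cut-point agrees exactly with an independent exhaustive scan", {
  set.seed(23)
  for (i in 1:3) {
    n <- 80L
    mean_nfd <- round(rnorm(n, 1.5, 0.12), 3)
    t_event <- rexp(n, 0.02 * ifelse(mean_nfd > 1.5, 0.4, 1))
    cens <- rexp(n, 0.01)
    patients <- data.frame(patient_id = as.character(seq_len(n)),
                           mean_nfd = mean_nfd,
                           time_months = pmin(t_event, cens, 60),
                           dss_event = t_event <= pmin(cens, 60))
    ct <- optimal_cutpoint(patients)
    orc <- cutpoint_oracle(mean_nfd, patients$time_months, patients$dss_event)
    expect_identical(ct$cut_value, orc$cut)
    expect_equal(ct$chi_square, orc$chi, tolerance = 1e-8)
  }
})

test_that("degenerate shared survival gives chi-square 0 at the smallest admissible cut", {
  n <- 40L
  patients <- data.frame(patient_id = as.character(seq_len(n)),
                         mean_nfd = seq(1.2, 1.8, length.out = n),
                         time_months = 24, dss_event = TRUE)
  ct <- optimal_cutpoint(patients)
  expect_equal(ct$chi_square, 0)
  admissible <- ct$scanned$candidate
  expect_equal(ct$cut_value, min(admissible))
})

test_that("cut-point search enforces its preconditions", {
  small <- data.frame(patient_id = as.character(1:10), mean_nfd = runif(10),
                      time_months = 10, dss_event = TRUE)
  expect_error(optimal_cutpoint(small), class = "nfdim_invalid_parameter")
  ok <- data.frame(patient_id = as.character(1:30),
                   mean_nfd = rnorm(30, 1.5, 0.1),
                   time_months = 10, dss_event = TRUE)
  expect_error(optimal_cutpoint(ok, min_group_fraction = 0.7),
               class = "nfdim_invalid_parameter")
})

test_that("dichotomization is strictly greater-than and partitions the cohort", {
  p <- data.frame(patient_id = c("a", "b", "c"),
                  mean_nfd = c(1.5, 1.5000001, 1.49))
  r <- apply_cutpoint(p, 1.5)
  expect_equal(as.character(r$nfd_group), c("low", "high", "low"))

  # 107 patients, 25 above the cut -> 23.4% high
  p2 <- data.frame(patient_id = as.character(1:107),
                   mean_nfd = c(seq(1.2, 1.5, length.out = 82),
                                seq(1.6, 1.84, length.out = 25)))
  r2 <- apply_cutpoint(p2, 1.55)
  expect_equal(sum(r2$nfd_group == "high"), 25L)
  expect_equal(round(100 * mean(r2$nfd_group == "high"), 1), 23.4)
  expect_equal(sum(table(r2$nfd_group)), sum(!is.na(r2$mean_nfd)))

  expect_error(apply_cutpoint(p2, 2.5), class = "nfdim_invalid_parameter")
})

test_that("LI dichotomization splits grades {0,1} versus {2,3} by default", {
  p <- data.frame(patient_id = as.character(1:5),
                  li_max = c(0L, 1L, 2L, 3L, NA_integer_))
  r <- li_dichotomize(p)
  expect_equal(as.character(r$li_group), c("low", "low", "high", "high", NA))
})
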