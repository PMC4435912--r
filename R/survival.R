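#' Prepare 5-year disease-specific survival records
#'
#' Follow-up is capped at the horizon (default 60 months); the event
#' indicator is death from disease at or before the horizon. Disease
#' deaths after the horizon and deaths from other causes (which enter as
#' `dss_event = FALSE`) are censored at `min(time, horizon)`.
#'
#' @param patients data frame with positive `time_months` and logical
#'   `dss_event` (death from disease at `time_months`).
#' @param horizon_months horizon in months (default 60).
#' @return the input with `time_months` capped and a logical `event`
#'   column; all other columns carried through.
#' @export
prepare_dss <- function(patients, horizon_months = 60) {
  stopifnot(is.data.frame(patients))
  if (!all(c("time_months", "dss_event") %in% names(patients))) {
    abort_nfdim("need `time_months` and `dss_event` columns",
                "nfdim_invalid_record")
  }
  t <- patients$time_months
  if (any(!is.na(t) & t <= 0)) {
    abort_nfdim("follow-up times must be positive", "nfdim_invalid_record")
  }
  patients$event <- !is.na(patients$dss_event) & patients$dss_event &
    !is.na(t) & t <= horizon_months
  patients$time_months <- pmin(t, horizon_months)
  patients
}

#' Kaplan-Meier estimate of disease-specific survival
#'
#' Product-limit estimator; survival is 1 before the first event and
#' non-increasing.
#'
#' @param dss data frame from [prepare_dss()] (`time_months`, `event`).
#' @return data frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, beginning with a `time = 0, survival = 1` row.
#' @export
km_estimate <- function(dss) {
  if (!is.data.frame(dss) || nrow(dss) == 0L) {
    abort_nfdim("no records to estimate survival from", "nfdim_empty_input")
  }
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = dss, conf.type = "none")
  data.frame(time = c(0, fit$time),
             n_risk = c(fit$n, fit$n.risk),
             n_event = c(0, fit$n.event),
             n_censor = c(0, fit$n.censor),
             survival = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) two-group log-rank statistic with one degree of
#' freedom.
#'
#' @param a,b data frames of the two groups (`time_months`, `event`).
#' @return list with `chi_square` and `p_value`.
#' @export
logrank <- function(a, b) {
  if (!is.data.frame(a) || !is.data.frame(b) || nrow(a) == 0L || nrow(b) == 0L) {
    abort_nfdim("both groups must be non-empty", "nfdim_degenerate_group")
  }
  time <- c(a$time_months, b$time_months)
  event <- c(a$event, b$event)
  if (sum(a$time_months) <= 0 || sum(b$time_months) <= 0) {
    abort_nfdim("a group has no at-risk time", "nfdim_degenerate_group")
  }
  grp <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  chi <- logrank_chisq(time, event, grp)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron tie approximation and 95% Wald
#' confidence intervals on the log-hazard scale. Binary factors should be
#' coded with the reference level first (e.g. `nfd_group` with levels
#' `low < high`, so the reported hazard ratio is high versus low).
#'
#' @param dss data frame from [prepare_dss()].
#' @param covariates character vector of covariate column names; a single
#'   name gives a univariate fit.
#' @return a `cox_result`: `table` (one row per model term: `covariate`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`), `n`, `n_events`, and
#'   the underlying `model`.
#' @export
cox_fit <- function(dss, covariates) {
  missing_cols <- setdiff(covariates, names(dss))
  if (length(missing_cols)) {
    abort_nfdim(paste("unknown covariates:", paste(missing_cols, collapse = ", ")),
                "nfdim_invalid_name")
  }
  keep <- stats::complete.cases(dss[, c("time_months", "event", covariates),
                                    drop = FALSE])
  d <- dss[keep, , drop = FALSE]
  if (sum(d$event) < 10L) {
    abort_nfdim(sprintf("only %d events; need >= 10", sum(d$event)),
                "nfdim_invalid_parameter")
  }
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                               paste(covariates, collapse = " + ")))
  warn <- character(0L)
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(f, data = d, ties = "efron"),
             error = function(e) {
               abort_nfdim(paste("Cox fit failed:", conditionMessage(e)),
                           "nfdim_fit_failure")
             }),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15) ||
      any(grepl("infinite|did not converge", warn, ignore.case = TRUE))) {
    abort_nfdim(paste("monotone likelihood / non-convergence:",
                      paste(warn, collapse = "; ")),
                "nfdim_monotone_likelihood")
  }
  s <- summary(fit)
  tab <- data.frame(covariate = rownames(s$coefficients),
                    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
                    ci_low = unname(s$conf.int[, "lower .95"]),
                    ci_high = unname(s$conf.int[, "upper .95"]),
                    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n = s$n, n_events = s$nevent, model = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d\n", x$n, x$n_events))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Percent hazard reduction implied by a hazard ratio
#'
#' For a protective hazard ratio (HR < 1), the percentage by which the
#' event hazard is reduced: `100 * (1 - HR)`.
#'
#' @param hazard_ratio positive hazard ratio.
#' @return percentage (e.g. 91 for HR 0.09).
#' @export
hazard_reduction_percent <- function(hazard_ratio) {
  if (any(hazard_ratio <= 0)) {
    abort_nfdim("hazard ratios must be positive", "nfdim_invalid_parameter")
  }
  100 * (1 - hazard_ratio)
}
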