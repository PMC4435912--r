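#' Apply core-level quality control
#'
#' A core is excluded iff it is out of focus, the tissue is folded, or it
#' contains fewer than 100 tumor cells. Missing QC metadata is tolerated
#' (a core is only dropped on a recorded failure). Exclusion reasons are
#' returned for audit.
#'
#' @param cores data frame with columns `in_focus`, `not_folded`,
#'   `tumor_cell_count` (plus any others, carried through).
#' @return list with `kept` and `dropped` data frames; `dropped` gains a
#'   `qc_reason` column.
#' @export
qc_filter <- function(cores) {
  stopifnot(is.data.frame(cores))
  need <- c("in_focus", "not_folded", "tumor_cell_count")
  missing_cols <- setdiff(need, names(cores))
  for (col in missing_cols) cores[[col]] <- NA
  reasons <- character(nrow(cores))
  bad_focus <- !is.na(cores$in_focus) & !cores$in_focus
  bad_fold <- !is.na(cores$not_folded) & !cores$not_folded
  bad_tumor <- !is.na(cores$tumor_cell_count) & cores$tumor_cell_count < 100
  add <- function(reasons, flag, txt) {
    ifelse(flag, ifelse(nzchar(reasons), paste(reasons, txt, sep = "; "), txt),
           reasons)
  }
  reasons <- add(reasons, bad_focus, "out of focus")
  reasons <- add(reasons, bad_fold, "folded tissue")
  reasons <- add(reasons, bad_tumor, "insufficient tumor (<100 cells)")
  drop <- bad_focus | bad_fold | bad_tumor
  dropped <- cores[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$qc_reason <- reasons[drop]
  else dropped$qc_reason <- character(0L)
  list(kept = cores[!drop, , drop = FALSE], dropped = dropped)
}

#' Aggregate one patient's cores into a patient record
#'
#' The patient-level score is the arithmetic mean of the available
#' per-core nFD values (patients with fewer than the nominal three usable
#' cores are aggregated over what remains); lymphocytic infiltration is
#' summarized as the maximum grade across cores.
#'
#' @param cores data frame of one patient's (QC-passing) cores, with
#'   columns `patient_id`, `nfd`, `li_grade`.
#' @return one-row data frame: `patient_id`, `mean_nfd`, `li_max`,
#'   `n_cores_nfd`, `n_cores_li`.
#' @export
aggregate_patient <- function(cores) {
  stopifnot(is.data.frame(cores))
  ids <- unique(cores$patient_id)
  if (length(ids) != 1L) {
    abort_nfdim("cores from more than one patient passed to aggregate_patient",
                "nfdim_inconsistent_input")
  }
  nfd <- cores$nfd[!is.na(cores$nfd)]
  li <- if ("li_grade" %in% names(cores)) {
    cores$li_grade[!is.na(cores$li_grade)]
  } else {
    numeric(0L)
  }
  if (length(li) && !all(li %in% 0:3)) {
    abort_nfdim("`li_grade` must be in {0, 1, 2, 3}", "nfdim_invalid_parameter")
  }
  data.frame(patient_id = ids,
             mean_nfd = if (length(nfd)) mean(nfd) else NA_real_,
             li_max = if (length(li)) as.integer(max(li)) else NA_integer_,
             n_cores_nfd = length(nfd),
             n_cores_li = length(li),
             stringsAsFactors = FALSE)
}

#' Aggregate all cores to patient level and join clinical covariates
#'
#' @param cores per-core data frame (see [aggregate_patient()]; QC columns
#'   honoured when `apply_qc = TRUE`).
#' @param clinical optional per-patient data frame joined on `patient_id`.
#' @param apply_qc run [qc_filter()] first (default TRUE).
#' @return patient-level data frame; one row per patient appearing in
#'   `cores` or `clinical`.
#' @export
aggregate_cohort <- function(cores, clinical = NULL, apply_qc = TRUE) {
  if (apply_qc) cores <- qc_filter(cores)$kept
  agg <- do.call(rbind, lapply(split(cores, cores$patient_id), aggregate_patient))
  if (is.null(agg)) {
    agg <- data.frame(patient_id = character(0L), mean_nfd = numeric(0L),
                      li_max = integer(0L), n_cores_nfd = integer(0L),
                      n_cores_li = integer(0L), stringsAsFactors = FALSE)
  }
  rownames(agg) <- NULL
  if (!is.null(clinical)) {
    agg <- merge(clinical, agg, by = "patient_id", all = TRUE, sort = TRUE)
  }
  agg
}

#' Survival-driven optimal cut-point for the continuous nFD score
#'
#' Emulates an X-tile style cut-point search: every midpoint between
#' consecutive distinct patient-level nFD values whose two groups each hold
#' at least `min_group_fraction` of the evaluable patients is scanned, the
#' two-group log-rank chi-square on 5-year disease-specific survival is
#' computed at each, and the candidate maximizing the statistic is
#' returned (ties broken towards the smaller cut value). Because the cut is
#' chosen to maximize the statistic, the naive log-rank p-value at the
#' selected cut is anti-conservative and is deliberately not reported; a
#' Miller-Siegmund corrected p-value is returned as advisory only.
#'
#' @param patients patient-level data frame with `mean_nfd`, `time_months`,
#'   `dss_event` (at least 20 evaluable rows).
#' @param min_group_fraction minimum fraction of evaluable patients on each
#'   side of the cut (in (0, 0.5); default 0.10).
#' @param horizon_months disease-specific survival horizon (default 60).
#' @return a `cutpoint_result`: `cut_value`, `chi_square`, `n_low`,
#'   `n_high`, `scanned` (data frame of every admissible candidate and its
#'   chi-square), `p_advisory_miller_siegmund`.
#' @export
optimal_cutpoint <- function(patients, min_group_fraction = 0.10,
                             horizon_months = 60) {
  if (!(min_group_fraction > 0 && min_group_fraction < 0.5)) {
    abort_nfdim("`min_group_fraction` must be in (0, 0.5)",
                "nfdim_invalid_parameter")
  }
  ok <- !is.na(patients$mean_nfd) & !is.na(patients$time_months) &
    !is.na(patients$dss_event)
  recs <- patients[ok, , drop = FALSE]
  if (nrow(recs) < 20L) {
    abort_nfdim(sprintf("only %d evaluable patients; need >= 20", nrow(recs)),
                "nfdim_invalid_parameter")
  }
  d <- prepare_dss(recs, horizon_months = horizon_months)
  v <- sort(unique(d$mean_nfd))
  if (length(v) < 2L) {
    abort_nfdim("all nFD scores identical; no candidate cut-points",
                "nfdim_no_cutpoint")
  }
  cand <- (v[-length(v)] + v[-1L]) / 2
  n <- nrow(d)
  minn <- min_group_fraction * n
  n_below <- vapply(cand, function(ct) sum(d$mean_nfd <= ct), integer(1L))
  adm <- n_below >= minn & (n - n_below) >= minn
  if (!any(adm)) {
    abort_nfdim("no candidate satisfies the minimum group fraction",
                "nfdim_no_cutpoint")
  }
  cand <- cand[adm]
  chi <- vapply(cand, function(ct) {
    logrank_chisq(d$time_months, d$event, d$mean_nfd > ct)
  }, numeric(1L))
  best <- which.max(chi)  # candidates ascending: first max = smallest cut
  cut <- cand[best]
  z <- sqrt(max(chi[best], 0))
  q1 <- min_group_fraction; q2 <- 1 - q1
  p_ms <- if (z > 1) {
    min(1, stats::dnorm(z) * (z - 1 / z) *
          log((q2 * (1 - q1)) / (q1 * (1 - q2))) + 4 * stats::dnorm(z) / z)
  } else {
    1
  }
  structure(
    list(cut_value = cut,
         chi_square = chi[best],
         n_low = sum(d$mean_nfd <= cut),
         n_high = sum(d$mean_nfd > cut),
         scanned = data.frame(candidate = cand, chi_square = chi),
         p_advisory_miller_siegmund = p_ms,
         min_group_fraction = min_group_fraction),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> cut = %.4f (chi-square %.2f; %d low / %d high; %d candidates scanned)\n",
              x$cut_value, x$chi_square, x$n_low, x$n_high, nrow(x$scanned)))
  cat(sprintf("  advisory Miller-Siegmund corrected p = %.4f\n",
              x$p_advisory_miller_siegmund))
  invisible(x)
}

# log-rank chi-square via survival::survdiff; degenerate scans (zero
# variance, e.g. a shared constant event time) contribute chi-square 0
logrank_chisq <- function(time, event, grp) {
  sd <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ grp),
    error = function(e) NULL
  )
  if (is.null(sd) || !is.finite(sd$chisq)) 0 else sd$chisq
}

#' Dichotomize patients at an nFD cut value
#'
#' Group assignment is strictly greater-than: `nfd_group = "high"` iff
#' `mean_nfd > cut_value`, otherwise `"low"`. Candidates produced by
#' [optimal_cutpoint()] are midpoints, so observed scores never sit on the
#' boundary.
#'
#' @param patients patient-level data frame with `mean_nfd`.
#' @param cut_value cut within the observed nFD range.
#' @return `patients` with an `nfd_group` factor (`low` < `high`) added;
#'   patients without `mean_nfd` keep `NA`.
#' @export
apply_cutpoint <- function(patients, cut_value) {
  rng <- range(patients$mean_nfd, na.rm = TRUE)
  if (!is.finite(cut_value) || cut_value < rng[1L] || cut_value > rng[2L]) {
    abort_nfdim("`cut_value` must lie within the observed nFD range",
                "nfdim_invalid_parameter")
  }
  patients$nfd_group <- factor(
    ifelse(is.na(patients$mean_nfd), NA_character_,
           ifelse(patients$mean_nfd > cut_value, "high", "low")),
    levels = c("low", "high")
  )
  patients
}

#' Dichotomize the lymphocytic infiltration grade
#'
#' @param patients patient-level data frame with `li_max` (grades 0-3).
#' @param high_min smallest grade counted as high (default 2: grades
#'   \{0,1\} low, \{2,3\} high).
#' @return `patients` with an `li_group` factor (`low` < `high`) added.
#' @export
li_dichotomize <- function(patients, high_min = 2L) {
  patients$li_group <- factor(
    ifelse(is.na(patients$li_max), NA_character_,
           ifelse(patients$li_max >= high_min, "high", "low")),
    levels = c("low", "high")
  )
  patients
}
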