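#' Cross-tabulate a covariate against the nFD group
#'
#' Complete-case: patients missing either the covariate or the nFD group
#' are excluded from this table only (per-variable complete-case, matching
#' clinical-table "Missing" rows).
#'
#' @param patients patient-level data frame with `nfd_group` and the
#'   covariate column.
#' @param covariate covariate column name.
#' @return integer matrix, covariate levels x nFD groups (`low`, `high`).
#'   When no complete cases exist, a 0-row matrix with attribute
#'   `degenerate = TRUE`.
#' @export
crosstab <- function(patients, covariate) {
  if (!is.character(covariate) || length(covariate) != 1L ||
      !covariate %in% names(patients)) {
    abort_nfdim(sprintf("unknown covariate: %s", paste(covariate, collapse = ",")),
                "nfdim_invalid_name")
  }
  if (!"nfd_group" %in% names(patients)) {
    abort_nfdim("`nfd_group` not present; apply a cut-point first",
                "nfdim_invalid_name")
  }
  v <- patients[[covariate]]
  g <- patients$nfd_group
  ok <- !is.na(v) & !is.na(g)
  if (!any(ok)) {
    m <- matrix(integer(0L), nrow = 0L, ncol = 2L,
                dimnames = list(NULL, c("low", "high")))
    attr(m, "degenerate") <- TRUE
    return(m)
  }
  v <- if (is.factor(v)) droplevels(factor(v[ok])) else factor(v[ok])
  g <- factor(as.character(g[ok]), levels = c("low", "high"))
  tab <- table(v, g)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Fisher's exact test on a contingency table
#'
#' Two-sided by the point-probability rule: the p-value is the sum of the
#' probabilities, under the hypergeometric null with fixed margins, of all
#' tables whose probability does not exceed the observed table's. Tables
#' larger than 2x2 use the exact network algorithm where feasible, with a
#' chi-square fallback (and a warning) for tables too large to enumerate.
#'
#' @param tab integer matrix of counts, at least 2x2, with positive
#'   margins.
#' @return the two-sided p-value.
#' @export
fishers_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort_nfdim("contingency table must be at least 2x2",
                "nfdim_invalid_parameter")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    abort_nfdim("counts must be non-negative integers",
                "nfdim_invalid_parameter")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort_nfdim("a zero margin leaves the test undefined",
                "nfdim_undefined_test")
  }
  res <- tryCatch(stats::fisher.test(tab),
                  error = function(e) NULL)
  if (is.null(res)) {
    warning("exact enumeration infeasible for this table; using chi-square approximation")
    return(suppressWarnings(stats::chisq.test(tab)$p.value))
  }
  res$p.value
}

#' Compare continuous nFD between two groups
#'
#' Two-sided Wilcoxon rank-sum by default (exact when sample sizes permit
#' and no ties are present), with Welch's t as a configurable alternative.
#' Identical values across both groups give the degenerate p = 1.
#'
#' @param x,y numeric vectors (each with at least 2 values).
#' @param method `"wilcoxon"` (default) or `"welch"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
rank_compare <- function(x, y, method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort_nfdim("each group needs at least 2 values", "nfdim_invalid_parameter")
  }
  if (length(unique(c(x, y))) == 1L) {
    stat <- if (method == "wilcoxon") length(x) * length(y) / 2 else 0
    return(list(statistic = stat, p_value = 1, method = method))
  }
  if (method == "wilcoxon") {
    t <- suppressWarnings(stats::wilcox.test(x, y))
    list(statistic = unname(t$statistic), p_value = t$p.value,
         method = "wilcoxon")
  } else {
    t <- stats::t.test(x, y)
    list(statistic = unname(t$statistic), p_value = t$p.value,
         method = "welch")
  }
}

#' Five-number summaries per group
#'
#' Min, lower quartile, median, upper quartile and max per group
#' (linear-interpolation quantiles), the numbers behind a box-and-whisker
#' plot.
#'
#' @param values_by_group named list of numeric vectors (each non-empty).
#' @return data frame: `group`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
boxplot_summary <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 1L)
  rows <- lapply(seq_along(values_by_group), function(i) {
    v <- values_by_group[[i]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      abort_nfdim("each group needs at least 1 value", "nfdim_invalid_parameter")
    }
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    nm <- names(values_by_group)[i]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- as.character(i)
    data.frame(group = nm,
               n = length(v), min = q[1L], q1 = q[2L], median = q[3L],
               q3 = q[4L], max = q[5L], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clinico-pathological association table
#'
#' One block per covariate: level counts, percent of evaluable patients,
#' counts by nFD group, and the Fisher's exact p-value for the
#' covariate-by-group table (reported on the covariate's first row).
#'
#' @param patients patient-level data frame with `nfd_group`.
#' @param covariates covariate column names (categorical).
#' @return data frame: `covariate`, `level`, `n`, `percent`, `n_low`,
#'   `n_high`, `n_missing`, `test`, `p_value`.
#' @export
table_one <- function(patients,
                      covariates = c("gender", "pt_stage", "pn_status",
                                     "smoking", "alcohol", "differentiation",
                                     "treatment", "ki67_group", "li_group")) {
  covariates <- intersect(covariates, names(patients))
  blocks <- lapply(covariates, function(cv) {
    tab <- crosstab(patients, cv)
    if (isTRUE(attr(tab, "degenerate"))) return(NULL)
    p <- tryCatch(fishers_exact(tab), nfdim_error = function(e) NA_real_)
    ntot <- sum(tab)
    nmiss <- nrow(patients) - ntot
    data.frame(covariate = cv,
               level = rownames(tab),
               n = rowSums(tab),
               percent = round(100 * rowSums(tab) / ntot, 1),
               n_low = tab[, "low"],
               n_high = tab[, "high"],
               n_missing = c(nmiss, rep(NA_integer_, nrow(tab) - 1L)),
               test = c("fishers_exact", rep(NA_character_, nrow(tab) - 1L)),
               p_value = c(p, rep(NA_real_, nrow(tab) - 1L)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
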