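#' Score every core image in a directory
#'
#' Reads each single-channel grayscale TIFF, runs the full threshold sweep,
#' and returns one row per core. Core and patient identifiers come from an
#' optional metadata table, or else from file names of the form
#' `<patient>_<core>.tif`. Cores whose sweep yields no signal are kept in
#' the output with `nfd = NA` and a `flag` explaining why (flagged, never
#' silently dropped); unreadable files are skipped with a warning.
#'
#' @param image_dir directory of TIFF files (or a character vector of
#'   paths).
#' @param pixel_size_um pixel calibration applied to every image.
#' @param metadata optional data frame with columns `path`, `core_id`,
#'   `patient_id` and optionally `in_focus`, `not_folded`,
#'   `tumor_cell_count`.
#' @param output_csv optional path; per-core results written as CSV.
#' @param sweep_json optional path; the full FD-versus-threshold curves
#'   written as JSON.
#' @param ... passed to [sweep_nfd()].
#' @return data frame: `core_id`, `patient_id`, `nfd`, `argmax_threshold`,
#'   `n_thresholds_fit`, `min_r_squared`, `flag`, plus QC columns.
#' @export
score_cores <- function(image_dir, pixel_size_um = 0.468, metadata = NULL,
                        output_csv = NULL, sweep_json = NULL, ...) {
  paths <- if (length(image_dir) == 1L && dir.exists(image_dir)) {
    sort(list.files(image_dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                    full.names = TRUE))
  } else {
    as.character(image_dir)
  }
  if (length(paths) == 0L) {
    abort_nfdim("no TIFF images found", "nfdim_invalid_parameter")
  }
  meta_for <- function(p) {
    if (!is.null(metadata)) {
      hit <- metadata[basename(metadata$path) == basename(p), , drop = FALSE]
      if (nrow(hit) == 1L) return(as.list(hit))
    }
    list()
  }
  rows <- list(); sweeps <- list(); n_fail <- 0L
  for (p in paths) {
    md <- meta_for(p)
    img <- tryCatch(
      read_core_tiff(p, pixel_size_um = pixel_size_um,
                     core_id = md$core_id, patient_id = md$patient_id,
                     in_focus = md$in_focus %_or_% TRUE,
                     not_folded = md$not_folded %_or_% TRUE,
                     tumor_cell_count = md$tumor_cell_count %_or_% NA_integer_),
      error = function(e) {
        warning(sprintf("skipping %s: %s", basename(p), conditionMessage(e)))
        NULL
      })
    if (is.null(img)) { n_fail <- n_fail + 1L; next }
    sw <- tryCatch(sweep_nfd(img, ...), nfdim_no_signal = function(e) e)
    flagged <- inherits(sw, "condition")
    rows[[length(rows) + 1L]] <- data.frame(
      core_id = img$core_id, patient_id = img$patient_id,
      nfd = if (flagged) NA_real_ else sw$nfd,
      argmax_threshold = if (flagged) NA_integer_ else sw$argmax_threshold,
      n_thresholds_fit = if (flagged) 0L else length(sw$thresholds),
      min_r_squared = if (flagged) NA_real_ else sw$min_r_squared,
      flag = if (flagged) conditionMessage(sw) else NA_character_,
      in_focus = img$qc$in_focus, not_folded = img$qc$not_folded,
      tumor_cell_count = img$qc$tumor_cell_count,
      stringsAsFactors = FALSE)
    if (!flagged) {
      sweeps[[img$core_id]] <- list(thresholds = sw$thresholds,
                                    fd_values = sw$fd_values,
                                    nfd = sw$nfd,
                                    argmax_threshold = sw$argmax_threshold,
                                    skipped = sw$skipped)
    }
  }
  if (length(rows) == 0L) {
    abort_nfdim("all images failed to score", "nfdim_no_signal")
  }
  out <- do.call(rbind, rows)
  if (!is.null(output_csv)) utils::write.csv(out, output_csv, row.names = FALSE)
  if (!is.null(sweep_json)) {
    jsonlite::write_json(sweeps, sweep_json, auto_unbox = TRUE, digits = NA)
  }
  out
}

`%_or_%` <- function(a, b) if (is.null(a)) b else a

#' Run the full patient-level analysis
#'
#' Aggregates QC-passing cores per patient, joins clinical covariates,
#' finds the survival-driven optimal nFD cut-point, dichotomizes, and
#' emits the association table, univariate and multivariate Cox models
#' (the multivariate model adjusted for pT-stage and pN-status, plus a
#' second specification additionally adjusted for radiotherapy), and
#' Kaplan-Meier step functions by nFD group for all patients and for the
#' radiotherapy / surgery-only subgroups (re-using the cohort-wide
#' cut-point).
#'
#' @param cores per-core data frame or CSV path (columns as written by
#'   [score_cores()] plus optional `li_grade`).
#' @param clinical per-patient data frame or CSV path.
#' @param output_dir optional directory; writes `patients.csv`,
#'   `cutpoint.json`, `association.csv`, `survival.csv`, `km_all.csv`, and
#'   when treatment is available `km_rt.csv` and `km_surgery.csv`.
#' @param min_group_fraction see [optimal_cutpoint()].
#' @param li_high_min see [li_dichotomize()].
#' @return (invisibly) a list: `patients`, `cutpoint`, `association`,
#'   `cox_univariate`, `cox_multivariate`, `cox_multivariate_rt`,
#'   `km` (named list of step-function data frames).
#' @export
analyze_cohort <- function(cores, clinical, output_dir = NULL,
                           min_group_fraction = 0.10, li_high_min = 2L) {
  if (is.character(cores)) cores <- utils::read.csv(cores)
  if (is.character(clinical)) clinical <- utils::read.csv(clinical)
  for (col in c("patient_id", "time_months", "dss_event")) {
    if (!col %in% names(clinical)) {
      abort_nfdim(sprintf("clinical table lacks required column `%s`", col),
                  "nfdim_invalid_record")
    }
  }
  patients <- aggregate_cohort(cores, clinical)
  cut <- optimal_cutpoint(patients, min_group_fraction = min_group_fraction)
  patients <- apply_cutpoint(patients, cut$cut_value)
  if ("li_max" %in% names(patients)) {
    patients <- li_dichotomize(patients, high_min = li_high_min)
  }

  assoc <- table_one(patients)

  dss <- prepare_dss(patients[!is.na(patients$nfd_group), , drop = FALSE])
  factorize <- function(d) {
    if ("pt_stage" %in% names(d)) d$pt_stage <- factor(d$pt_stage, c("low", "high"))
    if ("pn_status" %in% names(d)) d$pn_status <- factor(d$pn_status, c("N0", "N1/N2"))
    if ("treatment" %in% names(d)) d$treatment <- factor(d$treatment, c("surgery", "surgery+RT"))
    d
  }
  dss <- factorize(dss)
  uni_terms <- intersect(c("nfd_group", "pt_stage", "pn_status", "treatment"),
                         names(dss))
  cox_uni <- lapply(uni_terms, function(cv) {
    tryCatch(cox_fit(dss, cv)$table, nfdim_error = function(e) NULL)
  })
  cox_uni <- do.call(rbind, cox_uni)
  multi_terms <- intersect(c("nfd_group", "pt_stage", "pn_status"), names(dss))
  cox_multi <- tryCatch(cox_fit(dss, multi_terms)$table,
                        nfdim_error = function(e) NULL)
  cox_multi_rt <- if ("treatment" %in% names(dss)) {
    tryCatch(cox_fit(dss, c(multi_terms, "treatment"))$table,
             nfdim_error = function(e) NULL)
  }

  km_by_group <- function(d) {
    lapply(split(d, d$nfd_group), km_estimate)
  }
  km <- list(all = km_by_group(dss))
  if ("treatment" %in% names(dss) && !all(is.na(dss$treatment))) {
    km$rt <- km_by_group(dss[!is.na(dss$treatment) &
                               dss$treatment == "surgery+RT", , drop = FALSE])
    km$surgery <- km_by_group(dss[!is.na(dss$treatment) &
                                    dss$treatment == "surgery", , drop = FALSE])
  } else {
    warning("no `treatment` column; radiotherapy subgroup analyses skipped")
  }

  res <- list(patients = patients, cutpoint = cut, association = assoc,
              cox_univariate = cox_uni, cox_multivariate = cox_multi,
              cox_multivariate_rt = cox_multi_rt, km = km)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(d, f) utils::write.csv(d, file.path(output_dir, f),
                                         row.names = FALSE)
    w(patients, "patients.csv")
    jsonlite::write_json(
      list(cut_value = cut$cut_value, chi_square = cut$chi_square,
           n_low = cut$n_low, n_high = cut$n_high,
           p_advisory_miller_siegmund = cut$p_advisory_miller_siegmund,
           scanned = cut$scanned),
      file.path(output_dir, "cutpoint.json"), auto_unbox = TRUE, digits = NA)
    w(assoc, "association.csv")
    surv_tab <- rbind(
      if (!is.null(cox_uni)) cbind(model = "univariate", cox_uni),
      if (!is.null(cox_multi)) cbind(model = "multivariate", cox_multi),
      if (!is.null(cox_multi_rt)) cbind(model = "multivariate+RT", cox_multi_rt))
    if (is.null(surv_tab)) {
      surv_tab <- data.frame(model = character(0), covariate = character(0),
                             hazard_ratio = numeric(0), ci_low = numeric(0),
                             ci_high = numeric(0), p_value = numeric(0))
    }
    w(surv_tab, "survival.csv")
    flat_km <- function(l) do.call(rbind, lapply(names(l), function(g) {
      cbind(nfd_group = g, l[[g]])
    }))
    w(flat_km(km$all), "km_all.csv")
    if (!is.null(km$rt)) {
      w(flat_km(km$rt), "km_rt.csv")
      w(flat_km(km$surgery), "km_surgery.csv")
    }
  }
  invisible(res)
}

#' Write a synthetic fixture bundle to disk
#'
#' Generates a cohort with [generate_cohort()] and writes `clinical.csv`,
#' `cores.csv` and `truth.csv` (plus `class_boundary` and `true_hr` in
#' `truth_meta.json`). Optionally renders the first `n_images` cores as
#' TIFF images with [render_core()] (one seed per core, derived from the
#' cohort seed) and writes an image `metadata.csv`.
#'
#' @param output_dir output directory (created if needed).
#' @param cohort_config a [synthetic_cohort_config()].
#' @param image_config a [synthetic_image_config()] template for rendered
#'   images (its `seed` is re-derived per core).
#' @param n_images number of cores to render as TIFFs (default 0).
#' @return (invisibly) named list of the file paths written.
#' @export
simulate_bundle <- function(output_dir,
                            cohort_config = synthetic_cohort_config(),
                            image_config = synthetic_image_config(),
                            n_images = 0L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort(cohort_config)
  paths <- list(clinical = file.path(output_dir, "clinical.csv"),
                cores = file.path(output_dir, "cores.csv"),
                truth = file.path(output_dir, "truth.csv"),
                truth_meta = file.path(output_dir, "truth_meta.json"))
  utils::write.csv(gen$patients, paths$clinical, row.names = FALSE)
  utils::write.csv(gen$cores, paths$cores, row.names = FALSE)
  utils::write.csv(gen$truth, paths$truth, row.names = FALSE)
  jsonlite::write_json(list(class_boundary = attr(gen$truth, "class_boundary"),
                            true_hr = attr(gen$truth, "true_hr"),
                            seed = cohort_config$seed),
                       paths$truth_meta, auto_unbox = TRUE, digits = NA)
  if (n_images > 0L) {
    img_dir <- file.path(output_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    md <- list()
    for (i in seq_len(min(n_images, nrow(gen$cores)))) {
      cfg <- image_config
      cfg$seed <- cohort_config$seed * 1000L + i
      rc <- render_core(cfg, core_id = gen$cores$core_id[i],
                        patient_id = gen$cores$patient_id[i])
      f <- file.path(img_dir, paste0(gen$cores$core_id[i], ".tif"))
      write_core_tiff(rc$image, f)
      md[[i]] <- data.frame(path = f, core_id = gen$cores$core_id[i],
                            patient_id = gen$cores$patient_id[i],
                            in_focus = TRUE, not_folded = TRUE,
                            tumor_cell_count = rc$image$qc$tumor_cell_count,
                            stringsAsFactors = FALSE)
    }
    paths$image_metadata <- file.path(output_dir, "image_metadata.csv")
    utils::write.csv(do.call(rbind, md), paths$image_metadata,
                     row.names = FALSE)
    paths$image_dir <- img_dir
  }
  invisible(paths)
}
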