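# nfdim

Nuclear fractal dimension (nFD) scoring and prognostic analysis for tissue
microarray (TMA) cores.

Histopathological risk assessment in oral squamous cell carcinoma (OSCC)
relies on expert, labour-intensive scoring of tumor and stromal features.
`nfdim` implements a digital alternative: a single prognostic score computed
from DAPI-stained grayscale images of whole TMA cores, capturing how densely
the outlines of nuclei — tumor *and* stroma together — fill the plane. The
package is aimed at digital-pathology and biostatistics groups who want the
complete analysis path (image → score → dichotomization → survival and
association models) as tested, reproducible code, plus a synthetic-data
module so every stage can be exercised without patient data.

## The score

For a calibrated grayscale core image (0.468 μm/pixel by default):

1. binarize at a series of intensity thresholds *t* (foreground: intensity ≥ *t*);
2. extract the nuclear outlines (foreground pixels with a background 4-neighbor);
3. box-count each outline image over box sizes *s* ∈ {8, 16, 32, 64, 128} px
   (3.7–60 μm) and estimate the fractal dimension as the OLS slope of
   log *N*(*s*) versus log (1/*s*), where *N*(*s*) is the number of occupied
   grid cells;
4. nFD = the global maximum of the dimension-versus-threshold curve.

Patients are scored by the mean nFD of their (QC-passing) triplicate cores,
dichotomized at the cut-point maximizing the two-group log-rank chi-square
on 5-year disease-specific survival (an X-tile-style exhaustive scan), and
analysed with Fisher's exact tests, Kaplan–Meier/log-rank comparisons, and
univariate/multivariate Cox proportional-hazards models.

## Worked example

```r
library(nfdim)

# score a synthetic DAPI-like core image
img <- render_core(synthetic_image_config(size_px = 512L, n_nuclei = 400L,
                                          seed = 7L))$image
sweep_nfd(img)
#> <threshold_sweep> core synthetic_core: nFD = 1.6235 at threshold 21 (64 fitted, 0 skipped)

# a synthetic cohort with a known protective high-nFD class (HR 0.1)
gen <- generate_cohort(synthetic_cohort_config(
  n_patients = 300L, nfd_class_mix = 0.5,
  baseline_hazard_per_month = 0.016, censoring_rate_per_month = 0.002,
  seed = 7L))
res <- analyze_cohort(gen$cores, gen$patients)

res$cutpoint
#> <cutpoint_result> cut = 1.5111 (chi-square 123.40; 135 low / 165 high; 239 candidates scanned)
#>   advisory Miller-Siegmund corrected p = 0.0000

res$cox_multivariate
#>        covariate hazard_ratio     ci_low   ci_high      p_value
#>    nfd_grouphigh   0.07331184 0.04040809 0.1330086 8.148497e-18
#>     pt_stagehigh   0.86564057 0.57530417 1.3024999 4.888400e-01
#>   pn_statusN1/N2   1.11801276 0.74690079 1.6735188 5.878017e-01
```

The recovered cut (1.51) sits near the generative class boundary (1.575),
and the adjusted hazard ratio of the high-nFD group (0.073, 95% CI
0.040–0.133) recovers the generative hazard ratio 0.1: high nFD is
protective. `analyze_cohort(..., output_dir = ...)` additionally writes the
patient table, the cut-point audit (every scanned candidate and its
chi-square), the association table, the Cox models and the Kaplan–Meier
step functions (all patients and radiotherapy/surgery-only subgroups) as
CSV/JSON.

Real images enter through `score_cores("dir/of/tiffs/")` (single-channel
grayscale TIFF, 8- or 16-bit) followed by the same `analyze_cohort()` call;
a thin command-line wrapper lives at `inst/cli/nfdim.R`
(`score` / `analyze` / `simulate` subcommands).

## Methods documentation

The methods vignette (`vignettes/nfd-methods.Rmd`) documents the model and
its assumptions, every tunable parameter with its default and rationale,
the threshold-series amendments (degenerate-band fallback and the
background-noise floor), prefractal truncation and its consequences for
calibration, the selection bias of maximally selected cut-points, the
synthetic generator's scope and limitations, and the design of the
validation experiments.
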