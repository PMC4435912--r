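# Classed conditions so callers can distinguish failure modes
# (e.g. a core with no thresholdable signal is flagged, not dropped).

abort_nfdim <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "nfdim_error"), call = call))
}

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
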