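# Independent oracles, coded without reference to the package internals.

# brute-force box counting: explicit double loop over grid cells
box_count_oracle <- function(bits, s) {
  nr <- nrow(bits); nc <- ncol(bits)
  cnt <- 0L
  for (i in seq(1L, nr, by = s)) {
    for (j in seq(1L, nc, by = s)) {
      if (any(bits[i:min(i + s - 1L, nr), j:min(j + s - 1L, nc)])) {
        cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# closed-form ordinary least squares slope/intercept/r^2
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  r2 <- sum((x - mx) * (y - my))^2 / (sum((x - mx)^2) * sum((y - my)^2))
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# two-group log-rank chi-square from an explicit observed-minus-expected
# tabulation over event times
logrank_oracle <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  o1 <- e1sum <- v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= tt & grp == 1L)
    n2 <- sum(time >= tt & grp == 2L)
    n <- n1 + n2
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1L)
    o1 <- o1 + d1
    e1sum <- e1sum + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o1 - e1sum)^2 / v
}

# two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins (point-probability rule, with fisher.test's relative
# tolerance on the probability comparison)
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0L, r1 + c1 - n); a_max <- min(r1, c1)
  support <- a_min:a_max
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independently coded exhaustive cut-point scan over the same candidates,
# driven by the O-E log-rank oracle
cutpoint_oracle <- function(mean_nfd, time, event, mgf = 0.1, horizon = 60) {
  ev <- event & time <= horizon
  tt <- pmin(time, horizon)
  v <- sort(unique(mean_nfd))
  cands <- (v[-length(v)] + v[-1]) / 2
  n <- length(mean_nfd)
  best_cut <- NA_real_; best_chi <- -Inf
  for (ct in cands) {
    hi <- mean_nfd > ct
    if (sum(hi) < mgf * n || sum(!hi) < mgf * n) next
    chi <- logrank_oracle(tt[!hi], ev[!hi], tt[hi], ev[hi])
    if (chi > best_chi + 1e-12) { best_chi <- chi; best_cut <- ct }
  }
  list(cut = best_cut, chi = best_chi)
}

# quick builder for survival record frames
dss_frame <- function(time, event) {
  data.frame(time_months = time, event = as.logical(event))
}
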