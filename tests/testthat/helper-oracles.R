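# Independent oracles and small fixture builders shared across tests.

# Exact Gaussian profile sampled on a uniform grid.
gaussian_profile <- function(sigma = 1, mu = 0, A = 10, b = 0,
                             from = -4, to = 4, by = 0.25) {
  u <- seq(from, to, by = by)
  data.frame(position = u, value = A * exp(-(u - mu)^2 / (2 * sigma^2)) + b)
}

# Brute-force Brenner gradient: explicit double loop over pixels.
brute_brenner <- function(plane, step = 2) {
  acc <- 0
  for (y in seq_len(nrow(plane)))
    for (x in seq_len(ncol(plane) - step))
      acc <- acc + (plane[y, x + step] - plane[y, x])^2
  acc
}

# Brute-force Otsu: exhaustive scan over candidate splits maximising the
# between-class variance computed directly from the two pixel classes.
brute_otsu <- function(x, n_bins = 256) {
  v <- as.vector(x)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in seq_len(n_bins - 1)) {
    thr <- breaks[t + 1]
    lo <- v[v <= thr]
    hi <- v[v > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  breaks[best_t + 1]
}

# Standardised pairwise rank-sum statistic (tie-corrected), as used by the
# DSCF procedure; duplicated here so the permutation oracle is independent
# of the package implementation.
oracle_pair_stat <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj); n <- ni + nj
  r <- rank(c(xi, xj))
  W <- sum(r[(ni + 1):n])
  ties <- table(c(xi, xj))
  v <- ni * nj / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v > 0) (W - nj * (n + 1) / 2) / sqrt(v) else 0
}

# Full permutation distribution of the maximum absolute pairwise statistic
# over all assignments of the pooled values to three groups.
perm_dscf_p <- function(groups) {
  ns <- lengths(groups)
  pooled <- unlist(groups)
  obs <- c(oracle_pair_stat(groups[[1]], groups[[2]]),
           oracle_pair_stat(groups[[1]], groups[[3]]),
           oracle_pair_stat(groups[[2]], groups[[3]]))
  idx <- seq_along(pooled)
  c1 <- utils::combn(idx, ns[1])
  mx <- numeric(0)
  for (a in seq_len(ncol(c1))) {
    g1 <- c1[, a]
    rest <- setdiff(idx, g1)
    c2 <- utils::combn(rest, ns[2])
    for (b in seq_len(ncol(c2))) {
      g2 <- c2[, b]
      g3 <- setdiff(rest, g2)
      s <- c(oracle_pair_stat(pooled[g1], pooled[g2]),
             oracle_pair_stat(pooled[g1], pooled[g3]),
             oracle_pair_stat(pooled[g2], pooled[g3]))
      mx <- c(mx, max(abs(s)))
    }
  }
  vapply(abs(obs), function(o) mean(mx >= o - 1e-12), numeric(1))
}

# Noise-free single-bead parameter set (all stochastic degradation off).
clean_bead_params <- function(...) {
  bead_field_params(n_beads = 1, poisson = FALSE, read_noise_sd = 0,
                    jitter_sd = 0, fwhm_cv = 0, ...)
}

# Quiet ROI extraction for noise-free movies whose empty frames are
# constant (Otsu undefined there by design).
quiet_extract <- function(...) suppressWarnings(extract_activity(...))
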