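# shared model fixtures and independent oracles for the test suite

yule_spec <- function(beta = 1) rates_constant(beta, 0)

# Gamma(2, 2) unit-mean waiting times: hazard g/(1-G) = 4a/(1+2a)
gamma2_wt <- function() wt_gamma(2)

# brute-force oracle: number of set partitions of {1..n} into k blocks,
# by enumerating all block assignments
count_set_partitions <- function(n, k) {
  if (n == 0) return(as.numeric(k == 0))
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  cnt <- 0
  for (i in seq_len(nrow(grids))) {
    lab <- as.numeric(grids[i, ])
    if (length(unique(lab)) == k &&
        all(lab == as.numeric(factor(lab, levels = unique(lab)))))
      cnt <- cnt + 1
  }
  cnt
}

# brute-force oracle: coefficients of x(x-1)...(x-(n-1)) by polynomial
# multiplication; coef[l+1] is the x^l coefficient = s(n, l)
falling_factorial_coefs <- function(n) {
  p <- 1
  for (j in 0:(n - 1)) p <- c(0, p) - c(j * p, 0)  # multiply by (x - j)
  p
}

# independent oracle for the Gamma-fission mean population: count completed
# generations, whose waiting sums are Gamma(k*alpha, alpha)
gamma_series_T <- function(alpha, t) {
  vapply(t, function(t1) {
    G <- function(k) if (k == 0) 1 else pgamma(t1, k * alpha, alpha)
    sum(vapply(0:80, function(k) 2^k * (G(k) - G(k + 1)), numeric(1)))
  }, numeric(1))
}

# per-trajectory total counts at snapshot t
ensemble_counts <- function(ens, t) {
  i <- which(abs(ens$snapshot_times - t) < 1e-9)
  vapply(ens$states, function(tr)
    length(tr[[i]]$s) + 2L * length(tr[[i]]$d), numeric(1))
}

# expected count in a TOB bin from a mean-field matrix column (trapezoid)
field_bin_integral <- function(mat, grid, col, lo, hi) {
  h <- grid[2] - grid[1]
  xs <- seq(lo, hi, by = h)
  y <- mat[round(xs / h) + 1L, col]
  sum((y[-1] + y[-length(y)]) / 2) * h
}

expect_within_se <- function(observed, expected, se, n_se = 3,
                             floor_se = 0) {
  expect_lt(abs(observed - expected), n_se * max(se, floor_se) + 1e-12)
}
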