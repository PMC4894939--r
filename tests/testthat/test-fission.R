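test_that("fission fecundity and total population match exponential laws", {
  tg <- seq(0, 3, by = 1e-3)
  spf <- hazards_from_waiting_time(wt_exponential(1), 1)
  B <- solve_fission_B(spf, tg)
  ff <- fission_fields(B, spf)
  expect_lt(max(abs(ff$Ttot - exp(tg)) / exp(tg)), 1e-6)
  # no fission hazard: B identically zero
  spd <- hazards_from_waiting_time(wt_exponential(1), 0)
  expect_equal(max(abs(solve_fission_B(spd, tg)$B)), 0)
  # critical split: total population pinned at 1
  spc <- hazards_from_waiting_time(gamma2_wt(), 0.5)
  ffc <- fission_fields(solve_fission_B(spc, tg), spc)
  expect_lt(max(abs(ffc$Ttot - 1)), 1e-6)
})

test_that("assembled fields satisfy their structural identities", {
  tg <- seq(0, 3, by = 2e-3)
  spf <- hazards_from_waiting_time(wt_gamma(10), 1)
  B <- solve_fission_B(spf, tg)
  ff <- fission_fields(B, spf)
  # T = X + 2Y pointwise
  expect_lt(max(abs(ff$T - (ff$X + 2 * ff$Y))), 1e-10)
  # newborn pairs: X(x, x) = 0 and Y(x, x) = B(x)
  expect_equal(diag(ff$X), rep(0, length(tg)))
  expect_equal(diag(ff$Y), B$B)
  # doublets decay with the squared propagator: Y(x, t) = B(x) U^2
  i <- round(0.5 / 2e-3) + 1L; j <- round(2 / 2e-3) + 1L  # x = 0.5, t = 2
  S <- 1 - wt_gamma(10)$cdf(tg[j] - tg[i])
  expect_equal(ff$Y[i, j], B$B[i] * S^2, tolerance = 1e-10)
  expect_equal(ff$X[i, j], 2 * B$B[i] * S * (1 - S), tolerance = 1e-10)
  # all fields nonnegative
  expect_gte(min(ff$X), 0)
  expect_gte(min(ff$Y), 0)
})

test_that("frozen dynamics and pure-death initial densities propagate", {
  # beta = mu = 0: U = 1, fields frozen at the initial densities
  frozen <- rate_spec(function(n, a) rep(0, length(a)),
                      function(n, a) rep(0, length(a)),
                      progeny = c(1, 0),
                      cum_birth = function(a) 0 * a,
                      cum_death = function(a) 0 * a)
  tg <- seq(0, 2, by = 1e-3)
  X0 <- function(a) dexp(a); Y0 <- function(a) 0.5 * dexp(a)
  B <- solve_fission_B(frozen, tg, init = list(X0 = X0, Y0 = Y0))
  expect_equal(max(abs(B$B)), 0)
  ff <- fission_fields(B, frozen, init = list(X0 = X0, Y0 = Y0))
  expect_lt(max(abs(ff$Ttot - 2)), 1e-6)       # mass 1 + 2 * 0.5 conserved
  # pure death with constant hazard: T(t) = T(0) e^{-mu t}
  pd <- hazards_from_waiting_time(wt_exponential(1), 0)
  Bp <- solve_fission_B(pd, tg, init = list(X0 = X0, Y0 = Y0))
  ffp <- fission_fields(Bp, pd, init = list(X0 = X0, Y0 = Y0))
  expect_lt(max(abs(ffp$Ttot - 2 * exp(-tg))), 1e-6)
})

test_that("the transport reduction holds and converges at second order", {
  spf <- hazards_from_waiting_time(wt_exponential(1), 1)
  res <- vapply(c(4e-3, 2e-3, 1e-3), function(h) {
    tg <- seq(0, 2, by = h)
    ff <- fission_fields(solve_fission_B(spf, tg), spf)
    chk <- mvf_reduction_check(ff, spf)
    chk$max_boundary_residual
  }, numeric(1))
  expect_lt(res[3], 1e-4)
  expect_gt(res[1] / res[2], 3)        # O(h^2) shrinkage
  tg <- seq(0, 2, by = 1e-3)
  ff <- fission_fields(solve_fission_B(spf, tg), spf)
  expect_lt(mvf_reduction_check(ff, spf)$max_pde_residual, 1e-5)
})

test_that("Bellman-Harris renewal mean matches its benchmarks", {
  tg <- seq(0, 3, by = 1e-3)
  bh <- bellman_harris_mean(wt_exponential(1), 1, tg)
  expect_equal(bh$T[1], 1)
  expect_lt(max(abs(bh$T - exp(tg)) / exp(tg)), 1e-6)
  # critical process: T identically 1 for any proper waiting time
  for (w in list(wt_exponential(1.7), gamma2_wt(), wt_gamma(10))) {
    bhc <- bellman_harris_mean(w, 0.5, tg)
    expect_lt(max(abs(bhc$T - 1)), 1e-6)
  }
})

test_that("generating-function and kinetic means coincide (equivalence)", {
  tg <- seq(0, 3, by = 1e-3)
  tt <- seq(0.25, 3, by = 0.25)
  for (w in list(wt_exponential(1), gamma2_wt(), wt_gamma(10))) {
    bh <- bellman_harris_mean(w, 1, tg)
    Tl <- bellman_harris_mean_laplace(w, 1)
    ref <- approx(tg, bh$T, tt)$y
    expect_lt(max(abs(Tl(tt) - ref) / ref), 1e-4)
  }
  # pure death reduces to the waiting-time survival
  Tl0 <- bellman_harris_mean_laplace(wt_gamma(2), 0)
  expect_lt(max(abs(Tl0(tt) - (1 - pgamma(tt, 2, 2)))), 1e-6)
  expect_equal(Tl0(0), 1)
})

test_that("Gamma-fission closed forms match independent inversion", {
  tt <- c(0.5, 1, 2, 3)
  # alpha = 1: exactly e^t (single residue, no branch-cut term)
  expect_equal(gamma_fission_T(1, tt), exp(tt), tolerance = 1e-12)
  expect_equal(gamma_fission_B(1, tt), exp(tt), tolerance = 1e-12)
  # T(0) = 1 across dispersion values (integer and not)
  for (al in c(1, 2.5, 3, 5, 7, 10)) {
    expect_equal(gamma_fission_T(al, 0), 1, tolerance = 1e-8)
  }
  # mean population vs the exact generation-counting series
  # T(t) = sum_k 2^k P(S_k <= t < S_{k+1}), S_k ~ Gamma(k alpha, alpha)
  for (al in c(2, 10, 100)) {
    expect_equal(gamma_fission_T(al, tt), gamma_series_T(al, tt),
                 tolerance = 1e-10)
  }
  # branch-cut/residue evaluation vs Talbot inversion for moderate alpha
  for (al in c(2.5, 3, 5, 9)) {
    a <- gamma_fission_T(al, tt, method = "contour")
    b <- gamma_fission_T(al, tt, method = "talbot")
    expect_lt(max(abs(a - b) / b), 1e-6)
    aB <- gamma_fission_B(al, tt, method = "contour")
    bB <- gamma_fission_B(al, tt, method = "talbot")
    expect_lt(max(abs(aB - bB) / bB), 1e-6)
  }
  # even integer alpha: the printed residue listing would double-count the
  # pole at angle pi; an explicit contour request warns and the exact
  # rational residue sum is returned
  expect_warning(v <- gamma_fission_T(2, 1, method = "contour"),
                 class = "agekin_contour_fallback")
  expect_equal(v, gamma_fission_T(2, 1, method = "residues"))
})

test_that("mean population is ordered in dispersion and enveloped", {
  als <- c(1, 2, 10, 100)
  for (t in c(1, 2, 3)) {
    Ts <- vapply(als, function(al) gamma_fission_T(al, t), numeric(1))
    expect_true(all(diff(Ts) <= 1e-10))          # nonincreasing in alpha
    # Galton-Watson floor: the synchronized process doubles just AFTER each
    # integer time, so the lower envelope at t is its left limit 2^floor(t-)
    expect_true(all(Ts >= 2^floor(t - 1e-9) - 1e-8))
    expect_true(all(Ts <= exp(t) + 1e-8))        # continuous compounding cap
  }
})

test_that("all four solution routes agree for Gamma fission", {
  tg <- seq(0, 3, by = 1e-3)
  tt <- seq(0.25, 3, by = 0.25)
  it <- round(tt / 1e-3) + 1L
  for (al in c(1, 2, 10)) {
    spf <- hazards_from_waiting_time(wt_gamma(al), 1)
    T1 <- fission_fields(solve_fission_B(spf, tg), spf)$Ttot[it]
    T2 <- bellman_harris_mean(wt_gamma(al), 1, tg)$T[it]
    T3 <- bellman_harris_mean_laplace(wt_gamma(al), 1)(tt)
    T4 <- gamma_fission_T(al, tt)
    for (pair in list(cbind(T1, T2), cbind(T1, T3), cbind(T1, T4),
                      cbind(T2, T3), cbind(T2, T4), cbind(T3, T4)))
      expect_lt(max(abs(pair[, 1] - pair[, 2]) / pair[, 2]), 1e-4)
  }
})
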