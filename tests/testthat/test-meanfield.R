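test_that("renewal fecundity matches closed-form benchmarks", {
  tg <- seq(0, 3, by = 1e-3)
  nob <- rate_spec(function(n, a) rep(0, length(a)),
                   function(n, a) rep(0.3, length(a)),
                   cum_birth = function(a) 0 * a,
                   cum_death = function(a) 0.3 * a)
  expect_equal(max(abs(solve_renewal_B(function(a) dexp(a), nob, tg)$B)), 0)
  B1 <- solve_renewal_B(list(point = 0), rates_constant(1, 0), tg)
  expect_lt(max(abs(B1$B - exp(tg)) / exp(tg)), 1e-6)
  B2 <- solve_renewal_B(list(point = 0), rates_constant(1, 0.5), tg)
  expect_lt(max(abs(B2$B - exp(0.5 * tg)) / exp(0.5 * tg)), 1e-6)
  # any unit-mass initial density gives the same e^t for constant hazards
  B3 <- solve_renewal_B(function(a) dexp(a), rates_constant(1, 0), tg)
  expect_lt(max(abs(B3$B - exp(tg)) / exp(tg)), 1e-6)
})

test_that("plain trapezoidal marching converges at second order", {
  sp <- rates_constant(1, 0.2)
  err <- vapply(c(4e-3, 2e-3, 1e-3), function(h) {
    tg <- seq(0, 2, by = h)
    B <- solve_renewal_B(list(point = 0), sp, tg, richardson = FALSE)
    max(abs(B$B - exp(0.8 * tg)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
  expect_lt(err[1] / err[2], 4.5)
})

test_that("McKendrick-von Foerster solution transports and renews mass", {
  tg <- seq(0, 1.5, by = 5e-3)
  ag <- seq(0, 25, by = 5e-3)
  # no births: pure transport-decay, no mass below a = t
  spd <- rates_constant(0, 0.4)
  f0 <- solve_mvf(function(a) dexp(a), spd, tg, ag)
  j <- length(tg)
  young <- ag < tg[j]
  expect_equal(max(f0$values[young, j]), 0)
  old <- ag > tg[j]                     # the a = t tie takes the renewal branch
  expect_equal(f0$values[old, j],
               dexp(ag[old] - tg[j]) * exp(-0.4 * tg[j]),
               tolerance = 1e-10)
  # along characteristics rho * U^{-1} is constant for beta = 0
  i0 <- 600; j0 <- 100
  r1 <- f0$values[i0, j0] * exp(0.4 * tg[j0])
  r2 <- f0$values[i0 + 100, j0 + 100] * exp(0.4 * tg[j0 + 100])
  expect_equal(r1, r2, tolerance = 1e-8)
  # constant birth: total population e^{beta t}
  sp <- rates_constant(1, 0)
  f1 <- solve_mvf(function(a) dexp(a), sp, tg, ag)
  h <- ag[2] - ag[1]
  tot <- colSums((f1$values[-1, ] + f1$values[-length(ag), ]) / 2) * h
  expect_lt(max(abs(tot - exp(tg)) / exp(tg)), 1e-4)
  # beta = mu: constant population
  spb <- rates_constant(0.7, 0.7)
  fb <- solve_mvf(function(a) dexp(a), spb, tg, ag)
  totb <- colSums((fb$values[-1, ] + fb$values[-length(ag), ]) / 2) * h
  expect_lt(max(abs(totb - 1)), 1e-3)
})

test_that("transform-inverted fecundity agrees with the marching solver", {
  tg <- seq(0, 3, by = 1e-3)
  tt <- seq(0.25, 3, by = 0.25)
  for (g0 in list(list(point = 0), function(a) dexp(a))) {
    sp <- rates_constant(1, 0)
    Bm <- solve_renewal_B(g0, sp, tg)
    Bl <- laplace_renewal_B(g0, sp)
    ref <- approx(tg, Bm$B, tt)$y
    expect_lt(max(abs(Bl(tt) - ref) / ref), 1e-4)
  }
  spm <- rates_constant(1, 0.5)
  Bm <- solve_renewal_B(list(point = 0), spm, tg)
  Bl <- laplace_renewal_B(list(point = 0), spm)
  ref <- approx(tg, Bm$B, tt)$y
  expect_lt(max(abs(Bl(tt) - ref) / ref), 1e-4)
})

test_that("master equation reproduces closed-form laws", {
  # pure death: binomial thinning of the initial size
  spd <- rates_constant(0, 0.8)
  ms <- solve_master_equation(spd, 12, 6L, c(0, 0.5, 1.5))
  p <- exp(-0.8 * 1.5)
  expect_equal(ms[3, 1:7], dbinom(0:6, 6, p), tolerance = 1e-8)
  expect_lt(max(abs(rowSums(ms) - 1)), 1e-8)
  # carrying capacity: support confined to 1..K
  spk <- rates_capacity(1, 5)
  mk <- solve_master_equation(spk, 8, 1L, c(0, 5))
  expect_lt(sum(mk[2, c(1, 7:9)]), 1e-10)
  # Yule: mean e^{beta t} to 1e-6
  spy <- rates_constant(1, 0)
  my <- solve_master_equation(spy, 200, 1L, seq(0, 2, by = 0.5))
  means <- as.vector(my %*% 0:200)
  expect_lt(max(abs(means - exp(seq(0, 2, by = 0.5))) / means), 1e-6)
  # age-dependent hazards are rejected
  expect_error(solve_master_equation(rates_linear_death(1), 10, 5L, c(0, 1)),
               "age-independent")
  # n_max too small is an error, not silent truncation
  expect_error(solve_master_equation(spy, 5, 1L, c(0, 2)), "n_max")
})

test_that("mean-field total equals the master-equation mean", {
  sp <- rates_constant(1, 0.5)
  tg <- seq(0, 1.5, by = 2e-3)
  ag <- seq(0, 25, by = 2e-3)
  f <- solve_mvf(function(a) dexp(a), sp, tg, ag)
  h <- ag[2] - ag[1]
  tot <- sum((f$values[-1, length(tg)] +
                f$values[-length(ag), length(tg)]) / 2) * h
  ms <- solve_master_equation(sp, 80, 1L, c(0, 1.5))
  expect_equal(tot, sum(ms[2, ] * 0:80), tolerance = 1e-4)
})
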