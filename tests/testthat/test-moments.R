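test_that("Stirling numbers match brute-force enumeration", {
  # S(3,2): set partitions of {1,2,3} into 2 blocks, enumerated
  expect_equal(stirling_second(3, 2), count_set_partitions(3, 2))
  expect_equal(stirling_second(3, 2), 3)
  expect_equal(stirling_second(4, 2), count_set_partitions(4, 2))
  # s(3,2): x^2 coefficient of x(x-1)(x-2), by polynomial expansion
  expect_equal(stirling_first(3, 2), falling_factorial_coefs(3)[3])
  expect_equal(stirling_first(3, 2), -3)
  for (l in 0:5) expect_equal(stirling_first(5, l),
                              falling_factorial_coefs(5)[l + 1])
  expect_equal(pochhammer(5, 2), 20)
  expect_equal(pochhammer(3, 0), 1)
  expect_error(stirling_first(2, 3))
})

test_that("factorial/raw moment maps invert exactly up to order 6", {
  set.seed(2)
  for (k in 1:6) {
    x <- as.numeric(sample(-9:9, k + 1, replace = TRUE))
    # integer-valued series: the Stirling maps are exact, bit for bit
    expect_identical(raw_to_factorial(factorial_to_raw(x)), x)
    expect_identical(factorial_to_raw(raw_to_factorial(x)), x)
    y <- rnorm(k + 1)
    expect_equal(raw_to_factorial(factorial_to_raw(y)), y,
                 tolerance = 1e-12)
  }
  expect_equal(factorial_to_raw(c(0, 7))[2], 7)          # Y1 = X1
  # Y2 = X2 + X1 (diagonal contraction: n^2 = (n)_2 + n)
  y <- factorial_to_raw(c(0, 1.5, 4))
  expect_equal(y[3], 4 + 1.5)
})

test_that("order-1 factorial moment field equals the mean-field density", {
  sp <- yule_spec()
  h <- 5e-3
  f1 <- solve_Xk(1, sp, function(a) dexp(a), t_final = 1.5, h = h)
  tg <- seq(0, 1.5, by = h)
  ag <- seq(0, 22, by = h)
  f <- solve_mvf(function(a) dexp(a), sp, tg, ag)
  expect_lt(max(abs(f1$eval(ag, 1.5) - f$values[, length(tg)])), 1e-8)
})

test_that("order-2 field matches the Yule-Furry closed form", {
  sp <- yule_spec()
  f2 <- solve_Xk(2, sp, function(a) dexp(a), t_final = 1.2, h = 0.015,
                 richardson = TRUE)
  as <- seq(0.03, 2.4, by = 0.06)
  g <- expand.grid(a = as, b = as)
  for (tt in c(0.6, 1.2)) {
    ref <- yule_furry_moments(1, 1, g$a, g$b, tt)$X2
    expect_lt(max(abs(f2$eval(g$a, g$b, tt) - ref)), 1e-4)
  }
  # symmetry under exchange of the age arguments
  expect_equal(f2$eval(g$a, g$b, 1.2), f2$eval(g$b, g$a, 1.2),
               tolerance = 1e-12)
})

test_that("zero death hazard freezes X^(k) along characteristics", {
  sp <- yule_spec()
  f2 <- solve_Xk(2, sp, function(a) dexp(a), t_final = 1, h = 0.02)
  # X2(a + s, b + s; t + s) = X2(a, b; t) when U = 1
  v1 <- f2$eval(0.3, 0.7, 0.5)
  v2 <- f2$eval(0.3 + 0.3, 0.7 + 0.3, 0.5 + 0.3)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("generalized transport residual shrinks at second order", {
  spm <- rates_constant(1, 0.4)
  resid <- vapply(c(0.04, 0.02), function(h) {
    f2 <- solve_Xk(2, spm, function(a) dexp(a), t_final = 1, h = h)
    # PDE: (d/dt + d/da + d/db) X2 = -(mu(a) + mu(b)) X2 along interior pts
    a <- 0.31; b <- 0.52; t <- 0.72; d <- h
    lhs <- (f2$eval(a + d, b + d, t + d) - f2$eval(a - d, b - d, t - d)) /
      (2 * d)
    abs(lhs + (0.4 + 0.4) * f2$eval(a, b, t))
  }, numeric(1))
  expect_gt(resid[1] / resid[2], 3)
})

test_that("Yule-Furry closed forms obey their regional structure", {
  # region t < a < b vanishes
  expect_equal(yule_furry_moments(1, 1, 1.2, 2, 0.5)$X2, 0)
  # region a < t < b, direct substitution
  expect_equal(yule_furry_moments(1, 1, 0.5, 2, 1)$X2, exp(-0.5),
               tolerance = 1e-12)
  # symmetry in the age pair
  expect_equal(yule_furry_moments(1, 1, 2, 0.5, 1)$X2, exp(-0.5),
               tolerance = 1e-12)
  # X1 continuity at a = t iff lambda = beta; jump |beta - lambda| otherwise
  lam <- 0.7; bet <- 1.3; t <- 0.9; eps <- 1e-9
  jump <- yule_furry_moments(lam, bet, t - eps, 1, t)$X1 -
    yule_furry_moments(lam, bet, t + eps, 1, t)$X1
  expect_equal(jump, bet - lam, tolerance = 1e-6)
  same <- yule_furry_moments(1, 1, t - eps, 1, t)$X1 -
    yule_furry_moments(1, 1, t + eps, 1, t)$X1
  expect_lt(abs(same), 1e-8)
})

test_that("window mean/variance closed forms have the right limits", {
  wm <- yule_furry_window_mean_var(1, 1, 0, Inf, 1)
  expect_equal(wm$mean, exp(1), tolerance = 1e-12)
  expect_equal(wm$var, exp(1) * (exp(1) - 1), tolerance = 1e-12)
  wm0 <- yule_furry_window_mean_var(1, 1, 0, Inf, 0)
  expect_equal(wm0$mean, 1)
  expect_equal(wm0$var, 0)
  # property sweep: a variance is nonnegative and respects the count bound
  for (lam in c(0.5, 1, 2)) for (bet in c(0.3, 1, 2))
    for (t in c(0.2, 1, 2.5)) for (w in list(c(0, 0.5), c(0.4, 1.5),
                                             c(1, 3), c(2.6, 4))) {
      v <- yule_furry_window_mean_var(lam, bet, w[1], w[2], t)
      expect_gte(v$var, -1e-12)
      expect_gte(v$var, v$mean - v$mean^2 - 1e-12)
    }
})

test_that("window moments from fields agree with closed forms", {
  sp <- yule_spec()
  f1 <- solve_Xk(1, sp, function(a) dexp(a), t_final = 1.5, h = 5e-3)
  f2 <- solve_Xk(2, sp, function(a) dexp(a), t_final = 1.5, h = 0.015,
                 richardson = TRUE)
  expect_equal(window_moments_from_fields(f1, f2, c(0.7, 0.7), 1),
               list(mean = 0, var = 0))
  for (w in list(c(0, Inf), c(0.5, 2), c(1.8, 3))) {
    wm <- window_moments_from_fields(f1, f2, w, 1.5)
    cf <- yule_furry_window_mean_var(1, 1, w[1], w[2], 1.5)
    expect_lt(abs(wm$mean - cf$mean) / cf$mean, 1e-3)
    expect_lt(abs(wm$var - cf$var) / cf$var, 1e-3)
  }
})

test_that("unsupported moment orders and models are rejected", {
  sp <- yule_spec()
  expect_error(solve_Xk(3, sp, function(a) dexp(a), t_final = 1, h = 0.1),
               "k = 1 and k = 2")
  expect_error(solve_Xk(1, rates_capacity(1, 5), function(a) dexp(a),
                        t_final = 1, h = 0.1), "size-independent")
})
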