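test_that("event-free models preserve the founders at every snapshot", {
  zero <- rate_spec(function(n, a) rep(0, length(a)),
                    function(n, a) rep(0, length(a)),
                    cum_birth = function(a) 0 * a,
                    cum_death = function(a) 0 * a,
                    next_event_age = function(a0, u) Inf)
  init <- population_state(0, singlets = -(0:6) / 10)
  tr <- simulate_budding(zero, init, 5, seed = 1, snapshots = c(1, 3, 5))
  expect_equal(nrow(tr$events), 0)
  for (s in tr$snapshots) expect_equal(sort(s$singlets), sort(init$singlets))
})

test_that("trajectories are bitwise reproducible under a fixed seed", {
  sp <- yule_spec()
  t1 <- simulate_budding(sp, population_state(0, 0), 2, seed = 99)
  t2 <- simulate_budding(sp, population_state(0, 0), 2, seed = 99)
  expect_identical(t1$events, t2$events)
  spk <- rates_capacity(1, 5)
  t3 <- simulate_budding(spk, population_state(0, 0), 3, seed = 5)
  t4 <- simulate_budding(spk, population_state(0, 0), 3, seed = 5)
  expect_identical(t3$events, t4$events)
  spf <- hazards_from_waiting_time(wt_gamma(10), 1)
  t5 <- simulate_fission_death(spf, population_state(0, 0), 3, seed = 7)
  t6 <- simulate_fission_death(spf, population_state(0, 0), 3, seed = 7)
  expect_identical(t5$events, t6$events)
})

test_that("linear-hazard death times match the closed-form survival", {
  spd <- rates_linear_death(1)
  R <- 20000
  ens <- simulate_ensemble(spd, population_state(0, 0), 1, R = R, seed = 31)
  alive <- mean(ensemble_counts(ens, 1))
  p <- exp(-0.5)
  expect_within_se(alive, p, sqrt(p * (1 - p) / R))
})

test_that("Yule-Furry growth matches its mean and variance", {
  sp <- yule_spec()
  R <- 20000
  ens <- simulate_ensemble(sp, population_state(0, 0), 1, R = R, seed = 17)
  cnt <- ensemble_counts(ens, 1)
  expect_within_se(mean(cnt), exp(1), sd(cnt) / sqrt(R))
  v <- var(cnt)
  m4 <- mean((cnt - mean(cnt))^4)
  expect_within_se(v, exp(1) * (exp(1) - 1),
                   sqrt((m4 - (R - 3) / (R - 1) * v^2) / R))
})

test_that("thinning and exact inversion sample the same first-event law", {
  # pure-death model with the Gamma(2,2) event hazard 4a/(1+2a): the
  # trajectory ends at its single event, whose time is the quantity compared
  w <- gamma2_wt()
  haz <- function(a) 4 * a / (1 + 2 * a)
  sp_inv <- rate_spec(function(n, a) rep(0, length(a)),
                      function(n, a) haz(a),
                      cum_birth = function(a) 0 * a,
                      cum_death = function(a) -log1p(-w$cdf(a)),
                      next_event_age = function(a0, u) {
                        S0 <- 1 - w$cdf(a0)
                        w$quantile(1 - S0 * u)
                      })
  sp_thin <- rate_spec(function(n, a) rep(0, length(a)),
                       function(n, a) haz(a),
                       bound = function(n) 2, size_dependent = TRUE)
  draw_first <- function(spec, method, R, seed) {
    ens <- simulate_ensemble(spec, population_state(0, 0), 12, R = R,
                             seed = seed, method = method,
                             record_events = TRUE)
    vapply(ens$events, function(e) if (nrow(e)) e$time[1] else NA_real_,
           numeric(1))
  }
  R <- 20000
  x <- draw_first(sp_inv, "inversion", R, 12)
  y <- draw_first(sp_thin, "thinning", R, 13)
  expect_lt(mean(is.na(x)) + mean(is.na(y)), 1e-3)
  ks <- suppressWarnings(stats::ks.test(x[!is.na(x)], y[!is.na(y)]))
  expect_gt(ks$p.value, 0.01)
  # and both agree with the waiting-time law itself
  ks2 <- suppressWarnings(stats::ks.test(x[!is.na(x)], w$cdf))
  expect_gt(ks2$p.value, 0.01)
})

test_that("carrying-capacity simulation matches the master-equation oracle", {
  spk <- rates_capacity(1, 5)
  R <- 20000
  ens <- simulate_ensemble(spk, population_state(0, 0), 5, R = R, seed = 21)
  cnt <- ensemble_counts(ens, 5)
  expect_true(all(cnt >= 1 & cnt <= 5))    # births forbidden above K
  ms <- solve_master_equation(spk, 8, 1L, c(0, 5))
  phat <- tabulate(cnt + 1L, nbins = 9) / R
  tv <- 0.5 * sum(abs(phat - ms[2, ]))
  se <- sqrt(max(phat * (1 - phat)) / R)
  expect_lt(tv, 4 * 5 * se)
})

test_that("bound violations are reported, never silently accepted", {
  bad <- rate_spec(function(n, a) rep(0, length(a)),
                   function(n, a) a,               # unbounded in age
                   bound = function(n) 0.5, size_dependent = TRUE)
  expect_error(simulate_budding(bad, population_state(0, 0), 10, seed = 2),
               "bound violated")
  nobound <- rate_spec(function(n, a) rep(n, length(a)),
                       function(n, a) rep(0, length(a)),
                       size_dependent = TRUE)
  expect_error(simulate_budding(nobound, population_state(0, 0), 1, seed = 2),
               "bound")
})

test_that("fission bookkeeping follows the four structural moves", {
  spf <- hazards_from_waiting_time(wt_exponential(1), 1)
  tr <- simulate_fission_death(spf, population_state(0, 0), 3, seed = 3)
  ev <- tr$events
  expect_true(all(diff(ev$time) >= 0))
  # every event changes the total count by exactly +1 (fission) or -1 (death)
  deltas <- diff(c(ev$n_before, length(tr$snapshots[[1]]$singlets) +
                     2 * length(tr$snapshots[[1]]$doublets)))
  expect_true(all(deltas[ev$kind == "fission"] == 1))
  expect_true(all(deltas[ev$kind == "death"] == -1))
  # pure death from a pair founder: pair -> singlet -> extinct
  spd <- hazards_from_waiting_time(wt_exponential(1), 0)
  trd <- simulate_fission_death(spd, population_state(0, doublets = 0), 50,
                                seed = 4)
  expect_equal(trd$events$kind, c("death", "death"))
  expect_equal(length(trd$snapshots[[1]]$singlets), 0)
  expect_equal(length(trd$snapshots[[1]]$doublets), 0)
})

test_that("critical fission keeps the mean population at one", {
  spc <- hazards_from_waiting_time(wt_exponential(1), 0.5)
  R <- 20000
  ens <- simulate_ensemble(spc, population_state(0, 0), 2, R = R, seed = 23)
  cnt <- ensemble_counts(ens, 2)
  expect_within_se(mean(cnt), 1, sd(cnt) / sqrt(R))
})

test_that("the fixed-step scheme approximates the exact sampler", {
  sp <- yule_spec()
  R <- 4000
  m <- numeric(R)
  for (r in seq_len(R)) {
    tr <- simulate_budding(sp, population_state(0, 0), 1, seed = 1000 + r,
                           method = "fixed-step", dt = 0.01,
                           record_events = FALSE)
    m[r] <- length(tr$snapshots[[1]]$singlets)
  }
  # biased at O(dt); only require closeness at the few-percent level
  expect_lt(abs(mean(m) - exp(1)) / exp(1), 0.05)
})

test_that("spatial diffusion is exact and decouples from event statistics", {
  zero <- rate_spec(function(n, a) rep(0, length(a)),
                    function(n, a) rep(0, length(a)),
                    cum_birth = function(a) 0 * a,
                    cum_death = function(a) 0 * a,
                    next_event_age = function(a0, u) Inf)
  R <- 10000
  ens <- simulate_ensemble(zero, function(r)
    population_state(0, 0, positions = 0), 1.5, R = R, seed = 41, D = 1)
  pos <- vapply(ens$states, function(s) s[[1]]$pos[1], numeric(1))
  v <- var(pos)
  m4 <- mean(pos^4)
  expect_within_se(v, 2 * 1.5, sqrt((m4 - v^2) / R))
  # D = 0 consumes no Gaussian draws: event stream identical to budding
  sp <- yule_spec()
  t1 <- simulate_spatial(sp, population_state(0, 0, positions = 0), D = 0,
                         t_final = 1, seed = 55)
  t2 <- simulate_budding(sp, population_state(0, 0), 1, seed = 55)
  expect_identical(t1$events[c("time", "kind", "parent_tob")],
                   t2$events[c("time", "kind", "parent_tob")])
  # position-independent hazards leave size statistics at Yule-Furry growth
  ens2 <- simulate_ensemble(sp, function(r)
    population_state(0, 0, positions = 0), 1, R = 10000, seed = 42, D = 1)
  cnt <- ensemble_counts(ens2, 1)
  expect_within_se(mean(cnt), exp(1), sd(cnt) / sqrt(10000))
})

test_that("ensemble estimators are normalized and symmetric", {
  zero <- rate_spec(function(n, a) rep(0, length(a)),
                    function(n, a) rep(0, length(a)),
                    cum_birth = function(a) 0 * a,
                    cum_death = function(a) 0 * a,
                    next_event_age = function(a0, u) Inf)
  init <- population_state(0, singlets = rep(0, 10))
  ens <- simulate_ensemble(zero, init, 1, R = 200, seed = 8)
  nd <- estimate_number_density(ens, 1)
  expect_equal(sum(nd$estimate), 1)
  expect_equal(nd$estimate[nd$n == 10], 1)
  wm <- estimate_window_count_moments(ens, 1, c(0, Inf))
  expect_equal(wm$mean, 10)
  expect_equal(wm$var, 0)
  # k = 2 marginal estimate is exactly symmetric
  spd <- rates_linear_death(1)
  mk <- function(r) population_state(0,
    singlets = -sample_initial_ages("gamma-unit", 10))
  ens2 <- simulate_ensemble(spd, mk, 2, R = 3000, seed = 9)
  ad2 <- estimate_marginal_age_density(ens2, 2, "all", k = 2,
                                       breaks = seq(0, 6, by = 0.5))
  expect_identical(ad2$estimate, t(ad2$estimate))
  # never-realized population size flags an empty estimate
  ad0 <- estimate_marginal_age_density(ens2, 2, n_filter = 25, k = 1,
                                       breaks = seq(0, 6, by = 0.5))
  expect_true(ad0$empty)
  # k = 1 estimate for fixed n integrates to the empirical P(n)
  nd2 <- estimate_number_density(ens2, 2)
  ad1 <- estimate_marginal_age_density(ens2, 2, n_filter = 1, k = 1,
                                       breaks = seq(0, 8, by = 0.25))
  expect_equal(sum(ad1$estimate * 0.25), nd2$estimate[nd2$n == 1],
               tolerance = 1e-10)
})
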