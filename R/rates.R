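#' Define an age-structured hazard model
#'
#' A `rate_spec` bundles the per-individual birth (or fission) hazard
#' \eqn{\beta_n(a)} and death hazard \eqn{\mu_n(a)} that define a stochastic
#' age-structured population model.  Hazards may depend on the population size
#' `n` (e.g. a carrying capacity) and on the individual's age `a`; the total
#' event hazard is \eqn{\gamma_n(a) = \beta_n(a) + \mu_n(a)}.
#'
#' Internally all simulator state is stored as times of birth (TOB,
#' \eqn{b = t - a}); ages are derived quantities.  TOB is constant along the
#' characteristics of the transport equations, which keeps both the samplers
#' and the deterministic solvers simple.
#'
#' @param birth function `(n, a)` returning the birth/fission hazard per unit
#'   time; must be vectorized over `a` and nonnegative.
#' @param death function `(n, a)` returning the death hazard, same contract.
#' @param progeny optional numeric pair `c(h0, h2)` of progeny probabilities
#'   for binary fission models: an event is a fission into two age-zero twins
#'   with probability `h2` and a death with probability `h0`; must sum to 1.
#'   `NULL` for budding models.
#' @param bound optional function `(n)` returning a finite upper bound on
#'   \eqn{\gamma_n(a)} over all ages.  Required by the thinning sampler
#'   whenever hazards are size-dependent.
#' @param size_dependent logical; do the hazards depend on `n`?
#' @param age_independent logical; are the hazards constant in `a`?  Enables
#'   the master-equation oracle and a tight thinning bound.
#' @param cum_birth,cum_death optional closed-form cumulative hazards
#'   \eqn{\int_0^a \beta}, \eqn{\int_0^a \mu} as functions of `a`
#'   (size-independent models only).  When absent, integrals are computed by
#'   adaptive Gauss-Kronrod quadrature (`stats::integrate`, absolute tolerance
#'   `1e-10`).
#' @param next_event_age optional function `(a0, u)` mapping a current age and
#'   a uniform variate to the age at the next event, i.e. the solution `A` of
#'   \eqn{\exp[-\int_{a_0}^{A} \gamma] = u}.  Supplying a closed form gives the
#'   exact-inversion sampler a fast path; otherwise the integrated hazard is
#'   inverted numerically.
#' @param waiting optional [waiting_time_spec()] the hazards were derived from
#'   (see [hazards_from_waiting_time()]).
#' @param label short human-readable model label used in metadata.
#'
#' @return An object of class `"rate_spec"`.
#' @seealso [rates_constant()], [rates_linear_death()], [rates_capacity()],
#'   [hazards_from_waiting_time()]
#' @export
rate_spec <- function(birth, death, progeny = NULL, bound = NULL,
                      size_dependent = FALSE, age_independent = FALSE,
                      cum_birth = NULL, cum_death = NULL,
                      next_event_age = NULL, waiting = NULL,
                      label = "custom") {
  stopifnot(is.function(birth), is.function(death))
  if (!is.null(progeny)) {
    if (length(progeny) != 2L || any(progeny < 0) || any(progeny > 1) ||
        abs(sum(progeny) - 1) > 1e-12)
      stop("'progeny' must be probabilities c(h0, h2) summing to 1")
    names(progeny) <- c("h0", "h2")
  }
  structure(list(birth = birth, death = death, progeny = progeny,
                 bound = bound, size_dependent = isTRUE(size_dependent),
                 age_independent = isTRUE(age_independent),
                 cum_birth = cum_birth, cum_death = cum_death,
                 next_event_age = next_event_age, waiting = waiting,
                 label = label),
            class = "rate_spec")
}

#' @export
print.rate_spec <- function(x, ...) {
  cat("<rate_spec>", x$label, "\n")
  cat("  size-dependent:", x$size_dependent,
      " age-independent:", x$age_independent, "\n")
  if (!is.null(x$progeny))
    cat("  fission model: h0 =", x$progeny[["h0"]],
        ", h2 =", x$progeny[["h2"]], "\n")
  invisible(x)
}

#' Constant-hazard model
#'
#' Birth and death hazards independent of age and population size.  With
#' `mu0 = 0` this is the Yule-Furry pure birth process.
#'
#' @param beta0,mu0 nonnegative rates per unit time.
#' @param progeny optional `c(h0, h2)` to interpret events as fission (see
#'   [rate_spec()]).
#' @return A `"rate_spec"`.
#' @export
rates_constant <- function(beta0, mu0 = 0, progeny = NULL) {
  stopifnot(beta0 >= 0, mu0 >= 0)
  g0 <- beta0 + mu0
  rate_spec(
    birth = function(n, a) rep_len(beta0, length(a)),
    death = function(n, a) rep_len(mu0, length(a)),
    progeny = progeny,
    bound = function(n) g0,
    size_dependent = FALSE, age_independent = TRUE,
    cum_birth = function(a) beta0 * a,
    cum_death = function(a) mu0 * a,
    next_event_age = function(a0, u) if (g0 <= 0) Inf else a0 - log(u) / g0,
    label = sprintf("constant(beta=%g, mu=%g)", beta0, mu0))
}

#' Linear death hazard model
#'
#' Death hazard \eqn{\mu(a) = c\,a} growing linearly with age, plus an
#' optional constant birth hazard.  The survival of an individual from age 0
#' to age `a` under the pure-death model is `exp(-c a^2/2)`.
#'
#' @param slope slope `c` of the death hazard (per unit time squared).
#' @param beta0 constant birth hazard (default 0: pure death).
#' @return A `"rate_spec"`.
#' @export
rates_linear_death <- function(slope = 1, beta0 = 0) {
  stopifnot(slope >= 0, beta0 >= 0)
  rate_spec(
    birth = function(n, a) rep_len(beta0, length(a)),
    death = function(n, a) slope * a,
    size_dependent = FALSE, age_independent = FALSE,
    cum_birth = function(a) beta0 * a,
    cum_death = function(a) slope * a^2 / 2,
    # solve slope*(A^2 - a0^2)/2 + beta0*(A - a0) = -log(u)
    next_event_age = function(a0, u) {
      e <- -log(u)
      if (e == Inf) return(Inf)
      if (slope == 0) return(if (beta0 <= 0) Inf else a0 + e / beta0)
      b <- beta0 / slope
      sqrt((a0 + b)^2 + 2 * e / slope) - b
    },
    label = sprintf("linear-death(slope=%g, beta=%g)", slope, beta0))
}

#' Carrying-capacity birth hazard
#'
#' The logistic per-capita birth rate \eqn{\beta_n = \beta_0 (1 - n/K)},
#' clamped below at zero (a hazard is nonnegative by definition; `K` acts as a
#' population ceiling).
#'
#' @param beta0 intrinsic birth rate (nonnegative).
#' @param K carrying capacity, `K > 0`.
#' @param n population size count (vectorized).
#' @return Birth rate per individual per unit time.
#' @export
carrying_capacity_birth <- function(beta0, K, n) {
  if (!is.numeric(K) || K <= 0) stop("'K' must be a positive capacity")
  stopifnot(beta0 >= 0, all(n >= 0))
  pmax(0, beta0 * (1 - n / K))
}

#' Carrying-capacity budding model
#'
#' Age-independent, size-dependent model with birth rate
#' [carrying_capacity_birth()] and constant death rate.
#'
#' @inheritParams carrying_capacity_birth
#' @param mu0 constant death rate.
#' @return A `"rate_spec"` (size-dependent; thinning bound supplied).
#' @export
rates_capacity <- function(beta0, K, mu0 = 0) {
  if (!is.numeric(K) || K <= 0) stop("'K' must be a positive capacity")
  stopifnot(beta0 >= 0, mu0 >= 0)
  rate_spec(
    birth = function(n, a) rep_len(carrying_capacity_birth(beta0, K, n), length(a)),
    death = function(n, a) rep_len(mu0, length(a)),
    bound = function(n) carrying_capacity_birth(beta0, K, n) + mu0,
    size_dependent = TRUE, age_independent = TRUE,
    label = sprintf("capacity(beta0=%g, K=%g, mu=%g)", beta0, K, mu0))
}

#' Define a waiting-time distribution
#'
#' Inter-event time density `g` with CDF `G`, used by fission-type models in
#' which each individual's event time is drawn from `g` and the event is a
#' binary fission with probability `h2` or a death with probability
#' `h0 = 1 - h2`.
#'
#' @param density function `g(tau)`, a probability density on `[0, Inf)`.
#' @param cdf function `G(t) = int_0^t g`.
#' @param quantile optional quantile function (inverse CDF); enables exact
#'   event-time inversion in the simulator.
#' @param laplace optional Laplace transform `g~(s)` accepting complex `s`
#'   (analytic continuation); enables Talbot inversion in the mean-field
#'   solvers.
#' @param mean optional mean of the distribution (metadata).
#' @param label short label.
#' @return An object of class `"waiting_time_spec"`.
#' @export
waiting_time_spec <- function(density, cdf, quantile = NULL, laplace = NULL,
                              mean = NULL, label = "custom") {
  stopifnot(is.function(density), is.function(cdf))
  structure(list(density = density, cdf = cdf, quantile = quantile,
                 laplace = laplace, mean = mean, label = label),
            class = "waiting_time_spec")
}

#' @export
print.waiting_time_spec <- function(x, ...) {
  cat("<waiting_time_spec>", x$label, "\n")
  invisible(x)
}

#' Exponential waiting times
#' @param rate rate parameter (mean `1/rate`).
#' @return A `"waiting_time_spec"`.
#' @export
wt_exponential <- function(rate = 1) {
  stopifnot(rate > 0)
  waiting_time_spec(
    density = function(tau) stats::dexp(tau, rate),
    cdf = function(t) stats::pexp(t, rate),
    quantile = function(p) stats::qexp(p, rate),
    laplace = function(s) rate / (rate + s),
    mean = 1 / rate,
    label = sprintf("exponential(rate=%g)", rate))
}

#' Gamma waiting times with unit mean
#'
#' Gamma density with shape and rate both `alpha`, so the mean is 1 and the
#' variance `1/alpha`.  Large `alpha` concentrates events near integer
#' multiples of the mean (the Galton-Watson limit); `alpha = 1` is the
#' exponential (Markovian) case.
#'
#' @param alpha shape/rate parameter (`alpha > 0`).
#' @return A `"waiting_time_spec"` with a complex-capable Laplace transform
#'   \eqn{\tilde g(s) = (\alpha/(\alpha+s))^\alpha}.
#' @export
wt_gamma <- function(alpha) {
  stopifnot(alpha > 0)
  waiting_time_spec(
    density = function(tau) stats::dgamma(tau, shape = alpha, rate = alpha),
    cdf = function(t) stats::pgamma(t, shape = alpha, rate = alpha),
    quantile = function(p) stats::qgamma(p, shape = alpha, rate = alpha),
    laplace = function(s) exp(alpha * (log(alpha) - log(alpha + s))),
    mean = 1,
    label = sprintf("gamma(alpha=%g)", alpha))
}

#' Convert a waiting-time distribution to hazards
#'
#' Builds the size-independent hazard pair corresponding to a renewal-type
#' individual whose next event time is distributed with density `g`:
#' \deqn{\beta(a) = h_2\, g(a) / (1 - G(a)), \qquad
#'       \mu(a) = h_0\, g(a) / (1 - G(a)).}
#' The total-event propagator of the returned model satisfies
#' \eqn{U(x; x, t) = 1 - G(t - x)}, i.e. the no-event probability equals the
#' waiting-time survival.
#'
#' @param w a [waiting_time_spec()].
#' @param h2 fission probability at an event (`h0 = 1 - h2`).
#' @return A `"rate_spec"` with `progeny = c(1 - h2, h2)`.
#' @export
hazards_from_waiting_time <- function(w, h2) {
  stopifnot(inherits(w, "waiting_time_spec"), h2 >= 0, h2 <= 1)
  g <- w$density; G <- w$cdf; Q <- w$quantile
  haz <- function(a) {
    S <- 1 - G(a)
    if (any(S <= 0 & g(a) > 0))
      stop("waiting-time CDF reaches 1 inside the requested range: ",
           "hazard undefined beyond the support edge")
    ifelse(S > 0, g(a) / S, 0)
  }
  nea <- if (!is.null(Q)) {
    function(a0, u) {
      S0 <- 1 - G(a0)
      if (S0 <= 0) return(a0)          # at the support edge: immediate event
      Q(1 - S0 * u)
    }
  } else NULL
  rate_spec(
    birth = function(n, a) h2 * haz(a),
    death = function(n, a) (1 - h2) * haz(a),
    progeny = c(1 - h2, h2),
    size_dependent = FALSE, age_independent = FALSE,
    cum_birth = function(a) -h2 * log1p(-G(a)),
    cum_death = function(a) -(1 - h2) * log1p(-G(a)),
    next_event_age = nea,
    waiting = w,
    label = sprintf("waiting-time(%s, h2=%g)", w$label, h2))
}

# ---- cumulative hazards and the propagator --------------------------------

# integral of the given hazard (one of "birth", "death", "total") from age a0
# to age a1, for population size n.  Uses closed forms when the spec carries
# them; otherwise adaptive Gauss-Kronrod quadrature with abs.tol 1e-10.
cumulative_hazard <- function(spec, which, n, a0, a1) {
  stopifnot(a1 >= a0)
  if (a1 == a0) return(0)
  if (!spec$size_dependent) {
    if (which == "death" && is.function(spec$cum_death))
      return(spec$cum_death(a1) - spec$cum_death(a0))
    if (which == "birth" && is.function(spec$cum_birth))
      return(spec$cum_birth(a1) - spec$cum_birth(a0))
    if (which == "total" && is.function(spec$cum_birth) &&
        is.function(spec$cum_death))
      return(spec$cum_birth(a1) - spec$cum_birth(a0) +
             spec$cum_death(a1) - spec$cum_death(a0))
  }
  h <- switch(which,
    death = function(a) spec$death(n, a),
    birth = function(a) spec$birth(n, a),
    total = function(a) spec$birth(n, a) + spec$death(n, a))
  val <- h(c(a0, a1, (a0 + a1) / 2))
  if (any(val < 0)) stop("negative hazard encountered during quadrature")
  stats::integrate(h, a0, a1, abs.tol = 1e-10, rel.tol = 1e-10,
                   stop.on.error = TRUE)$value
}

#' Survival propagator over a time interval
#'
#' Returns \eqn{U = \exp(-\int_{t_0}^{t_1} h(s - b)\, ds)} for an individual
#' born at time `b`, where `h` is the death hazard (`which = "death"`, the
#' probability of not dying) or the total event hazard
#' \eqn{\gamma_n = \beta_n + \mu_n} (`which = "total"`, the probability of
#' experiencing no event at all).  The propagator is multiplicative over
#' abutting intervals and factorizes over individuals.
#'
#' @param spec a [rate_spec()].
#' @param n population size at which the hazards are evaluated.
#' @param b time of birth (`b <= t0`).
#' @param t0,t1 interval endpoints, `t0 <= t1`.
#' @param which `"death"` or `"total"`.
#' @return A probability in `(0, 1]`.
#' @export
propagator <- function(spec, n = 1, b = 0, t0, t1,
                       which = c("death", "total")) {
  which <- match.arg(which)
  stopifnot(inherits(spec, "rate_spec"), t0 <= t1, b <= t0)
  H <- cumulative_hazard(spec, which, n, t0 - b, t1 - b)
  if (H < 0) stop("negative integrated hazard: invalid model")
  exp(-H)
}

# vectorized survival from age 0 to ages a under the total-event hazard
# (size-independent models); used by the mean-field fission solvers.
total_survival <- function(spec, a) {
  if (!is.null(spec$waiting)) return(pmax(0, 1 - spec$waiting$cdf(a)))
  if (is.function(spec$cum_birth) && is.function(spec$cum_death))
    return(exp(-(spec$cum_birth(a) + spec$cum_death(a))))
  vapply(a, function(ai) propagator(spec, 1, 0, 0, ai, "total"), numeric(1))
}

# vectorized death-only survival U(a0, a1) (age a0 to a1), size-independent
death_survival <- function(spec, a0, a1) {
  if (is.function(spec$cum_death))
    return(exp(-(spec$cum_death(a1) - spec$cum_death(a0))))
  mapply(function(x, y) propagator(spec, 1, 0, x, y, "death"), a0, a1)
}

# numeric inversion of the integrated total hazard when no closed form is
# available: solve int_{a0}^{A} gamma = -log(u)
invert_event_age <- function(spec, a0, u) {
  if (!is.null(spec$next_event_age)) return(spec$next_event_age(a0, u))
  e <- -log(u)
  if (!is.finite(e)) return(Inf)
  f <- function(A) cumulative_hazard(spec, "total", 1, a0, A) - e
  hi <- a0 + 1
  while (f(hi) < 0) {
    hi <- a0 + (hi - a0) * 2
    if (hi - a0 > 1e6) return(Inf)
  }
  stats::uniroot(f, c(a0, hi), tol = 1e-12)$root
}

#' Sample initial (founder) ages
#'
#' Draws i.i.d. founder ages from one of the built-in initial-age
#' distributions: `"gamma-unit"` is the Gamma(shape 4, rate 4) density
#' \eqn{P(a) = 128 a^3 e^{-4a}/3} with unit mean and standard deviation 1/2;
#' `"exponential"` has the given `rate` (mean `1/rate`); `"point"` is a point
#' mass at `a0`.
#'
#' @param dist one of `"gamma-unit"`, `"exponential"`, `"point"`.
#' @param count number of founders.
#' @param rate rate of the exponential (mean `1/rate`).
#' @param a0 location of the point mass.
#' @return Numeric vector of `count` nonnegative ages (uses the current RNG
#'   state; call `set.seed()` for reproducibility).
#' @export
sample_initial_ages <- function(dist = c("gamma-unit", "exponential", "point"),
                                count, rate = 1, a0 = 0) {
  dist <- match.arg(dist)
  stopifnot(count >= 0)
  switch(dist,
    "gamma-unit" = stats::rgamma(count, shape = 4, rate = 4),
    "exponential" = stats::rexp(count, rate),
    "point" = rep_len(a0, count))
}
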