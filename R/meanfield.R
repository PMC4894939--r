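#' Rectangular field on age/TOB-by-time grids
#'
#' A function of age (or TOB) and time sampled on uniform grids.  The two
#' conventions are related by `b = t - a`, which is lossless on matched grids.
#'
#' @param axis numeric age or TOB grid (uniform, increasing).
#' @param t numeric time grid (uniform, increasing).
#' @param values matrix `length(axis)` by `length(t)`.
#' @param convention `"age"` or `"tob"`.
#' @return An object of class `"grid_field"`.
#' @export
grid_field <- function(axis, t, values, convention = c("age", "tob")) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(values), nrow(values) == length(axis),
            ncol(values) == length(t), all(is.finite(values)))
  if (length(axis) > 1) stopifnot(diff(range(diff(axis))) < 1e-9 * max(diff(axis)))
  if (length(t) > 1) stopifnot(diff(range(diff(t))) < 1e-9 * max(diff(t)))
  structure(list(axis = axis, t = t, values = values,
                 convention = convention),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat("<grid_field>", x$convention, "grid", length(x$axis), "x",
      length(x$t), "\n")
  invisible(x)
}

check_uniform <- function(g, name) {
  h <- diff(g)
  if (length(h) < 1 || any(h <= 0) || diff(range(h)) > 1e-9 * h[1])
    stop("'", name, "' must be a uniform increasing grid")
  h[1]
}

# cumulative trapezoid of y over uniform grid with step h (starts at 0)
cumtrapz <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * h))
}

# truncation point for an initial density: smallest grid age beyond which the
# remaining mass is below `tol` (cap at `amax`)
density_cutoff <- function(g0, h, tol = 1e-10, amax = 200) {
  A <- 10
  repeat {
    a <- seq(0, A, by = h)
    g <- g0(a)
    mass <- cumtrapz(g, h)
    total <- mass[length(mass)]
    # converged when the density itself and the residual mass are negligible
    scale <- max(total, 1)
    i <- which(total - mass < tol * scale)
    if (length(i) && g[length(g)] < tol * scale / max(A, 1))
      return(a[i[1]])
    if (A >= amax) {
      warning("initial-age density truncated at a = ", A,
              " with unresolved tail")
      return(A)
    }
    A <- min(2 * A, amax)
  }
}

# marching product-trapezoidal Volterra solver for
#   B(t) = int_0^t B(t - a) K(a) da + F(t)
# K, Fv given on the uniform grid (same step).
march_volterra <- function(K, Fv, h) {
  M <- length(Fv)
  B <- numeric(M)
  B[1] <- Fv[1]
  denom <- 1 - 0.5 * h * K[1]
  for (i in 2:M) {
    m <- i - 1L
    conv <- 0.5 * B[1] * K[i]
    if (m >= 2) conv <- conv + sum(B[i - seq_len(m - 1)] * K[1 + seq_len(m - 1)])
    B[i] <- (Fv[i] + h * conv) / denom
  }
  B
}

#' Volterra renewal equation for the fecundity B(t)
#'
#' Solves the renewal equation for the rate of age-0 arrivals in the budding
#' birth-death mean field,
#' \deqn{B(t) = \int_0^t B(t-a)\,U(0,a)\,\beta(a)\, da
#'       + \int_0^\infty g_0(a)\, U(a, a+t)\, \beta(a+t)\, da,}
#' where `U` is the death-only propagator, by product-trapezoidal marching on
#' a uniform grid.  By default a single Richardson extrapolation step (grids
#' `h` and `h/2`) removes the leading `O(h^2)` error term.
#'
#' @param g0 initial age density: a function, or `list(point = a0, weight =
#'   w)` for `w` founders of exact age `a0`.
#' @param spec a size-independent [rate_spec()].
#' @param t_grid uniform time grid starting at 0.
#' @param richardson logical: extrapolate over grids `h` and `h/2`.
#' @return An object of class `"volterra_solution"` with elements `t`, `B`,
#'   `h`, `rule`, `cutoff` (initial-density truncation age, if any) and
#'   `model`.
#' @export
solve_renewal_B <- function(g0, spec, t_grid, richardson = TRUE) {
  stopifnot(inherits(spec, "rate_spec"))
  if (spec$size_dependent)
    stop("mean-field solvers require size-independent hazards")
  if (t_grid[1] != 0) stop("'t_grid' must start at 0")
  h <- check_uniform(t_grid, "t_grid")
  sol <- renewal_on_grid(g0, spec, t_grid, h)
  if (richardson) {
    t2 <- seq(0, t_grid[length(t_grid)], by = h / 2)
    sol2 <- renewal_on_grid(g0, spec, t2, h / 2)
    B <- (4 * sol2$B[seq(1, length(t2), by = 2)] - sol$B) / 3
  } else B <- sol$B
  structure(list(t = t_grid, B = B, h = h,
                 rule = if (richardson) "product-trapezoidal+richardson"
                        else "product-trapezoidal",
                 cutoff = sol$cutoff, model = spec$label),
            class = "volterra_solution")
}

renewal_on_grid <- function(g0, spec, t_grid, h) {
  tmax <- t_grid[length(t_grid)]
  K <- death_survival(spec, 0, t_grid) * spec$birth(1, t_grid)
  if (any(K < 0)) stop("negative hazard encountered")
  cutoff <- NA_real_
  if (is.function(g0)) {
    A <- density_cutoff(g0, h)
    cutoff <- A
    a <- seq(0, A, by = h)
    g0v <- g0(a)
    # cumulative death hazard on the combined grid [0, A + tmax]
    full <- seq(0, A + tmax + h, by = h)
    Md <- if (is.function(spec$cum_death)) spec$cum_death(full)
          else cumtrapz(spec$death(1, full), h)
    if (any(diff(Md) < -1e-12)) stop("negative hazard encountered")
    bfull <- spec$birth(1, full)
    na <- length(a)
    Fv <- vapply(seq_along(t_grid), function(i) {
      idx <- seq_len(na) + (i - 1L)
      integrand <- g0v * exp(-(Md[idx] - Md[seq_len(na)])) * bfull[idx]
      sum((integrand[-1] + integrand[-na]) / 2) * h
    }, numeric(1))
  } else if (is.list(g0) && !is.null(g0$point)) {
    w <- if (is.null(g0$weight)) 1 else g0$weight
    a0 <- g0$point
    Fv <- w * death_survival(spec, a0, a0 + t_grid) * spec$birth(1, a0 + t_grid)
  } else stop("'g0' must be a density function or list(point=, weight=)")
  list(B = march_volterra(K, Fv, h), cutoff = cutoff)
}

#' @export
print.volterra_solution <- function(x, ...) {
  cat("<volterra_solution>", length(x$t), "nodes, h =", x$h, ",", x$rule, "\n")
  invisible(x)
}

#' McKendrick-von Foerster solution by characteristics
#'
#' Solves the transport equation
#' \eqn{\partial_t \rho + \partial_a \rho = -\mu(a) \rho} with renewal
#' boundary \eqn{\rho(0, t) = B(t)} and initial density `g0`:
#' \deqn{\rho(a,t) = B(t-a)\, U(0,a) \ (a < t), \qquad
#'       \rho(a,t) = g_0(a-t)\, U(a-t, a) \ (a > t).}
#'
#' @param g0 initial age density (function; point masses are not densities
#'   and are rejected here -- use [solve_renewal_B()] directly for founders of
#'   exact age).
#' @param spec a size-independent [rate_spec()].
#' @param t_grid,a_grid uniform grids (time starting at 0).
#' @param richardson passed to [solve_renewal_B()].
#' @return A `"grid_field"` (age convention) of the expected age density,
#'   with the fecundity solution attached as attribute `"B"`.
#' @export
solve_mvf <- function(g0, spec, t_grid, a_grid, richardson = TRUE) {
  stopifnot(is.function(g0))
  if (spec$size_dependent)
    stop("mean-field solvers require size-independent hazards")
  ha <- check_uniform(a_grid, "a_grid")
  ht <- check_uniform(t_grid, "t_grid")
  Bsol <- solve_renewal_B(g0, spec, t_grid, richardson = richardson)
  Bfun <- stats::approxfun(Bsol$t, Bsol$B, rule = 2)
  vals <- matrix(0, length(a_grid), length(t_grid))
  for (j in seq_along(t_grid)) {
    t <- t_grid[j]
    young <- a_grid <= t   # at the a = t tie the renewal branch applies
    if (any(young)) {
      a <- a_grid[young]
      vals[young, j] <- Bfun(t - a) * death_survival(spec, 0, a)
    }
    if (any(!young)) {
      a <- a_grid[!young]
      vals[!young, j] <- g0(a - t) * death_survival(spec, a - t, a)
    }
  }
  out <- grid_field(a_grid, t_grid, vals, "age")
  attr(out, "B") <- Bsol
  out
}

#' Renewal fecundity by Laplace transform inversion
#'
#' Evaluates the closed transform solution of the renewal equation,
#' \deqn{\hat B(s) = \frac{\int_0^\infty g_0(a)\,
#'   \mathcal{L}\{U(a,a+t)\beta(a+t)\}(s)\, da}{1 -
#'   \mathcal{L}\{U(0,t)\beta(t)\}(s)},}
#' computing both transforms by adaptive quadrature at real `s` and inverting
#' with the Gaver-Stehfest method, which requires only real positive
#' transform evaluations and therefore works for numerically defined hazard
#' models (a complex-contour method would require analytic continuations that
#' a black-box hazard cannot supply).
#'
#' @inheritParams solve_renewal_B
#' @param n even number of Stehfest terms.
#' @return A vectorized function `B(t)`.
#' @export
laplace_renewal_B <- function(g0, spec, n = 14L) {
  stopifnot(inherits(spec, "rate_spec"))
  if (spec$size_dependent)
    stop("mean-field solvers require size-independent hazards")
  Kfun <- function(tt) death_survival(spec, 0, tt) * spec$birth(1, tt)
  den <- function(s)
    stats::integrate(function(tt) exp(-s * tt) * Kfun(tt), 0, Inf,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  if (is.function(g0)) {
    h0 <- 1e-3
    A <- density_cutoff(g0, h0)
    a <- seq(0, A, by = h0)
    g0v <- g0(a)
    F0 <- function(tt)
      vapply(tt, function(t1) {
        integrand <- g0v * death_survival(spec, a, a + t1) *
          spec$birth(1, a + t1)
        sum((integrand[-1] + integrand[-length(a)]) / 2) * h0
      }, numeric(1))
  } else if (is.list(g0) && !is.null(g0$point)) {
    w <- if (is.null(g0$weight)) 1 else g0$weight
    a0 <- g0$point
    F0 <- function(tt) w * death_survival(spec, a0, a0 + tt) *
      spec$birth(1, a0 + tt)
  } else stop("'g0' must be a density function or list(point=, weight=)")
  num <- function(s)
    stats::integrate(function(tt) exp(-s * tt) * F0(tt), 0, Inf,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  Bhat <- function(s) {
    d <- 1 - den(s)
    if (abs(d) < 1e-12)
      stop("renewal denominator vanishes at s = ", s,
           " (Malthusian pole on a quadrature node)")
    num(s) / d
  }
  # Gaver-Stehfest nodes are k log(2)/t > 0, so a supercritical model (the
  # Malthusian root lambda* of L{U beta}(s) = 1 positive) must be shifted:
  # invert Bhat(s + lambda*) and restore the factor exp(lambda* t).
  cshift <- malthusian_root(den)
  function(t)
    exp(cshift * t) *
      invert_stehfest(function(s) Bhat(s + cshift), t, n = n)
}

# positive root of den(s) = 1 (den decreasing in s); 0 when sub/critical.
# Bisection that treats a divergent transform integral as "value above 1".
malthusian_root <- function(den) {
  dsafe <- function(s) tryCatch(den(s), error = function(e) Inf)
  lo <- 1e-6
  if (dsafe(lo) <= 1) return(0)
  hi <- 1
  while (dsafe(hi) > 1) {
    hi <- 2 * hi
    if (hi > 1e6) stop("no Malthusian root below 1e6")
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (dsafe(mid) > 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Master equation for age-independent rates
#'
#' Integrates the forward master equation for the population-size
#' probabilities under age-independent (possibly size-dependent) per-capita
#' rates \eqn{\beta_n, \mu_n}:
#' \deqn{\dot\rho_n = -n(\beta_n+\mu_n)\rho_n + (n-1)\beta_{n-1}\rho_{n-1}
#'       + (n+1)\mu_{n+1}\rho_{n+1}.}
#' Serves as the exact oracle for the event-driven simulator whenever the
#' hazards do not depend on age.
#'
#' @param spec an age-independent [rate_spec()].
#' @param n_max truncation size; the solution must keep negligible mass at
#'   the boundary (checked: mass at `n_max` must stay below `1e-6`).
#' @param init integer initial population size, or a probability vector over
#'   `0:n_max`.
#' @param t_grid output times (first element 0).
#' @return A matrix (rows = times, columns `n = 0:n_max`) of probabilities
#'   with attribute `"t"`; class `"master_solution"`.
#' @export
solve_master_equation <- function(spec, n_max, init, t_grid) {
  stopifnot(inherits(spec, "rate_spec"), n_max >= 1)
  if (!spec$age_independent)
    stop("the master equation applies only to age-independent hazards")
  if (t_grid[1] != 0) stop("'t_grid' must start at 0")
  ns <- 0:n_max
  rb <- vapply(ns, function(n) n * spec$birth(n, 0), numeric(1))
  rd <- vapply(ns, function(n) n * spec$death(n, 0), numeric(1))
  if (any(rb < 0) || any(rd < 0)) stop("negative rates")
  N <- n_max + 1L
  p0 <- if (length(init) == 1L) {
    stopifnot(init >= 0, init <= n_max)
    replace(numeric(N), init + 1L, 1)
  } else {
    stopifnot(length(init) == N, all(init >= 0), abs(sum(init) - 1) < 1e-10)
    as.numeric(init)
  }
  deriv <- function(t, p, parms) {
    dp <- -(rb + rd) * p
    dp[2:N] <- dp[2:N] + rb[1:(N - 1)] * p[1:(N - 1)]
    dp[1:(N - 1)] <- dp[1:(N - 1)] + rd[2:N] * p[2:N]
    list(dp)
  }
  sol <- deSolve::ode(y = p0, times = t_grid, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  probs <- unname(sol[, -1, drop = FALSE])
  if (max(probs[, N]) > 1e-6)
    stop("probability mass at the n_max boundary exceeds 1e-6; ",
         "increase n_max")
  if (any(abs(rowSums(probs) - 1) > 1e-8))
    stop("master-equation probabilities do not sum to 1 within 1e-8")
  probs <- pmax(probs, 0)
  structure(probs, t = t_grid, n = ns, class = "master_solution")
}

#' @export
print.master_solution <- function(x, ...) {
  cat("<master_solution>", length(attr(x, "t")), "times, n up to",
      max(attr(x, "n")), "\n")
  invisible(x)
}
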