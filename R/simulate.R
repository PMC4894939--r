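#' Population state
#'
#' The full state of an age-structured population at time `t`, stored in the
#' time-of-birth (TOB) representation `b = t - a`.  For budding models every
#' individual is a "singlet"; for fission models a "doublet" entry represents
#' a living twin pair sharing one TOB (two individuals).
#'
#' @param t current time.
#' @param singlets numeric vector of singlet TOBs (all `<= t`).
#' @param doublets numeric vector of twin-pair TOBs (each entry is two
#'   individuals).
#' @param positions optional numeric vector of one-dimensional positions
#'   aligned with `singlets` (spatial budding models).
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(t = 0, singlets = numeric(0),
                             doublets = numeric(0), positions = NULL) {
  stopifnot(all(singlets <= t), all(doublets <= t))
  if (!is.null(positions) && length(positions) != length(singlets))
    stop("'positions' must align with 'singlets'")
  structure(list(t = t, singlets = as.numeric(singlets),
                 doublets = as.numeric(doublets), positions = positions),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> t =", x$t, ":", length(x$singlets), "singlet(s),",
      length(x$doublets), "doublet pair(s)\n")
  invisible(x)
}

# total number of living individuals
state_count <- function(s) length(s$singlets) + 2L * length(s$doublets)

# deterministic per-trajectory seed stream: two Lehmer steps mixing the
# master seed and the trajectory index (all arithmetic exact in doubles)
mix_seed <- function(seed, r) {
  m <- 2147483647
  x <- seed %% m
  x <- (x * 16807) %% m
  x <- (x + r) %% m
  x <- (x * 48271) %% m
  if (x == 0) x <- 1
  as.integer(x)
}

new_event_log <- function() {
  list(time = numeric(0), kind = character(0), parent_tob = numeric(0),
       child_tob = numeric(0), n_before = integer(0))
}

log_event <- function(log, time, kind, parent_tob, child_tob, n_before) {
  if (is.null(log)) return(NULL)
  log$time <- c(log$time, time)
  log$kind <- c(log$kind, kind)
  log$parent_tob <- c(log$parent_tob, parent_tob)
  log$child_tob <- c(log$child_tob, child_tob)
  log$n_before <- c(log$n_before, n_before)
  log
}

finish_log <- function(log) {
  if (is.null(log)) return(NULL)
  as.data.frame(log, stringsAsFactors = FALSE)
}

# ---- single-trajectory cores ----------------------------------------------
# All cores share the snapshot convention: the state at a snapshot time is
# recorded AFTER any event occurring at exactly that time.  Snapshot times
# strictly before the next event time are flushed first.

# budding, size-independent hazards: exact per-individual inversion of the
# integrated total hazard, with a competing-risks coin beta/gamma at each
# event.  Draw order per event: [coin u_kind]; on birth [u_child_clock,
# u_parent_clock].  Initial clocks are drawn in individual order.
sim_budding_inversion <- function(spec, tobs, t_final, snapshots,
                                  record = FALSE, D = 0, positions = NULL) {
  log <- if (record) new_event_log() else NULL
  spatial <- !is.null(positions)
  lu <- if (spatial) rep(0, length(tobs)) else NULL  # last position update
  ev <- numeric(length(tobs))
  for (i in seq_along(tobs))
    ev[i] <- tobs[i] + invert_event_age(spec, -tobs[i], stats::runif(1))
  snaps <- vector("list", length(snapshots))
  si <- 1L
  flush <- function(upto) {
    while (si <= length(snapshots) && snapshots[si] < upto) {
      pos <- NULL
      if (spatial) {
        if (D > 0 && length(tobs)) {
          dtv <- snapshots[si] - lu
          positions <<- positions + stats::rnorm(length(positions), 0,
                                                 sqrt(2 * D * pmax(dtv, 0)))
          lu <<- rep(snapshots[si], length(tobs))
        }
        pos <- positions
      }
      snaps[[si]] <<- list(s = tobs, d = numeric(0), pos = pos)
      si <<- si + 1L
    }
  }
  repeat {
    if (length(tobs) == 0L) { flush(Inf); break }
    imin <- which.min(ev)
    tev <- ev[imin]
    flush(tev)                      # snapshots strictly before the event
    if (tev > t_final) break
    a <- tev - tobs[imin]
    bz <- spec$birth(length(tobs), a)
    mz <- spec$death(length(tobs), a)
    g <- bz + mz
    if (g <= 0) stop("event scheduled where total hazard is zero")
    u <- stats::runif(1)
    if (u < bz / g) {                 # budding birth: parent survives
      log <- log_event(log, tev, "birth", tobs[imin], tev, length(tobs))
      if (spatial) {
        if (D > 0) {
          positions[imin] <- positions[imin] +
            stats::rnorm(1, 0, sqrt(2 * D * (tev - lu[imin])))
          lu[imin] <- tev
        }
        positions <- c(positions, positions[imin])
        lu <- c(lu, tev)
      }
      tobs <- c(tobs, tev)
      ev <- c(ev, tev + invert_event_age(spec, 0, stats::runif(1)))
      ev[imin] <- tobs[imin] + invert_event_age(spec, a, stats::runif(1))
    } else {                          # death
      log <- log_event(log, tev, "death", tobs[imin], NA_real_, length(tobs))
      tobs <- tobs[-imin]
      ev <- ev[-imin]
      if (spatial) { positions <- positions[-imin]; lu <- lu[-imin] }
    }
  }
  list(snaps = snaps, events = finish_log(log))
}

# budding, possibly size- (and position-) dependent hazards: Ogata-style
# thinning against bound(n).  Proposals arrive at rate n*bound(n); the chosen
# individual is accepted with probability gamma/bound.  All pending proposals
# are implicitly discarded after every accepted event (the rate is recomputed
# each iteration).  Draw order per proposal: [u_wait, u_index (n>1),
# u_accept, and on acceptance u_kind].
sim_budding_thinning <- function(spec, tobs, t_final, snapshots,
                                 record = FALSE, D = 0, positions = NULL) {
  if (!is.function(spec$bound))
    stop("size-dependent hazards require a finite 'bound' (hazard bound) ",
         "for the thinning sampler")
  log <- if (record) new_event_log() else NULL
  spatial <- !is.null(positions)
  qdep <- spatial && length(formals(spec$birth)) >= 3
  lu <- if (spatial) rep(0, length(tobs)) else NULL
  t <- 0
  snaps <- vector("list", length(snapshots))
  si <- 1L
  flush <- function(upto) {
    while (si <= length(snapshots) && snapshots[si] < upto) {
      pos <- NULL
      if (spatial) {
        if (D > 0 && length(tobs)) {
          dtv <- snapshots[si] - lu
          positions <<- positions + stats::rnorm(length(positions), 0,
                                                 sqrt(2 * D * pmax(dtv, 0)))
          lu <<- rep(snapshots[si], length(tobs))
        }
        pos <- positions
      }
      snaps[[si]] <<- list(s = tobs, d = numeric(0), pos = pos)
      si <<- si + 1L
    }
  }
  repeat {
    n <- length(tobs)
    if (n == 0L) { flush(Inf); break }
    Bn <- spec$bound(n)
    if (!is.finite(Bn) || Bn < 0) stop("hazard bound must be finite and >= 0")
    if (Bn == 0) { flush(Inf); break }
    tprop <- t + stats::rexp(1, n * Bn)
    flush(tprop)
    if (tprop > t_final) break
    i <- if (n == 1L) 1L else sample.int(n, 1L)
    a <- tprop - tobs[i]
    if (spatial && D > 0) {
      positions[i] <- positions[i] +
        stats::rnorm(1, 0, sqrt(2 * D * (tprop - lu[i])))
      lu[i] <- tprop
    }
    if (qdep) {
      bz <- spec$birth(n, a, positions[i]); mz <- spec$death(n, a, positions[i])
    } else {
      bz <- spec$birth(n, a); mz <- spec$death(n, a)
    }
    g <- bz + mz
    if (g > Bn * (1 + 1e-9))
      stop(sprintf("hazard bound violated: gamma=%g > bound=%g at n=%d, a=%g",
                   g, Bn, n, a))
    if (stats::runif(1) <= g / Bn) {
      if (stats::runif(1) < bz / g) {
        log <- log_event(log, tprop, "birth", tobs[i], tprop, n)
        if (spatial) {
          positions <- c(positions, positions[i])
          lu <- c(lu, tprop)
        }
        tobs <- c(tobs, tprop)
      } else {
        log <- log_event(log, tprop, "death", tobs[i], NA_real_, n)
        tobs <- tobs[-i]
        if (spatial) { positions <- positions[-i]; lu <- lu[-i] }
      }
    }
    t <- tprop
  }
  list(snaps = snaps, events = finish_log(log))
}

# budding, fixed-timestep scheme (the O(dt)-biased discretization kept for
# fidelity experiments): at most one event per step of length dt.
sim_budding_fixed_step <- function(spec, tobs, t_final, snapshots, dt,
                                   record = FALSE) {
  stopifnot(is.numeric(dt), dt > 0)
  log <- if (record) new_event_log() else NULL
  t <- 0
  snaps <- vector("list", length(snapshots))
  si <- 1L
  flush <- function(upto) {
    while (si <= length(snapshots) && snapshots[si] < upto) {
      snaps[[si]] <<- list(s = tobs, d = numeric(0), pos = NULL)
      si <<- si + 1L
    }
  }
  while (t < t_final) {
    tn <- min(t + dt, t_final)
    flush(tn)
    n <- length(tobs)
    if (n > 0L) {
      ages <- tn - tobs
      bz <- spec$birth(n, ages); mz <- spec$death(n, ages)
      gz <- bz + mz
      p <- sum(gz) * (tn - t)
      if (p > 1) stop("fixed-step probability exceeds 1; decrease dt")
      if (stats::runif(1) < p) {
        i <- if (n == 1L) 1L else sample.int(n, 1L, prob = gz)
        if (stats::runif(1) < bz[i] / gz[i]) {
          log <- log_event(log, tn, "birth", tobs[i], tn, n)
          tobs <- c(tobs, tn)
        } else {
          log <- log_event(log, tn, "death", tobs[i], NA_real_, n)
          tobs <- tobs[-i]
        }
      }
    }
    t <- tn
  }
  flush(Inf)
  list(snaps = snaps, events = finish_log(log))
}

# fission-death, size-independent hazards, exact inversion.  Singlets carry
# the total-event hazard gamma(a); a twin pair carries 2*gamma(a) (both
# members at risk).  Structural moves at an event (probability h2 = beta/gamma
# of fission, h0 of death):
#   singlet fission: singlet removed, new age-0 pair added        (+1)
#   singlet death:   singlet removed                              (-1)
#   pair fission:    pair -> singlet (twin, old TOB) + new pair   (+1)
#   pair death:      pair -> singlet (twin, old TOB)              (-1)
# Draw order per event: [u_kind]; then new clocks in the order
# new-pair, surviving-twin (each one uniform).
sim_fission_inversion <- function(spec, s_tobs, d_tobs, t_final, snapshots,
                                  record = FALSE) {
  log <- if (record) new_event_log() else NULL
  draw_s <- function(a0) invert_event_age(spec, a0, stats::runif(1))
  draw_d <- function(a0) invert_event_age(spec, a0, sqrt(stats::runif(1)))
  s_ev <- vapply(s_tobs, function(b) b + draw_s(-b), numeric(1))
  d_ev <- vapply(d_tobs, function(b) b + draw_d(-b), numeric(1))
  snaps <- vector("list", length(snapshots))
  si <- 1L
  flush <- function(upto) {
    while (si <= length(snapshots) && snapshots[si] < upto) {
      snaps[[si]] <<- list(s = s_tobs, d = d_tobs, pos = NULL)
      si <<- si + 1L
    }
  }
  repeat {
    if (length(s_tobs) + length(d_tobs) == 0L) { flush(Inf); break }
    cand_s <- if (length(s_ev)) min(s_ev) else Inf
    cand_d <- if (length(d_ev)) min(d_ev) else Inf
    tev <- min(cand_s, cand_d)
    flush(tev)
    if (tev > t_final) break
    n_before <- length(s_tobs) + 2L * length(d_tobs)
    fission <- stats::runif(1) < spec$progeny[["h2"]]
    if (cand_s <= cand_d) {           # singlet event
      i <- which.min(s_ev)
      b <- s_tobs[i]
      s_tobs <- s_tobs[-i]; s_ev <- s_ev[-i]
      if (fission) {
        log <- log_event(log, tev, "fission", b, tev, n_before)
        d_tobs <- c(d_tobs, tev)
        d_ev <- c(d_ev, tev + draw_d(0))
      } else {
        log <- log_event(log, tev, "death", b, NA_real_, n_before)
      }
    } else {                          # pair event (one twin, chosen by symmetry)
      j <- which.min(d_ev)
      b <- d_tobs[j]
      a <- tev - b
      d_tobs <- d_tobs[-j]; d_ev <- d_ev[-j]
      if (fission) {
        log <- log_event(log, tev, "fission", b, tev, n_before)
        d_tobs <- c(d_tobs, tev)
        d_ev <- c(d_ev, tev + draw_d(0))
      } else {
        log <- log_event(log, tev, "death", b, NA_real_, n_before)
      }
      # the surviving twin becomes a singlet, keeping its TOB
      s_tobs <- c(s_tobs, b)
      s_ev <- c(s_ev, b + draw_s(a))
    }
  }
  list(snaps = snaps, events = finish_log(log))
}

# fission-death with size-dependent hazards: thinning over individual "slots"
# (one per singlet, two per pair) against bound(total count).
sim_fission_thinning <- function(spec, s_tobs, d_tobs, t_final, snapshots,
                                 record = FALSE) {
  if (!is.function(spec$bound))
    stop("size-dependent fission hazards require a finite 'bound'")
  log <- if (record) new_event_log() else NULL
  t <- 0
  snaps <- vector("list", length(snapshots))
  si <- 1L
  flush <- function(upto) {
    while (si <= length(snapshots) && snapshots[si] < upto) {
      snaps[[si]] <<- list(s = s_tobs, d = d_tobs, pos = NULL)
      si <<- si + 1L
    }
  }
  repeat {
    m <- length(s_tobs); p <- length(d_tobs)
    ntot <- m + 2L * p
    if (ntot == 0L) { flush(Inf); break }
    Bn <- spec$bound(ntot)
    if (!is.finite(Bn) || Bn < 0) stop("hazard bound must be finite and >= 0")
    if (Bn == 0) { flush(Inf); break }
    tprop <- t + stats::rexp(1, ntot * Bn)
    flush(tprop)
    if (tprop > t_final) break
    slot <- if (ntot == 1L) 1L else sample.int(ntot, 1L)
    is_singlet <- slot <= m
    b <- if (is_singlet) s_tobs[slot] else d_tobs[ceiling((slot - m) / 2)]
    a <- tprop - b
    bz <- spec$birth(ntot, a); mz <- spec$death(ntot, a)
    g <- bz + mz
    if (g > Bn * (1 + 1e-9)) stop("hazard bound violated in fission thinning")
    if (stats::runif(1) <= g / Bn) {
      fission <- stats::runif(1) < bz / g
      if (is_singlet) {
        s_tobs <- s_tobs[-slot]
      } else {
        j <- ceiling((slot - m) / 2)
        d_tobs <- d_tobs[-j]
        s_tobs <- c(s_tobs, b)        # surviving twin
      }
      if (fission) {
        log <- log_event(log, tprop, "fission", b, tprop, ntot)
        d_tobs <- c(d_tobs, tprop)
      } else {
        log <- log_event(log, tprop, "death", b, NA_real_, ntot)
      }
    }
    t <- tprop
  }
  list(snaps = snaps, events = finish_log(log))
}

# ---- user-facing simulators ------------------------------------------------

choose_method <- function(spec, method) {
  if (method != "auto") return(method)
  if (spec$size_dependent) "thinning" else "inversion"
}

check_init <- function(init) {
  stopifnot(inherits(init, "population_state"))
  if (init$t != 0) stop("simulations start at t = 0; supply founder TOBs <= 0")
  if (any(init$singlets > 0) || any(init$doublets > 0))
    stop("founder TOBs must be <= 0")
}

wrap_trajectory <- function(res, snapshots, fission = FALSE, spatial = FALSE) {
  states <- lapply(seq_along(snapshots), function(i) {
    s <- res$snaps[[i]]
    population_state(snapshots[i], s$s, s$d, s$pos)
  })
  structure(list(events = res$events, snapshots = states,
                 snapshot_times = snapshots, fission = fission,
                 spatial = spatial),
            class = "agekin_trajectory")
}

#' @export
print.agekin_trajectory <- function(x, ...) {
  ne <- if (is.null(x$events)) NA_integer_ else nrow(x$events)
  cat("<agekin_trajectory>", ne, "events,",
      length(x$snapshots), "snapshot(s)\n")
  invisible(x)
}

#' Simulate a budding birth-death trajectory
#'
#' Statistically exact event-driven simulation of the age-structured budding
#' birth-death process: each individual of age `a` in a population of size `n`
#' gives birth (adding an age-0 individual, the parent surviving) with hazard
#' \eqn{\beta_n(a)} and dies with hazard \eqn{\mu_n(a)}.
#'
#' For size-independent hazards the default sampler inverts the integrated
#' total hazard per individual and flips a competing-risks coin
#' \eqn{\beta/\gamma} at each event.  Size-dependent hazards use exact
#' thinning against `spec$bound(n)`.  A fixed-timestep scheme (`method =
#' "fixed-step"`, `dt` required) is retained for fidelity experiments; it
#' carries an `O(dt)` bias and is never the default.
#'
#' @param spec a [rate_spec()] (without progeny split).
#' @param init a [population_state()] with founder TOBs `<= 0`.
#' @param t_final end time (`> 0`).
#' @param seed integer seed; identical `(spec, init, seed)` give bitwise
#'   identical trajectories.
#' @param snapshots times at which the state is recorded (default `t_final`).
#' @param method `"auto"`, `"inversion"`, `"thinning"` or `"fixed-step"`.
#' @param dt timestep for `method = "fixed-step"`.
#' @param record_events keep the event log (default `TRUE`).
#' @return An `"agekin_trajectory"`: event log (`time`, `kind`, `parent_tob`,
#'   `child_tob`, `n_before`) plus a [population_state()] per snapshot.
#' @export
simulate_budding <- function(spec, init, t_final, seed,
                             snapshots = t_final,
                             method = c("auto", "inversion", "thinning",
                                        "fixed-step"),
                             dt = NULL, record_events = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "rate_spec"), t_final > 0)
  if (!is.null(spec$progeny))
    stop("'spec' has a progeny split; use simulate_fission_death()")
  check_init(init)
  snapshots <- sort(snapshots)
  set.seed(mix_seed(seed, 0L))
  method <- choose_method(spec, method)
  res <- switch(method,
    inversion = {
      if (spec$size_dependent)
        stop("exact inversion requires size-independent hazards")
      sim_budding_inversion(spec, init$singlets, t_final, snapshots,
                            record_events)
    },
    thinning = sim_budding_thinning(spec, init$singlets, t_final, snapshots,
                                    record_events),
    `fixed-step` = sim_budding_fixed_step(spec, init$singlets, t_final,
                                          snapshots, dt, record_events))
  wrap_trajectory(res, snapshots)
}

#' Simulate a binary fission-death trajectory
#'
#' Event-driven simulation of the singlet/doublet fission-death process.  An
#' individual's event hazard is \eqn{\gamma(a) = \beta(a) + \mu(a)}; a twin
#' pair carries hazard \eqn{2\gamma} (both members at risk).  At an event the
#' individual either fissions (probability \eqn{\beta/\gamma}) into a new
#' age-0 twin pair -- its own twin, if any, surviving as a singlet that keeps
#' its TOB -- or dies (probability \eqn{\mu/\gamma}); a pair death leaves a
#' singlet.  Every event changes the total count by exactly +1 or -1.
#'
#' @inheritParams simulate_budding
#' @param spec a [rate_spec()] with a progeny split (e.g. from
#'   [hazards_from_waiting_time()]).
#' @return An `"agekin_trajectory"`.
#' @export
simulate_fission_death <- function(spec, init, t_final, seed,
                                   snapshots = t_final,
                                   method = c("auto", "inversion", "thinning"),
                                   record_events = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "rate_spec"), t_final > 0)
  if (is.null(spec$progeny))
    stop("'spec' must carry a progeny split for fission models")
  check_init(init)
  snapshots <- sort(snapshots)
  set.seed(mix_seed(seed, 0L))
  method <- choose_method(spec, method)
  res <- switch(method,
    inversion = {
      if (spec$size_dependent)
        stop("exact inversion requires size-independent hazards")
      sim_fission_inversion(spec, init$singlets, init$doublets, t_final,
                            snapshots, record_events)
    },
    thinning = sim_fission_thinning(spec, init$singlets, init$doublets,
                                    t_final, snapshots, record_events))
  wrap_trajectory(res, snapshots, fission = TRUE)
}

#' Simulate a spatially diffusing budding trajectory
#'
#' As [simulate_budding()], with every individual performing independent
#' Brownian motion with diffusivity `D` between events (exact Gaussian
#' increments at event and snapshot times).  A newborn is placed at its
#' parent's current position.  Hazards may depend on position via a third
#' argument `q` of `spec$birth`/`spec$death` (thinning required; the bound
#' must then hold over all positions).  With `D = 0` no Gaussian variates are
#' consumed, so the event statistics reduce exactly to [simulate_budding()]
#' under the same seed.
#'
#' @inheritParams simulate_budding
#' @param D diffusivity (`>= 0`).
#' @return An `"agekin_trajectory"` whose snapshot states carry positions.
#' @export
simulate_spatial <- function(spec, init, D, t_final, seed,
                             snapshots = t_final,
                             method = c("auto", "inversion", "thinning"),
                             record_events = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "rate_spec"), t_final > 0)
  if (!is.numeric(D) || D < 0) stop("'D' must be a nonnegative diffusivity")
  check_init(init)
  if (is.null(init$positions))
    stop("spatial simulation requires initial positions")
  snapshots <- sort(snapshots)
  set.seed(mix_seed(seed, 0L))
  method <- choose_method(spec, method)
  qdep <- length(formals(spec$birth)) >= 3
  if (qdep && method == "inversion")
    stop("position-dependent hazards require method = 'thinning'")
  res <- switch(method,
    inversion = sim_budding_inversion(spec, init$singlets, t_final, snapshots,
                                      record_events, D = D,
                                      positions = init$positions),
    thinning = sim_budding_thinning(spec, init$singlets, t_final, snapshots,
                                    record_events, D = D,
                                    positions = init$positions))
  wrap_trajectory(res, snapshots, spatial = TRUE)
}

#' Simulate an ensemble of independent trajectories
#'
#' Runs `R` trajectories with per-trajectory seeds derived deterministically
#' from `(seed, trajectory index)` and collects snapshot states for the
#' ensemble estimators.  `init` may be a fixed [population_state()] or a
#' function `(trajectory index)` returning one (drawing founder ages from the
#' trajectory's own stream).
#'
#' @inheritParams simulate_budding
#' @param R number of trajectories.
#' @param init a [population_state()] or a function `function(r)` returning
#'   one; the function is called after the trajectory's seed is set.
#' @param fission simulate the fission-death process (`spec` must carry a
#'   progeny split).
#' @param D optional diffusivity for spatial budding ensembles.
#' @param record_events keep per-trajectory event logs (memory-heavy;
#'   default `FALSE`).
#' @return An `"agekin_ensemble"`: snapshot times, per-trajectory states,
#'   seeds and model metadata.
#' @export
simulate_ensemble <- function(spec, init, t_final, snapshots = t_final,
                              R, seed, fission = !is.null(spec$progeny),
                              method = c("auto", "inversion", "thinning"),
                              D = NULL, record_events = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "rate_spec"), R >= 1, t_final > 0)
  snapshots <- sort(snapshots)
  method <- choose_method(spec, method)
  init_fun <- if (is.function(init)) init else function(r) init
  states <- vector("list", R)
  logs <- if (record_events) vector("list", R) else NULL
  for (r in seq_len(R)) {
    set.seed(mix_seed(seed, r))
    st <- init_fun(r)
    check_init(st)
    res <- if (fission) {
      if (method == "inversion")
        sim_fission_inversion(spec, st$singlets, st$doublets, t_final,
                              snapshots, record_events)
      else
        sim_fission_thinning(spec, st$singlets, st$doublets, t_final,
                             snapshots, record_events)
    } else if (!is.null(D)) {
      if (method == "inversion")
        sim_budding_inversion(spec, st$singlets, t_final, snapshots,
                              record_events, D = D, positions = st$positions)
      else
        sim_budding_thinning(spec, st$singlets, t_final, snapshots,
                             record_events, D = D, positions = st$positions)
    } else {
      if (method == "inversion")
        sim_budding_inversion(spec, st$singlets, t_final, snapshots,
                              record_events)
      else
        sim_budding_thinning(spec, st$singlets, t_final, snapshots,
                             record_events)
    }
    states[[r]] <- res$snaps
    if (record_events) logs[[r]] <- res$events
  }
  structure(list(snapshot_times = snapshots, states = states, R = R,
                 seed = seed, method = method, model = spec$label,
                 fission = fission, events = logs),
            class = "agekin_ensemble")
}

#' @export
print.agekin_ensemble <- function(x, ...) {
  cat("<agekin_ensemble>", x$R, "trajectories of", x$model,
      "| snapshots at", paste(signif(x$snapshot_times, 4), collapse = ", "),
      "\n")
  invisible(x)
}

snapshot_index <- function(ens, t) {
  i <- which(abs(ens$snapshot_times - t) < 1e-9)
  if (length(i) != 1L)
    stop("no snapshot recorded at t = ", t)
  i
}

# ---- ensemble estimators ---------------------------------------------------

#' Empirical population-size distribution
#'
#' Estimates the total number density \eqn{\rho_n^{(0)}(t)}, the probability
#' that the population contains `n` individuals at the snapshot time.
#'
#' @param ens an `"agekin_ensemble"`.
#' @param t a recorded snapshot time.
#' @return A data frame with columns `n`, `estimate` (summing to 1) and
#'   `stderr` (binomial standard errors).
#' @export
estimate_number_density <- function(ens, t) {
  i <- snapshot_index(ens, t)
  counts <- vapply(ens$states, function(tr) {
    s <- tr[[i]]
    length(s$s) + 2L * length(s$d)
  }, integer(1))
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  p <- tab / ens$R
  data.frame(n = seq_along(tab) - 1L, estimate = p,
             stderr = sqrt(p * (1 - p) / ens$R))
}

#' Marginal age-density estimator
#'
#' Estimates the one- or two-point marginal age density at a snapshot.  For
#' `k = 1` one individual is chosen uniformly per qualifying trajectory; for
#' `k = 2` one unordered pair per trajectory, symmetrized across the
#' diagonal.  Using a single draw per trajectory keeps trajectories i.i.d.,
#' so the binomial standard errors are clean.  The estimate is normalized so
#' that its integral over ages (for `n_filter = n`) equals the empirical
#' probability of observing `n` individuals at `t`.
#'
#' @param ens an `"agekin_ensemble"`.
#' @param t a recorded snapshot time.
#' @param n_filter restrict to trajectories with exactly this population
#'   size, or `"all"`.
#' @param k 1 or 2 (marginal dimension).
#' @param breaks strictly increasing bin edges for ages.
#' @return A list of class `"agekin_age_density"` with elements `breaks`,
#'   `estimate` (vector for `k = 1`, symmetric matrix for `k = 2`), `stderr`,
#'   `prob` (empirical probability of qualifying), and `empty` (`TRUE` when no
#'   trajectory qualified).
#' @export
estimate_marginal_age_density <- function(ens, t, n_filter = "all", k = 1,
                                          breaks) {
  stopifnot(k %in% c(1, 2), length(breaks) >= 2, all(diff(breaks) > 0))
  i <- snapshot_index(ens, t)
  set.seed(mix_seed(ens$seed, 999983L))  # estimator's own reproducible stream
  ages_of <- function(s) t - c(s$s, rep(s$d, each = 2L))
  nb <- length(breaks) - 1L
  w <- diff(breaks)
  R <- ens$R
  if (k == 1) {
    picked <- rep(NA_real_, R)
    nqual <- 0L
    for (r in seq_len(R)) {
      ages <- ages_of(ens$states[[r]][[i]])
      n <- length(ages)
      if (n < 1 || (!identical(n_filter, "all") && n != n_filter)) next
      nqual <- nqual + 1L
      picked[r] <- ages[if (n == 1L) 1L else sample.int(n, 1L)]
    }
    if (nqual == 0L)
      return(structure(list(breaks = breaks, estimate = rep(0, nb),
                            stderr = rep(0, nb), prob = 0, empty = TRUE),
                       class = "agekin_age_density"))
    cnt <- tabulate(findInterval(picked[!is.na(picked)], breaks,
                                 rightmost.closed = TRUE), nbins = nb)
    p <- cnt / R
    structure(list(breaks = breaks, estimate = p / w,
                   stderr = sqrt(p * (1 - p) / R) / w,
                   prob = nqual / R, empty = FALSE),
              class = "agekin_age_density")
  } else {
    cnt <- matrix(0, nb, nb)
    nqual <- 0L
    for (r in seq_len(R)) {
      ages <- ages_of(ens$states[[r]][[i]])
      n <- length(ages)
      if (n < 2 || (!identical(n_filter, "all") && n != n_filter)) next
      nqual <- nqual + 1L
      idx <- sample.int(n, 2L)
      b1 <- findInterval(ages[idx[1]], breaks, rightmost.closed = TRUE)
      b2 <- findInterval(ages[idx[2]], breaks, rightmost.closed = TRUE)
      if (b1 >= 1 && b1 <= nb && b2 >= 1 && b2 <= nb) {
        cnt[b1, b2] <- cnt[b1, b2] + 0.5
        cnt[b2, b1] <- cnt[b2, b1] + 0.5
      }
    }
    if (nqual == 0L)
      return(structure(list(breaks = breaks, estimate = matrix(0, nb, nb),
                            stderr = matrix(0, nb, nb), prob = 0,
                            empty = TRUE),
                       class = "agekin_age_density"))
    p <- cnt / R
    area <- outer(w, w)
    structure(list(breaks = breaks, estimate = p / area,
                   stderr = sqrt(p * (1 - p) / R) / area,
                   prob = nqual / R, empty = FALSE),
              class = "agekin_age_density")
  }
}

#' @export
print.agekin_age_density <- function(x, ...) {
  cat("<agekin_age_density>", if (is.matrix(x$estimate)) "k=2" else "k=1",
      "on", length(x$breaks) - 1L, "bins; qualifying fraction", x$prob, "\n")
  invisible(x)
}

#' Mean and variance of an age-window count
#'
#' Sample mean and unbiased sample variance, across trajectories, of the
#' number of individuals with age in `[window[1], window[2]]` at the snapshot
#' time, with standard errors (the SE of the variance uses the empirical
#' fourth central moment).
#'
#' @param ens an `"agekin_ensemble"`.
#' @param t a recorded snapshot time.
#' @param window numeric pair `c(a, b)` with `a < b` (ages).
#' @return A list with `mean`, `var`, `se_mean`, `se_var`, `R`.
#' @export
estimate_window_count_moments <- function(ens, t, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  i <- snapshot_index(ens, t)
  cnt <- vapply(ens$states, function(tr) {
    ages <- t - c(tr[[i]]$s, rep(tr[[i]]$d, each = 2L))
    sum(ages >= window[1] & ages <= window[2])
  }, numeric(1))
  R <- ens$R
  m <- mean(cnt)
  v <- stats::var(cnt)
  m4 <- mean((cnt - m)^4)
  list(mean = m, var = v,
       se_mean = sqrt(v / R),
       se_var = sqrt(pmax(m4 - (R - 3) / (R - 1) * v^2, 0) / R),
       R = R)
}
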