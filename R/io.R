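#' Write and read event logs
#'
#' Event logs are tab-separated with columns `time`, `kind`, `parent_tob`,
#' `child_tob`, `n_before` (and `trajectory` when several logs are combined).
#' Every writer/reader pair round-trips losslessly.
#'
#' @param events event-log data frame (from a trajectory) or a list of them.
#' @param path file path.
#' @return `read_events_tsv` returns the data frame; writers return `path`
#'   invisibly.
#' @export
write_events_tsv <- function(events, path) {
  if (is.data.frame(events)) {
    utils::write.table(events, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    combined <- do.call(rbind, lapply(seq_along(events), function(i) {
      e <- events[[i]]
      if (is.null(e) || !nrow(e)) return(NULL)
      cbind(trajectory = i, e)
    }))
    utils::write.table(combined, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write and read fields as long-format CSV
#'
#' A [grid_field()] serializes to one row per grid node with full
#' coordinates (`axis`, `t`, `value`) plus a JSON metadata sidecar carrying
#' the convention; long format keeps the files diffable and re-readable from
#' any language.
#'
#' @param field a `"grid_field"`.
#' @param path CSV path; metadata goes to `paste0(path, ".meta.json")`.
#' @return `read_field_csv` reconstructs the `"grid_field"`; the writer
#'   returns `path` invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  df <- data.frame(axis = rep(field$axis, times = length(field$t)),
                   t = rep(field$t, each = length(field$axis)),
                   value = as.vector(field$values))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(convention = field$convention,
                            n_axis = length(field$axis),
                            n_t = length(field$t)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  axis <- unique(df$axis)
  t <- unique(df$t)
  vals <- matrix(df$value, nrow = length(axis), ncol = length(t))
  grid_field(axis, t, vals, meta$convention)
}

#' Write and read a Volterra solution as CSV
#' @param sol a `"volterra_solution"`.
#' @param path CSV path.
#' @return `read_volterra_csv` reconstructs the object (quadrature metadata
#'   from the sidecar); the writer returns `path` invisibly.
#' @export
write_volterra_csv <- function(sol, path) {
  stopifnot(inherits(sol, "volterra_solution"))
  utils::write.csv(data.frame(t = sol$t, B = sol$B), path, row.names = FALSE)
  jsonlite::write_json(list(h = sol$h, rule = sol$rule, model = sol$model,
                            cutoff = sol$cutoff),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_volterra_csv
#' @export
read_volterra_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  cutoff <- meta$cutoff
  cutoff <- if (is.null(cutoff) || is.character(cutoff)) NA_real_
            else as.numeric(cutoff)
  structure(list(t = df$t, B = df$B, h = meta$h, rule = meta$rule,
                 cutoff = cutoff, model = meta$model),
            class = "volterra_solution")
}

#' Run configurations
#'
#' A `run_config` is a named list describing one computational experiment
#' (model preset, parameters, grids, trajectory count, seeds, snapshot times,
#' method selectors).  It round-trips losslessly through YAML, and [run()]
#' echoes the fully materialized configuration into the output metadata so no
#' run depends on implicit defaults.
#'
#' @param config a `"run_config"` to serialize.
#' @param subcommand one of `"simulate"`, `"meanfield"`, `"moments"`,
#'   `"fission"`.
#' @param model model preset name (see [fixture_config()] for examples).
#' @param params named list of model parameters.
#' @param R number of trajectories (simulate).
#' @param t_final horizon.
#' @param snapshots snapshot times (simulate).
#' @param seed master seed.
#' @param h grid step (deterministic solvers).
#' @param method method selector (see the respective solver).
#' @param ... further fields stored verbatim.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(subcommand, model, params = list(), R = 1000L,
                       t_final = 1, snapshots = t_final, seed = 1L,
                       h = 1e-3, method = "auto", ...) {
  stopifnot(subcommand %in% c("simulate", "meanfield", "moments", "fission"))
  structure(list(subcommand = subcommand, model = model, params = params,
                 R = R, t_final = t_final, snapshots = snapshots,
                 seed = seed, h = h, method = method, ...),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$subcommand, "/", x$model, "\n")
  invisible(x)
}

# materialize a rate_spec from a config's model preset
config_spec <- function(config) {
  p <- config$params
  switch(config$model,
    "constant" = rates_constant(p$beta0, p$mu0 %||% 0),
    "linear-death" = rates_linear_death(p$slope %||% 1, p$beta0 %||% 0),
    "capacity" = rates_capacity(p$beta0, p$K, p$mu0 %||% 0),
    "gamma-fission" = hazards_from_waiting_time(wt_gamma(p$alpha),
                                                p$h2 %||% 1),
    "exponential-fission" = hazards_from_waiting_time(
      wt_exponential(p$rate %||% 1), p$h2 %||% 1),
    stop("unknown model preset: ", config$model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_init <- function(config) {
  p <- config$params
  count <- p$founders %||% 1L
  dist <- p$init_ages %||% "point"
  function(r) {
    ages <- sample_initial_ages(dist, count, rate = p$init_rate %||% 1,
                                a0 = p$init_a0 %||% 0)
    population_state(0, singlets = -ages)
  }
}

#' Execute a run configuration
#'
#' Runs the experiment described by a [run_config()] and writes a
#' deterministic artifact directory: `events/` (TSV logs, simulate runs),
#' `fields/` (long-format CSV), `meta.json` (the fully materialized config,
#' seeds and wall-clock) and `log.txt`.  Identical configurations and seeds
#' produce byte-identical `events/` content.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; must not exist or be empty).
#' @return `out_dir`, invisibly.
#' @export
run <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)))
    stop("'out_dir' exists and is not empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(..., "\n", file = logf, append = TRUE)
  logline("run started:", config$subcommand, config$model)
  if (config$subcommand == "simulate") {
    spec <- config_spec(config)
    ens <- simulate_ensemble(spec, config_init(config), config$t_final,
                             snapshots = config$snapshots, R = config$R,
                             seed = config$seed, method = config$method,
                             record_events = isTRUE(config$record_events))
    dir.create(file.path(out_dir, "events"))
    if (!is.null(ens$events))
      write_events_tsv(ens$events, file.path(out_dir, "events", "events.tsv"))
    dir.create(file.path(out_dir, "fields"))
    for (tt in config$snapshots) {
      nd <- estimate_number_density(ens, tt)
      utils::write.csv(cbind(t = tt, nd),
                       file.path(out_dir, "fields",
                                 sprintf("number_density_t%g.csv", tt)),
                       row.names = FALSE)
    }
    logline("simulated", config$R, "trajectories")
  } else if (config$subcommand == "meanfield") {
    spec <- config_spec(config)
    tg <- seq(0, config$t_final, by = config$h)
    B <- solve_renewal_B(config$g0 %||% function(a) stats::dexp(a), spec, tg)
    dir.create(file.path(out_dir, "fields"))
    write_volterra_csv(B, file.path(out_dir, "fields", "B.csv"))
    logline("solved renewal equation on", length(tg), "nodes")
  } else if (config$subcommand == "fission") {
    p <- config$params
    tg <- seq(0, config$t_final, by = config$h)
    method <- if (identical(config$method, "auto")) "volterra" else config$method
    vals <- switch(method,
      volterra = {
        spec <- config_spec(config)
        B <- solve_fission_B(spec, tg)
        list(B = B$B, T = fission_fields(B, spec)$Ttot)
      },
      renewal = {
        bh <- bellman_harris_mean(wt_gamma(p$alpha), p$h2 %||% 1, tg)
        list(B = bh$B, T = bh$T)
      },
      laplace = {
        Tf <- bellman_harris_mean_laplace(wt_gamma(p$alpha), p$h2 %||% 1)
        list(B = rep(NA_real_, length(tg)), T = Tf(tg))
      },
      contour = list(B = gamma_fission_B(p$alpha, tg),
                     T = gamma_fission_T(p$alpha, tg)),
      stop("unknown fission method: ", method))
    dir.create(file.path(out_dir, "fields"))
    utils::write.csv(data.frame(t = tg, B = vals$B, T = vals$T),
                     file.path(out_dir, "fields", "fission_BT.csv"),
                     row.names = FALSE)
    logline("fission mean field via", method)
  } else if (config$subcommand == "moments") {
    p <- config$params
    spec <- config_spec(config)
    lam <- p$init_rate %||% 1
    g1 <- function(a) lam * exp(-lam * a)
    f1 <- solve_Xk(1, spec, g1, t_final = config$t_final, h = config$h)
    f2 <- solve_Xk(2, spec, g1, t_final = config$t_final, h = config$h)
    wm <- window_moments_from_fields(f1, f2,
                                     window = p$window %||% c(0, Inf),
                                     t = config$t_final)
    dir.create(file.path(out_dir, "fields"))
    utils::write.csv(data.frame(t = config$t_final,
                                window_lo = (p$window %||% c(0, Inf))[1],
                                window_hi = (p$window %||% c(0, Inf))[2],
                                mean = wm$mean, var = wm$var),
                     file.path(out_dir, "fields", "window_moments.csv"),
                     row.names = FALSE)
    logline("window moments computed")
  }
  meta <- list(config = unclass(config),
               wall_clock_sec = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")),
               package_version = as.character(utils::packageVersion("agekin")))
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logline("run finished")
  invisible(out_dir)
}

#' Ready-made experiment configurations
#'
#' Returns configurations reproducing the package's three reference
#' computational experiments: `"pure-death"` (linear death hazard
#' \eqn{\mu(a)=a}, 10 founders with Gamma(4, 4) initial ages, snapshot at
#' `t = 2`), `"capacity-budding"` (budding with \eqn{\beta_0 = 1}, carrying
#' capacity `K = 5`, one founder, snapshot at `t = 5`) and
#' `"gamma-fission"` (fission-only runs at dispersion
#' \eqn{\alpha \in \{1, 10, 100\}}); `scale = "full"` uses 400000
#' trajectories, `"desk"` 50000.
#'
#' @param which experiment name.
#' @param scale `"desk"` or `"full"`.
#' @param seed master seed stored in the config.
#' @return A [run_config()] (a list of them for `"gamma-fission"`).
#' @export
fixture_config <- function(which = c("pure-death", "capacity-budding",
                                     "gamma-fission"),
                           scale = c("desk", "full"), seed = 1L) {
  which <- match.arg(which)
  scale <- match.arg(scale)
  R <- if (scale == "full") 400000L else 50000L
  switch(which,
    "pure-death" = run_config("simulate", "linear-death",
      params = list(slope = 1, founders = 10L, init_ages = "gamma-unit"),
      R = R, t_final = 2, snapshots = 2, seed = seed),
    "capacity-budding" = run_config("simulate", "capacity",
      params = list(beta0 = 1, K = 5, founders = 1L,
                    init_ages = "gamma-unit"),
      R = R, t_final = 5, snapshots = 5, seed = seed),
    "gamma-fission" = lapply(c(1, 10, 100), function(al)
      run_config("fission", "gamma-fission",
                 params = list(alpha = al, h2 = 1),
                 R = R, t_final = 3, h = 1e-3, seed = seed,
                 method = "volterra")))
}
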