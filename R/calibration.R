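#' Construct an observed response profile
#'
#' Grouped mean (+/- sd) longitudinal CAR-T and tumor measurements for one
#' response group or dose arm, in total cells, with dosing metadata. This is
#' the unit the calibration objective consumes.
#'
#' @param group_label Group name (e.g. "CR", "PR", "NR" or a dose arm).
#' @param cart data.frame with columns \code{time_days}, \code{mean},
#'   \code{sd} (CAR-T total cells).
#' @param tumor data.frame with the same columns (tumor total cells).
#' @param dose_cells Infused dose (cells).
#' @param b0_cells Initial tumor burden (cells).
#' @return A list of class \code{observed_profile}.
#' @export
observed_profile <- function(group_label, cart, tumor, dose_cells,
                             b0_cells) {
  check_series <- function(d, nm) {
    stopifnot(is.data.frame(d))
    need <- c("time_days", "mean", "sd")
    if (!all(need %in% names(d)))
      stop(nm, " series needs columns time_days, mean, sd")
    if (nrow(d) < 3) stop(nm, " series needs at least 3 time points")
    if (any(d$time_days < 0) || is.unsorted(d$time_days, strictly = TRUE))
      stop(nm, " times must be non-negative and strictly increasing")
    if (any(d$sd < 0, na.rm = TRUE)) stop(nm, " sd must be non-negative")
    d
  }
  structure(list(group_label = group_label,
                 cart = check_series(cart, "cart"),
                 tumor = check_series(tumor, "tumor"),
                 dose_cells = dose_cells, b0_cells = b0_cells),
            class = "observed_profile")
}

#' Read grouped profiles from CSV plus dosing metadata
#'
#' The CSV carries columns \code{group}, \code{series} ("cart" or
#' "tumor"), \code{time_days}, \code{mean}, \code{sd} and optionally
#' \code{units} ("cells", "cells_per_ul" or "copies_per_ug"; converted to
#' total cells on read). Metadata supplies \code{dose_cells} and
#' \code{b0_cells} per group, either as a named list or a path to a JSON
#' file keyed by group.
#'
#' @param path Profile CSV path.
#' @param metadata Named list (group -> list(dose_cells, b0_cells)) or a
#'   JSON file path.
#' @param blood_volume_ul Blood volume for concentration units.
#' @return Named list of \code{\link{observed_profile}}s.
#' @export
read_profiles_csv <- function(path, metadata, blood_volume_ul = 2e6) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "series", "time_days", "mean", "sd")
  if (!all(need %in% names(df)))
    stop("profile CSV needs columns: ", paste(need, collapse = ", "))
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- jsonlite::read_json(metadata, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
  to_cells <- function(x, units) {
    if (is.null(units)) return(x)
    switch(units[1],
           cells = x,
           cells_per_ul = x * blood_volume_ul,
           copies_per_ug = convert_units(x, "copies_per_ug_to_cells"),
           stop("unknown units: ", units[1]))
  }
  out <- list()
  for (g in unique(df$group)) {
    md <- metadata[[g]]
    if (is.null(md))
      stop("metadata missing for group ", g)
    sub <- df[df$group == g, ]
    ser <- function(which) {
      s <- sub[sub$series == which, ]
      s <- s[order(s$time_days), ]
      u <- if ("units" %in% names(s)) s$units else NULL
      data.frame(time_days = s$time_days,
                 mean = to_cells(s$mean, u),
                 sd = to_cells(s$sd, u))
    }
    out[[g]] <- observed_profile(g, ser("cart"), ser("tumor"),
                                 dose_cells = md$dose_cells,
                                 b0_cells = md$b0_cells)
  }
  out
}

#' Write or read a parameter set as a flat JSON map
#'
#' @param params A \code{\link{cart_params}} vector.
#' @param path JSON path.
#' @return \code{path} (write) or a \code{cart_params} vector (read).
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(as.list(unclass(cart_params(params))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  cart_params(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
}

# Simulate a profile's conditions and return model values at observed times.
.simulate_at_profile <- function(params, profile, grid_dt = 0.1,
                                 antigen_init_mode = "quasi_steady_state") {
  t_end <- max(profile$cart$time_days, profile$tumor$time_days)
  cfg <- sim_config(dose_cells = profile$dose_cells,
                    b0 = profile$b0_cells,
                    t_end = max(t_end, grid_dt), grid_dt = grid_dt,
                    antigen_init_mode = antigen_init_mode)
  traj <- simulate_cart(params, cfg)
  list(
    cart = approx(traj$time_days, traj$cart_cells,
                  xout = profile$cart$time_days, rule = 2)$y,
    tumor = approx(traj$time_days, traj$b,
                   xout = profile$tumor$time_days, rule = 2)$y
  )
}

#' Log mean squared error calibration objective
#'
#' Mean of squared log10 differences between simulated and observed values,
#' with both simulation and data clipped from below at the lower limit of
#' quantification (points where both fall below the LLQ contribute zero).
#' CAR-T and tumor series are equally weighted (per-series means averaged);
#' missing observations are skipped. Simulation failure returns a fixed
#' penalty of 1e6.
#'
#' @param params A \code{\link{cart_params}} vector (or coercible).
#' @param profiles A list of \code{\link{observed_profile}}s fit jointly with
#'   one shared parameter vector (dose arms differ only in dose input).
#' @param llq_cells Lower limit of quantification, total cells (default 1e6).
#' @param grid_dt Simulation grid (days).
#' @return Non-negative scalar objective.
#' @export
log_mse_objective <- function(params, profiles, llq_cells = 1e6,
                              grid_dt = 0.1) {
  if (inherits(profiles, "observed_profile")) profiles <- list(profiles)
  series_mse <- c()
  for (pr in profiles) {
    sim <- tryCatch(.simulate_at_profile(params, pr, grid_dt = grid_dt),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    for (ser in c("cart", "tumor")) {
      obs <- pr[[ser]]$mean
      keep <- is.finite(obs)
      if (!any(keep)) next
      d <- log10(pmax(sim[[ser]][keep], llq_cells)) -
           log10(pmax(obs[keep], llq_cells))
      series_mse <- c(series_mse, mean(d^2))
    }
  }
  if (!length(series_mse)) stop("no usable observations in profiles")
  mean(series_mse)
}

# Transform between natural and search coordinates (log10 for wide-ranging
# parameters, linear otherwise).
.to_search <- function(p, log_idx) { p[log_idx] <- log10(p[log_idx]); p }
.from_search <- function(x, log_idx) { x[log_idx] <- 10^x[log_idx]; x }

#' Particle swarm optimization over a box
#'
#' Global-best PSO with constriction factor 0.729 and cognitive/social
#' weights 1.49445. Positions are clipped to the box (with velocity reset on
#' the clipped component); the returned trace of best objective values is
#' non-increasing. Deterministic given \code{seed}.
#'
#' @param objective Function of a numeric vector returning a scalar.
#' @param lower,upper Box bounds.
#' @param particles Swarm size (default 100).
#' @param iterations Iteration count (default 100).
#' @param seed Integer seed.
#' @return List with \code{par}, \code{value}, \code{trace}, \code{seed}.
#' @export
pso_optimize <- function(objective, lower, upper, particles = 100,
                         iterations = 100, seed = 1) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            particles >= 1, iterations >= 1)
  d <- length(lower)
  set.seed(seed)
  chi <- 0.729; c1 <- 1.49445; c2 <- 1.49445
  rng <- upper - lower
  X <- matrix(runif(particles * d, lower, upper), nrow = particles,
              byrow = TRUE)
  V <- matrix(runif(particles * d, -rng, rng), nrow = particles,
              byrow = TRUE) * 0.1
  f <- apply(X, 1, objective)
  Pbest <- X; fbest <- f
  g <- which.min(fbest)
  gbest <- Pbest[g, ]; gval <- fbest[g]
  trace <- numeric(iterations + 1)
  trace[1] <- gval
  for (it in seq_len(iterations)) {
    r1 <- matrix(runif(particles * d), particles, d)
    r2 <- matrix(runif(particles * d), particles, d)
    V <- chi * (V + c1 * r1 * (Pbest - X) +
                  c2 * r2 * matrix(gbest, particles, d, byrow = TRUE) -
                  c2 * r2 * X)
    vmax <- matrix(rng, particles, d, byrow = TRUE)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    lo <- matrix(lower, particles, d, byrow = TRUE)
    hi <- matrix(upper, particles, d, byrow = TRUE)
    out <- X < lo | X > hi
    X <- pmin(pmax(X, lo), hi)
    V[out] <- 0
    f <- apply(X, 1, objective)
    improved <- f < fbest
    Pbest[improved, ] <- X[improved, , drop = FALSE]
    fbest[improved] <- f[improved]
    g <- which.min(fbest)
    if (fbest[g] < gval) { gval <- fbest[g]; gbest <- Pbest[g, ] }
    trace[it + 1] <- gval
  }
  list(par = gbest, value = gval, trace = trace, seed = seed)
}

#' Fit model parameters to grouped profiles by particle swarm
#'
#' Minimizes \code{\link{log_mse_objective}} over the calibration box
#' (\code{\link{param_bounds}}). Parameters whose bound ratio spans more than
#' two decades are searched in log10 space.
#'
#' @param profiles A list of \code{\link{observed_profile}}s sharing one
#'   parameter vector.
#' @param particles,iterations PSO settings (published setting 100 x 100).
#' @param seed Integer seed.
#' @param llq_cells LLQ for the objective (cells).
#' @param grid_dt Simulation grid for the objective (days).
#' @return List of class \code{cart_fit}: \code{parameters}
#'   (\code{cart_params}), \code{objective}, \code{trace}, \code{seed}.
#' @export
pso_fit <- function(profiles, particles = 100, iterations = 100, seed = 1,
                    llq_cells = 1e6, grid_dt = 0.1) {
  b <- param_bounds()
  log_idx <- b$upper / b$lower > 100
  lower <- .to_search(b$lower, log_idx)
  upper <- .to_search(b$upper, log_idx)
  obj <- function(x) {
    p <- setNames(.from_search(x, log_idx), .param_names)
    log_mse_objective(p, profiles, llq_cells = llq_cells,
                      grid_dt = grid_dt)
  }
  res <- pso_optimize(obj, lower, upper, particles = particles,
                      iterations = iterations, seed = seed)
  pars <- cart_params(setNames(.from_search(res$par, log_idx),
                               .param_names), check_bounds = TRUE)
  structure(list(parameters = pars, objective = res$value,
                 trace = res$trace, seed = seed),
            class = "cart_fit")
}

#' Repeat-fit ensemble per response group
#'
#' Runs \code{\link{pso_fit}} \code{n_repeats} times per group with distinct
#' seeds derived from the master seed, mirroring repeated swarm starts on a
#' non-identifiable objective. With the defaults (12 repeats, 3 groups) this
#' yields 36 parameter sets.
#'
#' @param profiles_by_group Named list: group label -> list of
#'   \code{\link{observed_profile}}s (or a single profile).
#' @param n_repeats Fits per group (default 12).
#' @param particles,iterations,llq_cells,grid_dt Passed to
#'   \code{\link{pso_fit}}.
#' @param seed Master seed; repeat seeds are drawn reproducibly from it.
#' @return Named list of class \code{cart_ensemble}: group -> list of
#'   \code{cart_fit}.
#' @export
fit_ensemble <- function(profiles_by_group, n_repeats = 12,
                         particles = 100, iterations = 100, seed = 1,
                         llq_cells = 1e6, grid_dt = 0.1) {
  stopifnot(n_repeats >= 1, length(profiles_by_group) >= 1,
            !is.null(names(profiles_by_group)))
  set.seed(seed)
  all_seeds <- matrix(sample.int(2^30, length(profiles_by_group) * n_repeats),
                      nrow = n_repeats)
  ens <- list()
  for (gi in seq_along(profiles_by_group)) {
    gname <- names(profiles_by_group)[gi]
    prof <- profiles_by_group[[gi]]
    if (inherits(prof, "observed_profile")) prof <- list(prof)
    ens[[gname]] <- lapply(seq_len(n_repeats), function(i) {
      pso_fit(prof, particles = particles, iterations = iterations,
              seed = all_seeds[i, gi], llq_cells = llq_cells,
              grid_dt = grid_dt)
    })
  }
  structure(ens, class = "cart_ensemble", master_seed = seed)
}

#' Per-series goodness of fit
#'
#' Pearson correlation between observed means and model values at the
#' observed time points, per series.
#'
#' @param fit A \code{cart_fit} (or a bare \code{cart_params} vector).
#' @param profiles A list of \code{\link{observed_profile}}s.
#' @param grid_dt Simulation grid (days).
#' @return data.frame with columns \code{group}, \code{series}, \code{r},
#'   \code{n_points}.
#' @export
goodness_of_fit <- function(fit, profiles, grid_dt = 0.1) {
  params <- if (inherits(fit, "cart_fit")) fit$parameters else fit
  if (inherits(profiles, "observed_profile")) profiles <- list(profiles)
  rows <- list()
  for (pr in profiles) {
    sim <- .simulate_at_profile(params, pr, grid_dt = grid_dt)
    for (ser in c("cart", "tumor")) {
      obs <- pr[[ser]]$mean
      keep <- is.finite(obs) & is.finite(sim[[ser]])
      if (sum(keep) < 3)
        stop("fewer than 3 paired points for ", pr$group_label, "/", ser)
      rows[[length(rows) + 1]] <- data.frame(
        group = pr$group_label, series = ser,
        r = cor(obs[keep], sim[[ser]][keep]), n_points = sum(keep))
    }
  }
  do.call(rbind, rows)
}

#' Serialize a fitted ensemble to JSON
#'
#' @param ensemble A \code{cart_ensemble}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
ensemble_to_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cart_ensemble"))
  obj <- lapply(ensemble, function(fits) lapply(fits, function(f) {
    list(parameters = as.list(unclass(f$parameters)),
         objective = f$objective, seed = f$seed, trace = f$trace)
  }))
  jsonlite::write_json(list(master_seed = attr(ensemble, "master_seed"),
                            groups = obj),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fitted ensemble from JSON
#'
#' @param path Path written by \code{\link{ensemble_to_json}}.
#' @return A \code{cart_ensemble}.
#' @export
ensemble_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  ens <- lapply(raw$groups, function(fits) lapply(fits, function(f) {
    structure(list(parameters = cart_params(unlist(f$parameters)),
                   objective = f$objective, seed = f$seed,
                   trace = unlist(f$trace)),
              class = "cart_fit")
  }))
  structure(ens, class = "cart_ensemble", master_seed = raw$master_seed)
}

# Flatten an ensemble to a parameter matrix (sets x 27).
ensemble_param_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "cart_ensemble"))
  sets <- unlist(ensemble, recursive = FALSE)
  m <- t(vapply(sets, function(f) as.numeric(f$parameters),
                numeric(length(.param_names))))
  colnames(m) <- .param_names
  rownames(m) <- paste(rep(names(ensemble),
                           vapply(ensemble, length, 1L)),
                       unlist(lapply(ensemble, seq_along)), sep = "_")
  m
}
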