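#' Hill switch function
#'
#' Saturable antigen-sensing switch used throughout the toggle-switch model:
#' \code{up} is \eqn{x^n / (h^n + x^n)}, \code{down} its complement. The same
#' form gates memory self-renewal versus differentiation, effector
#' proliferation, exhaustion, memory regeneration and tumor killing, each
#' with its own exponent.
#'
#' @param x Input (antigen molecules or cells), non-negative.
#' @param half_max Half-maximum (same units as \code{x}), positive.
#' @param exponent Hill exponent, positive.
#' @param direction \code{"up"} (increasing) or \code{"down"} (\code{1 - up}).
#' @return Fraction in \code{[0, 1]}, vectorized over \code{x}.
#' @export
hill <- function(x, half_max, exponent, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(half_max) || half_max <= 0)
    stop("half_max must be positive")
  if (!is.numeric(exponent) || exponent <= 0)
    stop("exponent must be positive")
  if (any(x < 0)) stop("x must be non-negative")
  r <- (x / half_max)^exponent
  up <- ifelse(x == 0, 0, r / (1 + r))
  if (direction == "up") up else 1 - up
}

.state_names <- c("dose", "dosex", "t_m", "t_e1", "t_e2", "t_x", "b", "b_a")

#' Right-hand side of the toggle-switch ODE system
#'
#' The eight coupled equations: dose transfer (\code{dose}, \code{dosex}),
#' memory (\code{t_m}), pre-cytotoxic and cytotoxic effectors (\code{t_e1},
#' \code{t_e2}), exhausted cells (\code{t_x}), tumor B cells (\code{b},
#' logistic growth with saturable killing by \code{t_e2}) and tumor antigen
#' (\code{b_a}, produced by \code{b} and cleared first-order). The antigen
#' toggle switch shares one half-maximum \code{b50} across T-cell fates but
#' uses fate-specific exponents. This reference implementation in R mirrors
#' the compiled right-hand side used by \code{\link{simulate_cart}}; the two
#' are tested for agreement.
#'
#' @param state Named numeric state vector (cells; \code{b_a} in molecules).
#' @param params A \code{\link{cart_params}} vector.
#' @return Named numeric vector of time derivatives (per day).
#' @export
cart_derivatives <- function(state, params) {
  if (any(is.na(state)) || any(state < 0))
    stop("state must be non-negative and finite")
  s <- as.numeric(state[.state_names])
  if (any(is.na(s))) stop("state must contain: ",
                          paste(.state_names, collapse = ", "))
  p <- as.list(unclass(cart_params(params)))
  dose <- s[1]; dosex <- s[2]; t_m <- s[3]; t_e1 <- s[4]
  t_e2 <- s[5]; t_x <- s[6]; b <- s[7]; b_a <- s[8]
  hm <- hill(b_a, p$b50, p$km)
  hr <- hill(b_a, p$b50, p$kr)
  he <- hill(b_a, p$b50, p$ke)
  hx <- hill(b_a, p$b50, p$kx)
  ht <- hill(t_e2, p$tk50, p$kt)
  frac_sum <- p$f_tm + p$f_te1 + p$f_te2 + p$f_tx
  c(
    dose  = -(1 + p$f_loss) * dose,
    dosex = dose - frac_sum * dosex,
    t_m   = p$mu_m * (2 * p$f_max * (1 - hm) - 1) * t_m +
            p$r_m * (1 - hr) * t_e2 - p$d_m * t_m + p$f_tm * dosex,
    t_e1  = 2 * p$mu_m * (1 - p$f_max * (1 - hm)) * t_m -
            p$mu_e * he * t_e1 - p$d_e1 * t_e1 + p$f_te1 * dosex,
    t_e2  = p$mu_e * 2^p$n_doub * he * t_e1 - p$k_ex * hx * t_e2 -
            p$r_m * (1 - hr) * t_e2 - p$d_e2 * t_e2 + p$f_te2 * dosex,
    t_x   = p$k_ex * hx * t_e2 - p$d_x * t_x + p$f_tx * dosex,
    b     = p$mu_b * (1 - b / p$b_max) * b - p$k_kill * ht * b,
    b_a   = p$k_b1 * b - p$k_b2 * b_a
  )
}

#' Simulation configuration
#'
#' @param dose_cells Infused CAR-T dose (cells).
#' @param b0 Initial tumor burden (cells).
#' @param t_end Simulation horizon (days).
#' @param grid_dt Output/clamping grid step (days). The extinction clamp is
#'   applied between grid intervals.
#' @param extinction_threshold Cell populations below this count are set to
#'   exactly zero at grid points (default 1 cell).
#' @param blood_volume_ul Blood volume in microliters used for concentration
#'   observables (human default 2 L).
#' @param antigen_init_mode \code{"quasi_steady_state"} starts antigen at
#'   \code{k_b1 * b0 / k_b2} (tumor established before infusion);
#'   \code{"zero"} starts it at 0.
#' @param rtol,atol Integrator relative/absolute tolerance (cells).
#' @return A list of class \code{cart_sim_config}.
#' @export
sim_config <- function(dose_cells = 1e8, b0 = 1e10, t_end = 90,
                       grid_dt = 0.1, extinction_threshold = 1,
                       blood_volume_ul = 2e6,
                       antigen_init_mode = c("quasi_steady_state", "zero"),
                       rtol = 1e-8, atol = 1e-4) {
  antigen_init_mode <- match.arg(antigen_init_mode)
  stopifnot(t_end > 0, grid_dt > 0, extinction_threshold >= 0,
            dose_cells >= 0, b0 >= 0, blood_volume_ul > 0)
  structure(list(dose_cells = dose_cells, b0 = b0, t_end = t_end,
                 grid_dt = grid_dt,
                 extinction_threshold = extinction_threshold,
                 blood_volume_ul = blood_volume_ul,
                 antigen_init_mode = antigen_init_mode,
                 rtol = rtol, atol = atol),
            class = "cart_sim_config")
}

#' Simulate the CAR-T toggle-switch model
#'
#' Integrates the eight-state system on a uniform grid with an adaptive
#' embedded Runge-Kutta method, applying the extinction clamp (cell
#' populations with fractional counts set to exactly zero) between grid
#' intervals. Initial condition: \code{dose} compartment holds the full dose,
#' tumor at \code{b0}, antigen per \code{antigen_init_mode}, all T-cell
#' compartments zero.
#'
#' @param params A \code{\link{cart_params}} vector.
#' @param config A \code{\link{sim_config}} list.
#' @return A \code{cart_trajectory}: data.frame with \code{time_days}, the
#'   eight states, and derived observables \code{cart_cells} (total of the
#'   four T-cell compartments), \code{cart_cells_per_ul},
#'   \code{tumor_cells_per_ul} and \code{tumor_pct_change}; attributes carry
#'   the params and config.
#' @export
simulate_cart <- function(params, config = sim_config()) {
  p <- cart_params(params)
  stopifnot(inherits(config, "cart_sim_config"))
  times <- seq(0, config$t_end, by = config$grid_dt)
  ba0 <- switch(config$antigen_init_mode,
                zero = 0,
                quasi_steady_state = p[["k_b1"]] * config$b0 / p[["k_b2"]])
  y0 <- c(config$dose_cells, 0, 0, 0, 0, 0, config$b0, ba0)
  mat <- tryCatch(
    .cart_integrate_cpp(y0, as.numeric(p), times,
                        config$extinction_threshold, config$rtol,
                        config$atol),
    error = function(e) {
      stop("simulation failed: ", conditionMessage(e),
           " [dose=", config$dose_cells, ", b0=", config$b0, "]",
           call. = FALSE)
    })
  colnames(mat) <- .state_names
  out <- data.frame(time_days = times, mat, check.names = FALSE)
  out$cart_cells <- out$t_m + out$t_e1 + out$t_e2 + out$t_x
  out$cart_cells_per_ul <- out$cart_cells / config$blood_volume_ul
  out$tumor_cells_per_ul <- out$b / config$blood_volume_ul
  out$tumor_pct_change <- if (config$b0 > 0)
    100 * (out$b - config$b0) / config$b0 else NA_real_
  structure(out, class = c("cart_trajectory", "data.frame"),
            params = p, config = config)
}

#' Unit conversions at the model's I/O boundary
#'
#' \code{copies_per_ug_to_cells}: vector transgene copies per microgram of
#' genomic DNA to circulating CAR-T cell count (empirical factor ~1e4 cells
#' per copy/ug). \code{cells_to_cells_per_ul}: absolute count to
#' concentration given a blood volume. \code{tumor_cells_to_percent_change}:
#' absolute tumor burden to percent change from baseline.
#'
#' @param value Numeric value(s) to convert (positive).
#' @param mode One of \code{"copies_per_ug_to_cells"},
#'   \code{"cells_to_cells_per_ul"}, \code{"tumor_cells_to_percent_change"}.
#' @param blood_volume_ul Blood volume (microliters); required for
#'   concentration conversion. Human default 2e6 (2 L); mouse 2.
#' @param baseline_cells Baseline tumor burden; required for percent change.
#' @param copies_factor Cells per (copy/ug), default 1e4.
#' @return Converted numeric value(s).
#' @export
convert_units <- function(value,
                          mode = c("copies_per_ug_to_cells",
                                   "cells_to_cells_per_ul",
                                   "tumor_cells_to_percent_change"),
                          blood_volume_ul = NULL, baseline_cells = NULL,
                          copies_factor = 1e4) {
  mode <- match.arg(mode)
  if (any(value < 0)) stop("value must be non-negative")
  switch(mode,
    copies_per_ug_to_cells = value * copies_factor,
    cells_to_cells_per_ul = {
      if (is.null(blood_volume_ul))
        stop("blood_volume_ul required for concentration conversion")
      value / blood_volume_ul
    },
    tumor_cells_to_percent_change = {
      if (is.null(baseline_cells) || baseline_cells <= 0)
        stop("positive baseline_cells required for percent change")
      100 * (value - baseline_cells) / baseline_cells
    })
}

#' Write a trajectory to CSV
#'
#' @param traj A \code{cart_trajectory}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cart_trajectory"))
  out <- data.frame(
    time_days = traj$time_days, dose = traj$dose, doseX = traj$dosex,
    t_mem = traj$t_m, t_eff1 = traj$t_e1, t_eff2 = traj$t_e2,
    t_exh = traj$t_x, tumor_cells = traj$b, antigen = traj$b_a,
    cart_cells_per_ul = traj$cart_cells_per_ul,
    tumor_cells_per_ul = traj$tumor_cells_per_ul,
    tumor_pct_change = traj$tumor_pct_change
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
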