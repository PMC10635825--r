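#' Exposure metrics from a trajectory
#'
#' Trapezoidal AUC of circulating CAR-T concentration over \code{[0,
#' horizon]}, peak concentration (Cmax) with its time (tmax), and tumor AUC
#' on the same concentration scale.
#'
#' @param traj A \code{cart_trajectory}.
#' @param horizon Days; must not exceed the trajectory's span.
#' @return List with \code{cart_auc} (cells x day / ul), \code{cmax}
#'   (cells/ul), \code{tmax} (days), \code{tumor_auc} (cells x day / ul).
#' @export
exposure_metrics <- function(traj, horizon = max(traj$time_days)) {
  stopifnot(inherits(traj, "cart_trajectory"))
  if (horizon > max(traj$time_days) + 1e-9)
    stop("horizon exceeds trajectory span")
  keep <- traj$time_days <= horizon + 1e-9
  t <- traj$time_days[keep]
  trap <- function(y) sum(diff(t) * (head(y, -1) + y[-1]) / 2)
  cc <- traj$cart_cells_per_ul[keep]
  i <- which.max(cc)
  list(cart_auc = trap(cc), cmax = cc[i], tmax = t[i],
       tumor_auc = trap(traj$tumor_cells_per_ul[keep]))
}

#' Build a virtual patient population
#'
#' Monte Carlo cohort: each subject draws a whole fitted parameter vector
#' uniformly from the ensemble and, depending on \code{mode}, a CAR-T dose
#' (log-uniform in [1e7, 1e9] cells) and/or an initial tumor burden
#' (log-uniform in [8.5e8, 2.7e10] cells); the subject is then simulated and
#' summarized by exposure metrics. Response is defined as tumor AUC below
#' \code{tumor_auc_threshold}.
#'
#' @param ensemble A \code{cart_ensemble} (or a list of \code{cart_params}).
#' @param mode \code{"dose_and_b0"}, \code{"dose_only"} or \code{"b0_only"}.
#' @param n Cohort size (default 1000).
#' @param seed Integer seed; subject i is reproducible from (seed, i).
#' @param horizon Simulation/exposure horizon (days, default 365).
#' @param dose_range,b0_range Sampling ranges (cells).
#' @param fixed_dose,fixed_b0 Values used when a dimension is not randomized.
#' @param tumor_auc_threshold Response cut-off (cells x day / ul, default
#'   1e4).
#' @param grid_dt Simulation grid (days).
#' @return data.frame of class \code{virtual_cohort}: \code{subject_id},
#'   \code{param_set_id}, \code{dose}, \code{b0}, \code{cart_auc},
#'   \code{cmax}, \code{tmax}, \code{tumor_auc}, \code{responder}.
#' @export
build_virtual_population <- function(ensemble,
                                     mode = c("dose_and_b0", "dose_only",
                                              "b0_only"),
                                     n = 1000, seed = 1, horizon = 365,
                                     dose_range = c(1e7, 1e9),
                                     b0_range = c(8.5e8, 2.7e10),
                                     fixed_dose = 1e8, fixed_b0 = 1e10,
                                     tumor_auc_threshold = 1e4,
                                     grid_dt = 0.1) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  pm <- if (inherits(ensemble, "cart_ensemble")) {
    ensemble_param_matrix(ensemble)
  } else {
    m <- t(vapply(ensemble, function(p) as.numeric(cart_params(p)),
                  numeric(length(.param_names))))
    colnames(m) <- .param_names
    rownames(m) <- paste0("set_", seq_len(nrow(m)))
    m
  }
  set.seed(seed)
  idx <- sample.int(nrow(pm), n, replace = TRUE)
  loguni <- function(r) 10^runif(n, log10(r[1]), log10(r[2]))
  dose <- if (mode %in% c("dose_and_b0", "dose_only")) loguni(dose_range)
          else rep(fixed_dose, n)
  b0 <- if (mode %in% c("dose_and_b0", "b0_only")) loguni(b0_range)
        else rep(fixed_b0, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- cart_params(setNames(pm[idx[i], ], .param_names))
    traj <- simulate_cart(p, sim_config(dose_cells = dose[i], b0 = b0[i],
                                        t_end = horizon,
                                        grid_dt = grid_dt))
    m <- exposure_metrics(traj, horizon)
    rows[[i]] <- data.frame(subject_id = i,
                            param_set_id = rownames(pm)[idx[i]],
                            dose = dose[i], b0 = b0[i],
                            cart_auc = m$cart_auc, cmax = m$cmax,
                            tmax = m$tmax, tumor_auc = m$tumor_auc)
  }
  out <- do.call(rbind, rows)
  out$responder <- out$tumor_auc < tumor_auc_threshold
  structure(out, class = c("virtual_cohort", "data.frame"),
            mode = mode, seed = seed,
            tumor_auc_threshold = tumor_auc_threshold)
}

#' Univariable response-covariate logistic regressions
#'
#' Logistic regressions of responder status on log10 initial tumor burden,
#' log10 Cmax and log10(Cmax / tumor burden) across a virtual cohort, with
#' Wald confidence intervals. Complete separation is reported as a flag
#' rather than through inflated coefficients.
#'
#' @param cohort A \code{virtual_cohort}.
#' @param conf_level Wald CI level (default 0.95).
#' @return data.frame: \code{covariate}, \code{slope}, \code{se}, \code{z},
#'   \code{p_value}, \code{ci_lower}, \code{ci_upper}, \code{separation}.
#' @export
response_covariate_analysis <- function(cohort, conf_level = 0.95) {
  stopifnot(is.data.frame(cohort))
  y <- cohort$responder
  if (all(y)) stop("single-class cohort: all responders")
  if (!any(y)) stop("single-class cohort: all non-responders")
  covs <- list(log10_b0 = log10(cohort$b0),
               log10_cmax = log10(pmax(cohort$cmax, .Machine$double.xmin)),
               log10_cmax_over_b0 =
                 log10(pmax(cohort$cmax, .Machine$double.xmin) / cohort$b0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(names(covs), function(nm) {
    x <- covs[[nm]]
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    co <- summary(fit)$coefficients
    fitted_p <- fitted(fit)
    sep <- all(fitted_p[y] > 1 - 1e-6) && all(fitted_p[!y] < 1e-6)
    data.frame(covariate = nm, slope = co["x", "Estimate"],
               se = co["x", "Std. Error"], z = co["x", "z value"],
               p_value = co["x", "Pr(>|z|)"],
               ci_lower = co["x", "Estimate"] - zq * co["x", "Std. Error"],
               ci_upper = co["x", "Estimate"] + zq * co["x", "Std. Error"],
               separation = sep)
  })
  do.call(rbind, rows)
}

#' Local parameter sensitivity coefficients
#'
#' Percent change in CAR-T AUC and tumor AUC per percent change in each
#' parameter: LPSC = (dY/Y)/(dX/X) * 100, from a forward perturbation
#' (default +10 percent) around a parameter set. Given an ensemble, the
#' median LPSC across its parameter sets is reported.
#'
#' @param params A \code{cart_params} vector or a \code{cart_ensemble}.
#' @param config \code{\link{sim_config}} for the baseline simulation.
#' @param delta Relative perturbation (default 0.1).
#' @param horizon AUC horizon (days); defaults to the config's t_end.
#' @param outputs Named list of trajectory functionals (each
#'   \code{function(traj) -> scalar}); defaults to CAR-T AUC and tumor AUC.
#' @return data.frame: \code{parameter}, then one \code{<output>_lpsc}
#'   column per output. Entries are \code{NA} (flagged) when the baseline
#'   output is zero.
#' @export
local_sensitivity <- function(params, config = sim_config(t_end = 365),
                              delta = 0.1, horizon = config$t_end,
                              outputs = NULL) {
  if (is.null(outputs))
    outputs <- list(
      cart_auc = function(tr) exposure_metrics(tr, horizon)$cart_auc,
      tumor_auc = function(tr) exposure_metrics(tr, horizon)$tumor_auc)
  cols <- paste0(names(outputs), "_lpsc")
  if (inherits(params, "cart_ensemble")) {
    pm <- ensemble_param_matrix(params)
    tabs <- lapply(seq_len(nrow(pm)), function(i)
      local_sensitivity(cart_params(setNames(pm[i, ], .param_names)),
                        config, delta, horizon, outputs))
    out <- tabs[[1]]
    for (cl in cols)
      out[[cl]] <- apply(sapply(tabs, `[[`, cl), 1, median, na.rm = TRUE)
    return(out)
  }
  p0 <- cart_params(params)
  eval_outputs <- function(p) {
    tr <- simulate_cart(p, config)
    vapply(outputs, function(f) f(tr), 0)
  }
  base <- eval_outputs(p0)
  one <- function(nm) {
    p1 <- unclass(p0)
    p1[nm] <- p1[nm] * (1 + delta)
    y <- eval_outputs(cart_params(p1))
    ifelse(base > 0, (y - base) / base / delta * 100, NA_real_)
  }
  res <- matrix(vapply(.param_names, one, numeric(length(outputs))),
                nrow = length(outputs))
  out <- data.frame(parameter = .param_names, row.names = NULL)
  for (k in seq_along(cols)) out[[cols[k]]] <- res[k, ]
  out
}

#' PCA of log-scaled fitted parameters
#'
#' Principal component analysis of the log10 parameter sets of an ensemble
#' (centered, unit-variance scaled). Constant columns are dropped with a
#' warning.
#'
#' @param ensemble A \code{cart_ensemble} or a numeric matrix (sets x
#'   parameters, natural scale).
#' @return List: \code{scores}, \code{loadings}, \code{percent_variance}
#'   (sums to 100), \code{dropped} (constant columns).
#' @export
parameter_pca <- function(ensemble) {
  pm <- if (inherits(ensemble, "cart_ensemble"))
    ensemble_param_matrix(ensemble) else as.matrix(ensemble)
  if (nrow(pm) < 3) stop("need at least 3 parameter sets")
  lp <- log10(pm)
  const <- apply(lp, 2, function(x) max(x) - min(x) < 1e-12)
  if (any(const)) {
    warning("dropping constant parameter columns: ",
            paste(colnames(lp)[const], collapse = ", "))
    lp <- lp[, !const, drop = FALSE]
  }
  pc <- prcomp(lp, center = TRUE, scale. = TRUE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, percent_variance = pv,
       dropped = colnames(pm)[const])
}

#' T-cell compartment composition at a time point
#'
#' Fractions of memory, effector (both effector compartments pooled) and
#' exhausted cells among total T cells at time \code{t}, and the percent of
#' the population that is non-exhausted.
#'
#' @param traj A \code{cart_trajectory}.
#' @param t Time (days) within the trajectory's span.
#' @return List: \code{frac_memory}, \code{frac_effector},
#'   \code{frac_exhausted}, \code{percent_non_exhausted}.
#' @export
state_composition <- function(traj, t) {
  stopifnot(inherits(traj, "cart_trajectory"))
  if (t < min(traj$time_days) || t > max(traj$time_days))
    stop("t outside trajectory horizon")
  i <- which.min(abs(traj$time_days - t))
  tot <- traj$cart_cells[i]
  if (tot <= 0) stop("total T cells is zero at t=", t)
  list(frac_memory = traj$t_m[i] / tot,
       frac_effector = (traj$t_e1[i] + traj$t_e2[i]) / tot,
       frac_exhausted = traj$t_x[i] / tot,
       percent_non_exhausted = 100 * (1 - traj$t_x[i] / tot))
}
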