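#' @useDynLib cartqsp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rlnorm rbinom rpois rgamma rmultinom
#'   setNames quantile median sd var prcomp glm glm.fit binomial coef vcov
#'   logLik
#'   pbinom wilcox.test p.adjust pt approx cor predict fitted plogis qnorm
#'   chisq.test aggregate
#' @importFrom utils head read.csv write.csv write.table modifyList
NULL

# Canonical parameter order. Shared with the C++ right-hand side; do not
# reorder without updating src/cart_ode.cpp.
.param_names <- c(
  "b50", "mu_b", "k_kill", "f_loss", "tk50", "kt", "k_b1", "k_b2",
  "mu_m", "km", "f_max", "ke", "mu_e", "n_doub", "k_ex",
  "d_m", "d_e1", "d_e2", "d_x", "b_max", "kx", "kr", "r_m",
  "f_tm", "f_te1", "f_te2", "f_tx"
)

#' Kinetic parameter bounds for the CAR-T toggle-switch model
#'
#' Lower and upper box bounds for the 27 kinetic and dosing parameters, used
#' both to validate fitted parameter sets and as the search box for particle
#' swarm calibration. Rates are per day, antigen half-maxima in antigen
#' molecules, cell half-maxima and carrying capacity in cells; Hill exponents,
#' the maximum self-renewal fraction \code{f_max} and the population-doubling
#' number \code{n_doub} are dimensionless. The dose-routing coefficients
#' \code{f_tm}..\code{f_tx} are first-order rates (1/day) whose ratios set the
#' infused product's compartment composition.
#'
#' @return A data.frame with columns \code{parameter}, \code{lower},
#'   \code{upper}, one row per parameter in canonical order.
#' @export
param_bounds <- function() {
  data.frame(
    parameter = .param_names,
    lower = c(1e6, 0.001, 0.001, 1, 1e5, 0.2, 0.001, 0.001,
              0.001, 0.2, 0.5, 0.2, 0.001, 4, 0.001,
              0.001, 0.001, 0.001, 0.001, 1e8, 0.2, 0.2, 0.001,
              1, 1, 30, 5),
    upper = c(1e10, 0.1, 1, 1000, 1e9, 3, 1, 1,
              1, 3, 0.99, 3, 1, 12, 1,
              1, 1, 1, 1, 1e12, 3, 3, 1,
              10, 10, 70, 30),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated model parameter set
#'
#' @param ... Named parameter values (or a single named list/vector). All 27
#'   parameters must be supplied; see \code{\link{param_bounds}} for names.
#' @param check_bounds If \code{TRUE}, additionally require every value to lie
#'   within its calibration box bound (used for fitted sets; direct
#'   construction for limiting-case simulations may switch this off).
#' @return A named numeric vector of class \code{cart_params} in canonical
#'   order.
#' @export
cart_params <- function(..., check_bounds = FALSE) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || is.numeric(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  vals <- unlist(dots)
  missing <- setdiff(.param_names, names(vals))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), .param_names)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  p <- vals[.param_names]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all parameters must be finite and strictly positive")
  if (check_bounds) {
    b <- param_bounds()
    bad <- p < b$lower | p > b$upper
    if (any(bad))
      stop("parameters outside calibration bounds: ",
           paste(.param_names[bad], collapse = ", "))
  }
  structure(p, class = "cart_params")
}

#' @export
print.cart_params <- function(x, ...) {
  cat("CAR-T toggle-switch model parameters (27):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Archetype parameter presets
#'
#' Synthetic "complete responder"-like and "non-responder"-like parameter
#' sets, all inside the calibration box. The CR-like archetype combines a high
#' memory proliferation rate, potent killing (low \code{tk50}, high
#' \code{k_kill}) and slow exhaustion, yielding strong expansion and tumor
#' clearance; the NR-like archetype reverses these, yielding weak expansion,
#' rapid exhaustion and tumor progression. These are package-defined synthetic
#' archetypes for generators and benchmarks, not fitted clinical values.
#'
#' @param which One of \code{"CR"}, \code{"PR"}, \code{"NR"}.
#' @return A \code{cart_params} vector.
#' @export
archetype_params <- function(which = c("CR", "PR", "NR")) {
  which <- match.arg(which)
  base <- c(
    b50 = 1e8, mu_b = 0.01, k_kill = 0.5, f_loss = 9, tk50 = 1e7,
    kt = 1, k_b1 = 0.1, k_b2 = 0.5, mu_m = 0.5, km = 2, f_max = 0.55,
    ke = 2, mu_e = 0.2, n_doub = 6, k_ex = 0.05, d_m = 0.2,
    d_e1 = 0.1, d_e2 = 0.2, d_x = 0.3, b_max = 1e11, kx = 2, kr = 2,
    r_m = 0.01, f_tm = 5, f_te1 = 5, f_te2 = 50, f_tx = 10
  )
  over <- switch(which,
    CR = c(mu_m = 0.8, mu_e = 0.5, n_doub = 9, k_kill = 0.8,
           tk50 = 1e8, k_ex = 0.02),
    PR = c(mu_m = 0.5, mu_e = 0.45, n_doub = 8.5, k_kill = 0.3,
           tk50 = 1e8, k_ex = 0.12),
    NR = c(mu_m = 0.15, mu_e = 0.25, n_doub = 7, k_kill = 0.02,
           tk50 = 5e8, k_ex = 0.2, d_m = 0.02))
  base[names(over)] <- over
  cart_params(base, check_bounds = TRUE)
}

# Parameters searched in log10 space during calibration: box bound ratio
# exceeds 100 (spans decades).
.log_scale_params <- function() {
  b <- param_bounds()
  b$parameter[b$upper / b$lower > 100]
}
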