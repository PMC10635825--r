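test_that("hill switch has half-maximum, zero and complement properties", {
  expect_equal(hill(1e8, 1e8, 2.7), 0.5)
  expect_equal(hill(0, 1e8, 2), 0)
  ba <- 10^seq(0, 12, length.out = 40)
  expect_equal(hill(ba, 1e8, 1.3, "up") + hill(ba, 1e8, 1.3, "down"),
               rep(1, length(ba)))
  expect_true(all(diff(hill(ba, 1e8, 0.7)) > 0))
  expect_error(hill(1, -1, 1), "half_max")
  expect_error(hill(1, 1, 0), "exponent")
})

test_that("memory equation matches symbolic limiting cases", {
  # no antigen, no effectors: dT_M/dt = (mu_M (2 f_max - 1) - d_M) T_M
  p <- unclass(archetype_params("CR"))
  p[c("mu_m", "f_max", "d_m")] <- c(0.5, 0.99, 0.1)
  st <- c(dose = 0, dosex = 0, t_m = 1e6, t_e1 = 0, t_e2 = 0, t_x = 0,
          b = 0, b_a = 0)
  d <- cart_derivatives(st, p)
  expect_equal(unname(d["t_m"]), 3.9e5)
  # saturating antigen: self-renewal and regeneration both off
  st2 <- st; st2["b_a"] <- 1e20
  d2 <- cart_derivatives(st2, p)
  expect_equal(unname(d2["t_m"]), -(0.5 + 0.1) * 1e6, tolerance = 1e-9)
})

test_that("tumor equation is stationary at carrying capacity without killing", {
  p <- unclass(tumor_only_params(mu_b = 0.05, b_max = 1e11))
  st <- c(dose = 0, dosex = 0, t_m = 0, t_e1 = 0, t_e2 = 0, t_x = 0,
          b = 1e11, b_a = 0)
  d <- cart_derivatives(st, p)
  expect_equal(unname(d["b"]), 0, tolerance = 1e-3)
  expect_error(cart_derivatives(replace(st, "b", -1), p), "non-negative")
})

test_that("R and compiled right-hand sides agree on random states", {
  set.seed(42)
  for (i in 1:25) {
    b <- param_bounds()
    p <- cart_params(setNames(
      10^runif(nrow(b), log10(b$lower), log10(b$upper)), b$parameter))
    st <- setNames(10^runif(8, 0, 10), cartqsp:::.state_names)
    expect_equal(unname(cartqsp:::.cart_rhs_cpp(as.numeric(st[cartqsp:::.state_names]),
                                                as.numeric(p))),
                 unname(cart_derivatives(st, p)),
                 tolerance = 1e-12)
  }
})

test_that("dosing subsystem conserves and routes the transferred dose", {
  p <- kinetics_free_params(f_loss = 9, routing = c(1, 1, 2, 1))
  cfg <- sim_config(dose_cells = 1e8, b0 = 0, t_end = 30,
                    extinction_threshold = 0)
  tr <- simulate_cart(p, cfg)
  final <- tr[nrow(tr), ]
  total <- final$cart_cells
  expect_equal(total, 1e8 / (1 + 9), tolerance = 1e-3)
  expect_equal(final$t_e2 / total, 2 / 5, tolerance = 1e-3)
  expect_equal(final$t_m / total, 1 / 5, tolerance = 1e-3)
  expect_equal(final$t_x / total, 1 / 5, tolerance = 1e-3)
})

test_that("tumor follows the logistic closed form without killing", {
  mu <- 0.05; bmax <- 1e11; b0 <- 1e9
  tr <- simulate_cart(tumor_only_params(mu, bmax),
                      sim_config(dose_cells = 0, b0 = b0, t_end = 200))
  t <- tr$time_days
  exact <- bmax * b0 * exp(mu * t) / (bmax + b0 * (exp(mu * t) - 1))
  expect_lt(max(abs(tr$b - exact) / exact), 1e-6)
})

test_that("populations below the extinction threshold are zero at all later grid points", {
  # dose compartment decays below 1 cell and must stay exactly zero
  p <- kinetics_free_params(f_loss = 1, routing = c(1, 1, 2, 1), eps = 0.2)
  tr <- simulate_cart(p, sim_config(dose_cells = 30, b0 = 0, t_end = 60))
  for (col in c("dose", "dosex", "t_m", "t_e1", "t_e2", "t_x")) {
    v <- tr[[col]]
    # after the compartment's peak there is no influx left: once it dips
    # below one cell it must be exactly zero at every later grid point
    post_peak <- seq(which.max(v), length(v))
    first_zero <- post_peak[which(v[post_peak] < 1)[1]]
    expect_false(is.na(first_zero))
    expect_true(all(v[first_zero:length(v)] == 0),
                label = paste("clamped column", col))
  }
})

test_that("zero dose and zero tumor give the identically-zero trajectory", {
  tr <- simulate_cart(archetype_params("CR"),
                      sim_config(dose_cells = 0, b0 = 0, t_end = 30))
  expect_true(all(as.matrix(tr[cartqsp:::.state_names]) == 0))
})

test_that("trajectories are non-negative and tumor is bounded without killing", {
  set.seed(7)
  b <- param_bounds()
  for (i in 1:8) {
    p <- cart_params(setNames(
      10^runif(nrow(b), log10(b$lower), log10(b$upper)), b$parameter))
    tr <- simulate_cart(p, sim_config(t_end = 60))
    expect_true(all(as.matrix(tr[cartqsp:::.state_names]) >= 0))
  }
  pb <- unclass(tumor_only_params(mu_b = 0.08, b_max = 1e9))
  tr <- simulate_cart(cart_params(pb),
                      sim_config(dose_cells = 0, b0 = 5e9, t_end = 120))
  expect_true(all(tr$b <= 5e9 * (1 + 1e-9)))
})

test_that("trajectories agree with an independent reference integrator", {
  p <- archetype_params("PR")
  cfg <- sim_config(t_end = 30, extinction_threshold = 0)
  tr <- simulate_cart(p, cfg)
  rhs <- function(t, y, parms) {
    names(y) <- cartqsp:::.state_names
    list(cart_derivatives(pmax(y, 0), parms))
  }
  y0 <- c(cfg$dose_cells, 0, 0, 0, 0, 0, cfg$b0,
          p[["k_b1"]] * cfg$b0 / p[["k_b2"]])
  ref <- deSolve::lsoda(y0, seq(0, 30, by = 0.1), rhs, p,
                        rtol = 1e-10, atol = 1e-6)
  tot_ref <- rowSums(ref[, 4:7])
  keep <- tot_ref > 1  # compare above the extinction scale
  expect_lt(max(abs(tr$cart_cells[keep] - tot_ref[keep]) /
                  tot_ref[keep]), 1e-4)
  expect_lt(max(abs(tr$b - ref[, 8]) / pmax(ref[, 8], 1)), 1e-4)
})

test_that("halving the grid step changes CAR-T AUC by under 0.5 percent", {
  p <- archetype_params("CR")
  a1 <- exposure_metrics(simulate_cart(p, sim_config(t_end = 90,
                                                     grid_dt = 0.1)), 90)
  a2 <- exposure_metrics(simulate_cart(p, sim_config(t_end = 90,
                                                     grid_dt = 0.05)), 90)
  expect_lt(abs(a1$cart_auc - a2$cart_auc) / a2$cart_auc, 0.005)
})

test_that("unit conversions match their scaling factors and invert", {
  expect_equal(convert_units(250, "copies_per_ug_to_cells"), 2.5e6)
  expect_equal(convert_units(2e9, "cells_to_cells_per_ul",
                             blood_volume_ul = 2e6), 1e3)
  expect_equal(convert_units(5e9, "tumor_cells_to_percent_change",
                             baseline_cells = 1e10), -50)
  expect_error(convert_units(1, "cells_to_cells_per_ul"), "blood_volume")
  expect_error(convert_units(1, "tumor_cells_to_percent_change"),
               "baseline")
})

test_that("trajectory CSV export carries the declared columns", {
  tr <- simulate_cart(archetype_params("NR"), sim_config(t_end = 10))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- read.csv(f)
  expect_named(df, c("time_days", "dose", "doseX", "t_mem", "t_eff1",
                     "t_eff2", "t_exh", "tumor_cells", "antigen",
                     "cart_cells_per_ul", "tumor_cells_per_ul",
                     "tumor_pct_change"))
  expect_equal(df$t_mem, tr$t_m)
})
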