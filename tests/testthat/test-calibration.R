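# A tiny noise-free study used across calibration tests.
noise_free_study <- function(seed = 7)
  gen_pk_study(group_params = "CR", noise_cv = 0, seed = seed)

test_that("objective is zero on self-consistent data and counts decades", {
  study <- noise_free_study()
  prof <- study$profiles$CR
  expect_equal(log_mse_objective(study$truth$CR, prof), 0)
  # one series off by exactly one decade everywhere: per-series MSE 1,
  # equally weighted with the matching tumor series -> 0.5
  shifted <- prof
  shifted$cart$mean <- prof$cart$mean * 10
  sim_at <- cartqsp:::.simulate_at_profile(study$truth$CR, prof)
  expect_true(all(sim_at$cart > 1e6))  # decade shift fully above the LLQ
  expect_equal(log_mse_objective(study$truth$CR, shifted), 0.5)
})

test_that("points below the quantification limit contribute nothing", {
  study <- noise_free_study()
  prof <- study$profiles$CR
  # perturb only observations that sit below the LLQ
  sim_at <- cartqsp:::.simulate_at_profile(study$truth$CR, prof)
  low <- sim_at$tumor < 1e6
  expect_true(any(low))
  prof$tumor$mean[low] <- pmin(prof$tumor$mean[low] * 3, 9e5)
  expect_equal(log_mse_objective(study$truth$CR, prof), 0)
})

test_that("swarm locates the optimum of a sphere and respects the box", {
  viol <- 0
  obj <- function(x) {
    if (any(x < -2) || any(x > 5)) viol <<- viol + 1
    sum((x - 1)^2)
  }
  res <- pso_optimize(obj, lower = rep(-2, 3), upper = rep(5, 3),
                      particles = 30, iterations = 60, seed = 3)
  expect_equal(viol, 0)
  expect_lt(sqrt(sum((res$par - 1)^2)), 1e-3)
  expect_true(all(diff(res$trace) <= 0))
  res2 <- pso_optimize(obj, lower = rep(-2, 3), upper = rep(5, 3),
                       particles = 30, iterations = 60, seed = 3)
  expect_identical(res$par, res2$par)
})

test_that("repeat fits on a flat ridge find distinct, equally good optima", {
  # x1 * x2 = 4 is a non-identifiable ridge
  obj <- function(x) (x[1] * x[2] - 4)^2
  fits <- lapply(1:4, function(s)
    pso_optimize(obj, lower = c(0.5, 0.5), upper = c(8, 8),
                 particles = 25, iterations = 40, seed = s))
  vals <- vapply(fits, `[[`, 0, "value")
  pars <- t(vapply(fits, `[[`, numeric(2), "par"))
  expect_true(all(vals < 1e-6))
  expect_gt(max(dist(pars)), 0.1)
})

test_that("fitted parameters stay inside the calibration box", {
  study <- noise_free_study()
  fit <- pso_fit(study$profiles$CR, particles = 10, iterations = 10,
                 seed = 2)
  b <- param_bounds()
  expect_true(all(fit$parameters >= b$lower & fit$parameters <= b$upper))
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("ensembles have the configured shape and reproduce bit-exactly", {
  study <- gen_pk_study(group_params = c("CR", "NR"), noise_cv = 0.1,
                        seed = 3)
  ens1 <- fit_ensemble(study$profiles, n_repeats = 3, particles = 8,
                       iterations = 6, seed = 99)
  ens2 <- fit_ensemble(study$profiles, n_repeats = 3, particles = 8,
                       iterations = 6, seed = 99)
  expect_named(ens1, c("CR", "NR"))
  expect_length(ens1$CR, 3)
  expect_identical(ensemble_param_matrix(ens1),
                   ensemble_param_matrix(ens2))
  f <- withr::local_tempfile(fileext = ".json")
  ensemble_to_json(ens1, f)
  ens3 <- ensemble_from_json(f)
  expect_equal(ensemble_param_matrix(ens3), ensemble_param_matrix(ens1),
               tolerance = 1e-12)
  expect_equal(attr(ens3, "master_seed"), 99)
})

test_that("goodness of fit recovers perfect, reversed and attenuated correlation", {
  study <- noise_free_study()
  prof <- study$profiles$CR
  gof <- goodness_of_fit(study$truth$CR, prof)
  expect_equal(gof$r, c(1, 1), tolerance = 1e-9)
  # reversed ordering: observations anti-linear in the simulation
  sim_at <- cartqsp:::.simulate_at_profile(study$truth$CR, prof)
  rev_prof <- prof
  rev_prof$cart$mean <- max(sim_at$cart) - sim_at$cart
  expect_equal(goodness_of_fit(study$truth$CR,
                               rev_prof)$r[1], -1, tolerance = 1e-9)
  short <- prof
  short$cart <- short$cart[1:3, ]
  short$cart$mean[1] <- NA
  expect_error(goodness_of_fit(study$truth$CR, short), "3 paired points")
})

test_that("profile CSVs and parameter JSON round-trip with unit handling", {
  study <- gen_pk_study(group_params = c("CR", "NR"), noise_cv = 0.1,
                        seed = 2)
  rows <- do.call(rbind, lapply(names(study$profiles), function(g) {
    pr <- study$profiles[[g]]
    rbind(data.frame(group = g, series = "cart", pr$cart,
                     units = "cells"),
          data.frame(group = g, series = "tumor", pr$tumor,
                     units = "cells"))
  }))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  meta <- lapply(study$profiles, function(pr)
    list(dose_cells = pr$dose_cells, b0_cells = pr$b0_cells))
  back <- read_profiles_csv(f, meta)
  expect_equal(back$CR$cart$mean, study$profiles$CR$cart$mean)
  expect_equal(back$NR$b0_cells, study$profiles$NR$b0_cells)
  # concentration units scale back to total cells
  rows2 <- rows
  rows2$mean <- rows2$mean / 2e6
  rows2$sd <- rows2$sd / 2e6
  rows2$units <- "cells_per_ul"
  write.csv(rows2, f, row.names = FALSE)
  back2 <- read_profiles_csv(f, meta)
  expect_equal(back2$CR$cart$mean, study$profiles$CR$cart$mean,
               tolerance = 1e-12)
  expect_error(read_profiles_csv(f, meta["CR"]), "metadata missing")
  fj <- withr::local_tempfile(fileext = ".json")
  write_params_json(archetype_params("PR"), fj)
  expect_equal(read_params_json(fj), archetype_params("PR"),
               tolerance = 1e-12)
})

test_that("correlation under known noise sits in the resampling oracle band", {
  study <- noise_free_study()
  prof <- study$profiles$CR
  sim_at <- cartqsp:::.simulate_at_profile(study$truth$CR, prof)
  s <- log10(sim_at$cart)
  cv <- 0.3
  sdlog10 <- sqrt(log(1 + cv^2)) / log(10)
  # brute-force resampling oracle for the attenuation band of Pearson r
  set.seed(11)
  r_oracle <- replicate(400, cor(s, s + rnorm(length(s), 0, sdlog10)))
  band <- quantile(r_oracle, c(0.005, 0.995))
  set.seed(99)
  r_obs <- mean(replicate(50, cor(s, s + rnorm(length(s), 0, sdlog10))))
  expect_gt(r_obs, band[1])
  expect_lt(r_obs, band[2])
})
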