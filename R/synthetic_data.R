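#' Generate a synthetic grouped pharmacokinetic/tumor study
#'
#' Simulates the toggle-switch model per group at known ("ground truth")
#' parameters, samples the trajectories at the observation times, and
#' applies multiplicative lognormal noise to the means with the given
#' coefficient of variation. The attached sd is \code{cv * mean}. Ground
#' truth is stored so calibration-recovery tests can compare fitted
#' trajectories to the generating ones.
#'
#' @param group_params Named list: group label -> \code{cart_params} (or a
#'   character vector of archetype names, see
#'   \code{\link{archetype_params}}).
#' @param dose_cells,b0_cells Study conditions (cells); scalar or per-group.
#' @param obs_times Observation times (days).
#' @param noise_cv Lognormal coefficient of variation (0 = noise-free).
#' @param seed Integer seed.
#' @param grid_dt Simulation grid (days).
#' @return List of class \code{synthetic_pk_study}: \code{profiles} (named
#'   list of \code{\link{observed_profile}}), \code{truth} (named list of
#'   parameter vectors), \code{config}.
#' @export
gen_pk_study <- function(group_params = list(CR = archetype_params("CR"),
                                             NR = archetype_params("NR")),
                         dose_cells = 1e8, b0_cells = 1e10,
                         obs_times = c(3, 7, 10, 14, 21, 28, 42, 60, 90),
                         noise_cv = 0.1, seed = 1, grid_dt = 0.1) {
  if (is.character(group_params))
    group_params <- setNames(lapply(group_params, archetype_params),
                             group_params)
  stopifnot(length(group_params) >= 1, noise_cv >= 0,
            all(obs_times > 0))
  ngrp <- length(group_params)
  dose_cells <- rep(dose_cells, length.out = ngrp)
  b0_cells <- rep(b0_cells, length.out = ngrp)
  sdlog <- sqrt(log(1 + noise_cv^2))
  set.seed(seed)
  profiles <- list()
  for (gi in seq_len(ngrp)) {
    g <- names(group_params)[gi]
    p <- cart_params(group_params[[g]])
    cfg <- sim_config(dose_cells = dose_cells[gi], b0 = b0_cells[gi],
                      t_end = max(obs_times), grid_dt = grid_dt)
    traj <- simulate_cart(p, cfg)
    at <- function(col) approx(traj$time_days, traj[[col]],
                               xout = obs_times, rule = 2)$y
    noisy <- function(mu) {
      if (noise_cv == 0) return(mu)
      mu * rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    cart_mu <- at("cart_cells"); tum_mu <- at("b")
    profiles[[g]] <- observed_profile(
      group_label = g,
      cart = data.frame(time_days = obs_times, mean = noisy(cart_mu),
                        sd = noise_cv * cart_mu),
      tumor = data.frame(time_days = obs_times, mean = noisy(tum_mu),
                         sd = noise_cv * tum_mu),
      dose_cells = dose_cells[gi], b0_cells = b0_cells[gi])
  }
  structure(list(profiles = profiles, truth = group_params,
                 config = list(dose_cells = dose_cells,
                               b0_cells = b0_cells,
                               obs_times = obs_times,
                               noise_cv = noise_cv, seed = seed,
                               grid_dt = grid_dt)),
            class = "synthetic_pk_study")
}

# Gamma-mixed Poisson (negative-binomial-like) counts around mean mu with
# dispersion phi (var = mu + phi mu^2).
.nb_counts <- function(n, mu, phi) {
  if (phi <= 0) return(rpois(n, mu))
  rpois(n, rgamma(n, shape = 1 / phi, scale = mu * phi))
}

#' Generate a synthetic expression cohort with informative gene signatures
#'
#' Overdispersed (gamma-Poisson) count matrix for two response groups, plus
#' a gene-set compendium of \code{n_sets} sets of which
#' \code{n_informative} are shifted: genes of informative sets have their
#' log-scale mean raised by \code{effect_size} within-group standard
#' deviations in the responder group. The remaining sets are drawn from the
#' same gene universe but unshifted.
#'
#' @param n_per_group Samples per group (responders, non-responders).
#' @param n_genes Gene universe size.
#' @param n_sets Compendium size S.
#' @param n_informative Informative set count s (<= S).
#' @param set_size Genes per set (scalar or range c(lo, hi)).
#' @param effect_size Shift in units of within-group sd of log expression.
#' @param dispersion Gamma-Poisson dispersion phi.
#' @param base_log_mean,base_log_sd Distribution of baseline gene log-means.
#' @param seed Integer seed.
#' @return List of class \code{synthetic_expression_cohort}:
#'   \code{counts} (genes x samples), \code{labels} (logical, TRUE =
#'   responder), \code{sets} (named list), \code{informative_sets}
#'   (names), \code{config}.
#' @export
gen_expression_cohort <- function(n_per_group = c(10, 10), n_genes = 2000,
                                  n_sets = 50, n_informative = 5,
                                  set_size = c(15, 40), effect_size = 1.5,
                                  dispersion = 0.2, base_log_mean = 4,
                                  base_log_sd = 1, seed = 1) {
  stopifnot(n_informative <= n_sets, effect_size >= 0, all(n_per_group >= 1))
  n_per_group <- rep(n_per_group, length.out = 2)
  if (is.null(names(n_per_group))) names(n_per_group) <- c("R", "NR")
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  sizes <- if (length(set_size) == 2)
    sample(set_size[1]:set_size[2], n_sets, replace = TRUE)
  else rep(set_size, n_sets)
  if (max(sizes) > n_genes) stop("gene universe too small for set sizes")
  # informative sets are disjoint so the signal is attributable
  n_inf_genes <- sum(sizes[seq_len(n_informative)])
  if (n_inf_genes > n_genes)
    stop("gene universe too small for informative sets")
  pool <- sample(genes)
  sets <- vector("list", n_sets)
  used <- 0
  for (i in seq_len(n_sets)) {
    if (i <= n_informative) {
      sets[[i]] <- pool[(used + 1):(used + sizes[i])]
      used <- used + sizes[i]
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  names(sets) <- c(sprintf("informative_set_%02d",
                           seq_len(n_informative)),
                   sprintf("background_set_%02d",
                           seq_len(n_sets - n_informative)))
  inf_genes <- unique(unlist(sets[seq_len(n_informative)]))
  base_mu <- setNames(exp(rnorm(n_genes, base_log_mean, base_log_sd)),
                      genes)
  # within-group sd of log expression under the gamma-Poisson model
  sigma_w <- sqrt(log(1 + dispersion + 1 / base_mu))
  shift <- ifelse(genes %in% inf_genes,
                  exp(effect_size * sigma_w), 1)
  n_tot <- sum(n_per_group)
  labels <- rep(c(TRUE, FALSE), times = n_per_group)
  counts <- matrix(0L, n_genes, n_tot,
                   dimnames = list(genes,
                                   paste0("sample_", seq_len(n_tot))))
  for (j in seq_len(n_tot)) {
    mu <- if (labels[j]) base_mu * shift else base_mu
    counts[, j] <- .nb_counts(n_genes, mu, dispersion)
  }
  structure(list(counts = counts, labels = labels, sets = sets,
                 informative_sets = names(sets)[seq_len(n_informative)],
                 config = list(n_per_group = n_per_group,
                               n_genes = n_genes, n_sets = n_sets,
                               n_informative = n_informative,
                               effect_size = effect_size,
                               dispersion = dispersion, seed = seed)),
            class = "synthetic_expression_cohort")
}

#' Generate a synthetic single-cell cohort with phenotype frequencies
#'
#' Cells allocated to samples in two response groups; each cell is a
#' "memory", "effector" or "exhausted" phenotype drawn from per-sample
#' frequencies whose logit-scale means differ between groups by
#' \code{separation} (responders: more memory, fewer exhausted). Per-cell
#' counts are Poisson draws from phenotype-specific gene profiles, enabling
#' pseudobulk consistency and bivariate frequency-classifier tests.
#'
#' @param n_per_group Samples per group.
#' @param cells_per_sample Cells per sample.
#' @param n_genes Genes.
#' @param separation Logit-scale group separation of memory/exhausted
#'   frequencies (0 = no group difference).
#' @param freq_sd Logit-scale between-sample sd of frequencies.
#' @param seed Integer seed.
#' @return List of class \code{synthetic_cell_cohort}: \code{cell_counts}
#'   (cells x genes), \code{cell_samples}, \code{sample_labels} (named
#'   logical), \code{frequencies} (samples x phenotypes), \code{config}.
#' @export
gen_cell_cohort <- function(n_per_group = c(8, 8), cells_per_sample = 200,
                            n_genes = 300, separation = 1.5,
                            freq_sd = 0.5, seed = 1) {
  stopifnot(cells_per_sample >= 1, all(n_per_group >= 1))
  n_per_group <- rep(n_per_group, length.out = 2)
  set.seed(seed)
  n_samp <- sum(n_per_group)
  samples <- sprintf("sample_%02d", seq_len(n_samp))
  labels <- setNames(rep(c(TRUE, FALSE), times = n_per_group), samples)
  # phenotype frequencies via softmax of logit-normal draws
  base_logit <- c(memory = 0, effector = 0.5, exhausted = 0)
  freq <- t(vapply(seq_len(n_samp), function(i) {
    lg <- base_logit + rnorm(3, 0, freq_sd)
    if (labels[i]) {
      lg["memory"] <- lg["memory"] + separation / 2
      lg["exhausted"] <- lg["exhausted"] - separation / 2
    } else {
      lg["memory"] <- lg["memory"] - separation / 2
      lg["exhausted"] <- lg["exhausted"] + separation / 2
    }
    e <- exp(lg); e / sum(e)
  }, numeric(3)))
  rownames(freq) <- samples
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  # phenotype-specific expression: a dedicated gene block per phenotype
  block <- split(seq_len(n_genes),
                 cut(seq_len(n_genes), 3, labels = FALSE))
  prof <- sapply(1:3, function(k) {
    mu <- rep(2, n_genes)
    mu[block[[k]]] <- 10
    mu
  })
  colnames(prof) <- colnames(freq) <- c("memory", "effector", "exhausted")
  n_cells <- n_samp * cells_per_sample
  cell_samples <- rep(samples, each = cells_per_sample)
  pheno <- character(n_cells)
  counts <- matrix(0L, n_cells, n_genes,
                   dimnames = list(sprintf("cell_%05d", seq_len(n_cells)),
                                   genes))
  for (i in seq_len(n_samp)) {
    rows <- which(cell_samples == samples[i])
    ph <- sample(colnames(freq), length(rows), replace = TRUE,
                 prob = freq[i, ])
    pheno[rows] <- ph
    for (r in seq_along(rows))
      counts[rows[r], ] <- rpois(n_genes, prof[, ph[r]])
  }
  obs_freq <- t(vapply(samples, function(s) {
    tab <- table(factor(pheno[cell_samples == s],
                        levels = colnames(freq)))
    as.numeric(tab) / sum(tab)
  }, numeric(3)))
  colnames(obs_freq) <- colnames(freq)
  structure(list(cell_counts = counts, cell_samples = cell_samples,
                 cell_phenotypes = pheno, sample_labels = labels,
                 frequencies = obs_freq,
                 config = list(n_per_group = n_per_group,
                               cells_per_sample = cells_per_sample,
                               n_genes = n_genes,
                               separation = separation,
                               freq_sd = freq_sd, seed = seed)),
            class = "synthetic_cell_cohort")
}
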