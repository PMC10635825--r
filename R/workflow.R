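#' Run a named analysis workflow from a configuration
#'
#' Chains the package's stages into the three study workflows, writing all
#' tables under \code{out_dir} and returning a manifest with checksums.
#' Workflows:
#' \describe{
#'   \item{\code{simulate}}{Simulate archetype (or supplied) parameter sets;
#'     writes trajectory CSVs and a day-60 composition table.}
#'   \item{\code{pk}}{Synthetic grouped profiles -> particle swarm ensemble
#'     -> goodness of fit -> virtual population -> response covariates ->
#'     local sensitivity -> parameter PCA.}
#'   \item{\code{expression}}{Synthetic expression cohort -> ssGSEA ->
#'     min-max normalization -> differential ranking + preranked GSEA
#'     scorecard -> cross-validated classifiers (GA / random-pathway /
#'     null) with rank-sum comparisons and inclusion frequencies.}
#' }
#' All randomness derives from \code{config$seed}; re-running with the same
#' config reproduces every table bit-exactly.
#'
#' @param config Named list or path to a YAML file. Required keys:
#'   \code{workflow} (one of the names above), \code{out_dir}, \code{seed}.
#'   Optional per-stage blocks override defaults (see the methods
#'   vignette).
#' @return Manifest list: \code{workflow}, \code{seed}, \code{outputs}
#'   (named paths), \code{checksums}, \code{summary} (key numbers).
#' @export
run_workflow <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  need <- setdiff(c("workflow", "out_dir", "seed"), names(config))
  if (length(need))
    stop("config missing keys: ", paste(need, collapse = ", "))
  valid <- c("simulate", "pk", "expression")
  if (!config$workflow %in% valid)
    stop("unknown workflow '", config$workflow, "'; valid: ",
         paste(valid, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$workflow,
                simulate = .wf_simulate(config),
                pk = .wf_pk(config),
                expression = .wf_expression(config))
  files <- unlist(res$outputs)
  manifest <- list(workflow = config$workflow, seed = config$seed,
                   outputs = res$outputs,
                   checksums = as.list(tools::md5sum(files)),
                   summary = res$summary)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest$outputs$manifest <- mp
  manifest
}

.cfg <- function(config, key, default) {
  if (!is.null(config[[key]])) utils::modifyList(default, config[[key]])
  else default
}

.wf_simulate <- function(config) {
  cc <- .cfg(config, "simulate",
             list(groups = c("CR", "NR"), dose_cells = 1e8, b0 = 1e10,
                  t_end = 90, composition_day = 60))
  outs <- list(); comp <- list()
  for (g in cc$groups) {
    traj <- simulate_cart(archetype_params(g),
                          sim_config(dose_cells = cc$dose_cells,
                                     b0 = cc$b0, t_end = cc$t_end))
    f <- file.path(config$out_dir,
                   paste0("trajectory_", g, ".csv"))
    write_trajectory_csv(traj, f)
    outs[[paste0("trajectory_", g)]] <- f
    cs <- state_composition(traj, min(cc$composition_day, cc$t_end))
    comp[[g]] <- data.frame(group = g,
                            percent_non_exhausted =
                              cs$percent_non_exhausted)
  }
  ctab <- do.call(rbind, comp)
  f <- file.path(config$out_dir, "composition.csv")
  write.csv(ctab, f, row.names = FALSE)
  outs$composition <- f
  list(outputs = outs,
       summary = setNames(as.list(ctab$percent_non_exhausted),
                          paste0("percent_non_exhausted_", ctab$group)))
}

.wf_pk <- function(config) {
  gen <- .cfg(config, "generator",
              list(groups = c("CR", "NR"), noise_cv = 0.1,
                   dose_cells = 1e8, b0_cells = 1e10))
  fit <- .cfg(config, "fit",
              list(n_repeats = 3, particles = 20, iterations = 25))
  vp <- .cfg(config, "vpop",
             list(n = 200, horizon = 365, mode = "dose_and_b0"))
  study <- gen_pk_study(group_params = gen$groups,
                        dose_cells = gen$dose_cells,
                        b0_cells = gen$b0_cells,
                        noise_cv = gen$noise_cv, seed = config$seed)
  ens <- fit_ensemble(study$profiles, n_repeats = fit$n_repeats,
                      particles = fit$particles,
                      iterations = fit$iterations, seed = config$seed)
  outs <- list()
  f_ens <- file.path(config$out_dir, "ensemble.json")
  ensemble_to_json(ens, f_ens); outs$ensemble <- f_ens
  gof <- do.call(rbind, lapply(names(ens), function(g) {
    best <- ens[[g]][[which.min(vapply(ens[[g]], `[[`, 0, "objective"))]]
    goodness_of_fit(best, study$profiles[[g]])
  }))
  f_gof <- file.path(config$out_dir, "goodness_of_fit.tsv")
  write.table(gof, f_gof, sep = "\t", row.names = FALSE, quote = FALSE)
  outs$goodness_of_fit <- f_gof
  cohort <- build_virtual_population(ens, mode = vp$mode, n = vp$n,
                                     seed = config$seed,
                                     horizon = vp$horizon)
  f_coh <- file.path(config$out_dir, "virtual_cohort.tsv")
  write.table(as.data.frame(cohort), f_coh, sep = "\t",
              row.names = FALSE, quote = FALSE)
  outs$virtual_cohort <- f_coh
  summary <- list(median_dose = median(cohort$dose),
                  responder_fraction = mean(cohort$responder))
  cov <- tryCatch(response_covariate_analysis(cohort),
                  error = function(e) NULL)
  if (!is.null(cov)) {
    f_cov <- file.path(config$out_dir, "response_covariates.tsv")
    write.table(cov, f_cov, sep = "\t", row.names = FALSE, quote = FALSE)
    outs$response_covariates <- f_cov
    summary$cmax_over_b0_slope <-
      cov$slope[cov$covariate == "log10_cmax_over_b0"]
  }
  sens <- local_sensitivity(ens, sim_config(t_end = vp$horizon))
  f_sens <- file.path(config$out_dir, "sensitivity.tsv")
  write.table(sens, f_sens, sep = "\t", row.names = FALSE, quote = FALSE)
  outs$sensitivity <- f_sens
  if (nrow(ensemble_param_matrix(ens)) >= 3) {
    pca <- parameter_pca(ens)
    f_pca <- file.path(config$out_dir, "parameter_pca.tsv")
    write.table(data.frame(pc = seq_along(pca$percent_variance),
                           percent_variance = pca$percent_variance),
                f_pca, sep = "\t", row.names = FALSE, quote = FALSE)
    outs$parameter_pca <- f_pca
    summary$pc1_percent_variance <- pca$percent_variance[1]
  }
  summary$best_objectives <- lapply(ens, function(g)
    min(vapply(g, `[[`, 0, "objective")))
  list(outputs = outs, summary = summary)
}

.wf_expression <- function(config) {
  gen <- .cfg(config, "generator",
              list(n_per_group = c(10, 10), n_sets = 40,
                   n_informative = 5, effect_size = 1.5))
  cv <- .cfg(config, "classifier",
             list(n_iter = 100, fdr_cutoff = 0.05))
  cohort <- gen_expression_cohort(n_per_group = gen$n_per_group,
                                  n_sets = gen$n_sets,
                                  n_informative = gen$n_informative,
                                  effect_size = gen$effect_size,
                                  seed = config$seed)
  scores <- ssgsea(log2(cohort$counts + 1), cohort$sets)
  nrm <- normalize_scores(scores)
  outs <- list()
  f_scores <- file.path(config$out_dir, "ssgsea_normalized.tsv")
  write.table(nrm, f_scores, sep = "\t", quote = FALSE)
  outs$ssgsea_normalized <- f_scores
  rk <- differential_stat(cohort$counts, cohort$labels)
  ranked <- setNames(rk$statistic, rk$gene)
  gsea <- lapply(cohort$sets, function(s)
    preranked_gsea(ranked, s, n_perm = 500, seed = config$seed))
  card <- scorecard(list(synthetic = gsea))
  card$signature <- rownames(card)
  f_card <- file.path(config$out_dir, "scorecard.tsv")
  write.table(card[, c("signature", "synthetic")], f_card, sep = "\t",
              row.names = FALSE, quote = FALSE)
  outs$scorecard <- f_card
  tab <- feature_table(t(nrm), cohort$labels)
  sig_p <- vapply(gsea, `[[`, 0, "p_value")
  candidates <- names(sig_p)[p.adjust(sig_p, "BH") < cv$fdr_cutoff]
  if (length(candidates) < 2) candidates <- cohort$informative_sets
  null_pool <- setdiff(names(cohort$sets), candidates)
  acc_ga <- cv_accuracy(tab, "ga_transcriptome", candidates = candidates,
                        n_iter = cv$n_iter, seed = config$seed,
                        ga_args = list(pop_size = 30, generations = 10))
  acc_rp <- cv_accuracy(tab, "random_pathway", null_pool = null_pool,
                        n_iter = cv$n_iter, seed = config$seed)
  acc_null <- cv_accuracy(tab, "null", n_iter = cv$n_iter,
                          seed = config$seed)
  dist_tab <- data.frame(iteration = seq_len(cv$n_iter),
                         ga_transcriptome = acc_ga$accuracy,
                         random_pathway = acc_rp$accuracy,
                         null = acc_null$accuracy)
  f_acc <- file.path(config$out_dir, "accuracy_distributions.tsv")
  write.table(dist_tab, f_acc, sep = "\t", row.names = FALSE,
              quote = FALSE)
  outs$accuracy_distributions <- f_acc
  incl <- inclusion_frequency(acc_ga, features = names(cohort$sets))
  f_incl <- file.path(config$out_dir, "inclusion_frequency.tsv")
  write.table(data.frame(signature = names(incl), frequency = incl),
              f_incl, sep = "\t", row.names = FALSE, quote = FALSE)
  outs$inclusion_frequency <- f_incl
  list(outputs = outs,
       summary = list(
         median_accuracy_ga = median(acc_ga$accuracy),
         median_accuracy_random_pathway = median(acc_rp$accuracy),
         median_accuracy_null = median(acc_null$accuracy),
         p_ga_vs_null = compare_accuracy(acc_ga, acc_null),
         n_candidates = length(candidates)))
}

#' Summarize a workflow manifest
#'
#' Human-readable recap of a \code{\link{run_workflow}} manifest: the
#' workflow, seed, produced artifacts (flagging any missing files) and the
#' key summary numbers.
#'
#' @param manifest Manifest list (or path to a manifest.json).
#' @return The summary text, invisibly; printed as a side effect.
#' @export
report_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  lines <- c(sprintf("Workflow: %s (seed %s)",
                     manifest$workflow %||% "<none>",
                     manifest$seed %||% "<none>"))
  outs <- manifest$outputs
  if (length(outs)) {
    for (nm in names(outs)) {
      ok <- file.exists(outs[[nm]])
      lines <- c(lines, sprintf("  artifact %-24s %s%s", nm, outs[[nm]],
                                if (ok) "" else "  [MISSING]"))
    }
  }
  s <- manifest$summary
  if (length(s)) {
    lines <- c(lines, "Summary:")
    flat <- unlist(s)
    lines <- c(lines, sprintf("  %-32s %s", names(flat),
                              vapply(flat, format, "")))
  }
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
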