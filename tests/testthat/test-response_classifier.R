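test_that("logistic fits reproduce closed-form intercept-only and 2x2 cases", {
  # intercept-only, balanced n = 10: AIC = 2 - 2 * 10 * ln(0.5)
  tab <- feature_table(data.frame(f1 = rnorm(10)),
                       rep(c(TRUE, FALSE), 5))
  m0 <- fit_logistic(tab, features = character(0))
  expect_equal(m0$aic, 2 - 2 * 10 * log(0.5), tolerance = 1e-6)
  # single binary feature, response rates 8/10 vs 2/10: slope = log OR
  x <- rep(c(1, 0), each = 10)
  y <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  m1 <- fit_logistic(feature_table(data.frame(f1 = x), y), "f1")
  expect_equal(unname(m1$coefficients["f1"]), log(16), tolerance = 1e-4)
  # perfectly separable feature
  m2 <- fit_logistic(feature_table(data.frame(f1 = c(1:5, 11:15)),
                                   rep(c(FALSE, TRUE), each = 5)), "f1")
  expect_equal(m2$train_accuracy, 1)
  expect_true(m2$separation)
  # collinear design is refused with the offending features named
  tabc <- feature_table(data.frame(f1 = 1:10, f2 = 2 * (1:10)),
                        rep(c(TRUE, FALSE), 5))
  expect_error(fit_logistic(tabc, c("f1", "f2")), "collinear")
})

test_that("accuracy formula is exact on enumerated confusion matrices", {
  for (tp in 0:3) for (tn in 0:3) for (fp in 0:3) for (fn in 0:3) {
    if (tp + tn + fp + fn == 0) next
    expect_equal(confusion_accuracy(tp, tn, fp, fn),
                 (tp + tn) / (tp + tn + fp + fn))
  }
  expect_error(confusion_accuracy(0, 0, 0, 0), "empty")
  expect_error(confusion_accuracy(-1, 1, 1, 1), "non-negative")
})

test_that("genetic selection equals exhaustive AIC enumeration on 4 features", {
  tab <- gaussian_feature_table(n_per_class = 15, n_features = 4,
                                n_informative = 2, delta = 1.5, seed = 3)
  feats <- setdiff(names(tab), "label")
  subsets <- unlist(lapply(0:4, function(k)
    combn(feats, k, simplify = FALSE)), recursive = FALSE)
  brute <- t(vapply(subsets, function(s) {
    m <- fit_logistic(tab, s)
    c(aic = m$aic, acc = m$train_accuracy)
  }, numeric(2)))
  best_idx <- order(brute[, "aic"], -brute[, "acc"])[1]
  for (s in 1:3) {
    ga <- ga_select(tab, feats, pop_size = 40, generations = 15,
                    seed = s)
    expect_setequal(ga$features, subsets[[best_idx]])
    expect_equal(ga$aic, unname(brute[best_idx, "aic"]),
                 tolerance = 1e-9)
  }
})

test_that("a perfectly separating feature is almost always selected", {
  set.seed(6)
  n <- 30
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  X <- data.frame(sep = ifelse(lab, 1, 0) + rnorm(n, 0, 0.01),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  tab <- feature_table(X, lab)
  hits <- vapply(1:100, function(s)
    "sep" %in% ga_select(tab, pop_size = 20, generations = 8,
                         seed = s)$features, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("degenerate single-candidate pools resolve by AIC", {
  tab <- gaussian_feature_table(n_per_class = 15, n_features = 2,
                                n_informative = 1, delta = 3, seed = 2)
  ga_inf <- ga_select(tab, "f1", pop_size = 10, generations = 5, seed = 1)
  expect_equal(ga_inf$features, "f1")  # informative beats intercept-only
  ga_noise <- ga_select(tab, "f2", pop_size = 10, generations = 5,
                        seed = 1)
  aic_empty <- fit_logistic(tab, character(0))$aic
  aic_f2 <- fit_logistic(tab, "f2")$aic
  expect_equal(ga_noise$aic, min(aic_empty, aic_f2))
  expect_error(ga_select(tab, character(0)), "empty candidate")
})

test_that("cross-validated accuracy separates informative, null and seeded reruns", {
  tab <- gaussian_feature_table(n_per_class = 20, n_features = 6,
                                n_informative = 2, delta = 2, seed = 10)
  acc_ga <- cv_accuracy(tab, "ga_transcriptome", n_iter = 60, seed = 3,
                        ga_args = list(pop_size = 20, generations = 6))
  expect_gt(median(acc_ga$accuracy), 0.9)
  acc_null <- cv_accuracy(tab, "null", n_iter = 500, seed = 3)
  expect_lt(abs(median(acc_null$accuracy) - 0.5), 0.05)
  acc_null2 <- cv_accuracy(tab, "null", n_iter = 500, seed = 3)
  expect_identical(acc_null$accuracy, acc_null2$accuracy)
  expect_error(
    cv_accuracy(feature_table(data.frame(f = rnorm(4)),
                              c(TRUE, FALSE, FALSE, FALSE)),
                "null"), "stratif")
})

test_that("bivariate mode uses exactly two fixed features", {
  tab <- gaussian_feature_table(n_per_class = 12, n_features = 4,
                                n_informative = 2, delta = 2, seed = 8)
  acc <- cv_accuracy(tab, "fixed_bivariate", candidates = c("f1", "f2"),
                     n_iter = 30, seed = 1)
  expect_true(all(vapply(acc$selected, identical, TRUE, c("f1", "f2"))))
  expect_error(cv_accuracy(tab, "fixed_bivariate",
                           candidates = c("f1", "f2", "f3"), n_iter = 5),
               "exactly 2")
})

test_that("rank-sum comparisons separate distributions as constructed", {
  a <- list(accuracy = rep(0.8, 50))
  class(a) <- "accuracy_distribution"
  expect_equal(compare_accuracy(a, a), 1)
  set.seed(2)
  hi <- runif(100, 0.8, 1); lo <- runif(100, 0, 0.2)
  expect_lt(compare_accuracy(hi, lo), 1e-6)
  tab <- gaussian_feature_table(n_per_class = 20, n_features = 6,
                                n_informative = 2, delta = 2, seed = 10)
  acc_inf <- cv_accuracy(tab, "fixed_bivariate",
                         candidates = c("f1", "f2"), n_iter = 150,
                         seed = 4)
  acc_null <- cv_accuracy(tab, "null", n_iter = 150, seed = 4)
  expect_lt(compare_accuracy(acc_inf, acc_null), 1e-6)
})

test_that("inclusion frequencies equal brute-force recounts", {
  runs <- list(c("a", "b"), c("a"), c("a", "c"), character(0))
  freq <- inclusion_frequency(runs, features = c("a", "b", "c", "d"))
  expect_equal(freq, c(a = 0.75, b = 0.25, c = 0.25, d = 0))
  set.seed(1)
  rand_runs <- lapply(1:50, function(i)
    sample(letters[1:6], sample(0:4, 1)))
  freq2 <- inclusion_frequency(rand_runs, features = letters[1:6])
  brute <- sapply(letters[1:6], function(f)
    sum(sapply(rand_runs, function(r) f %in% r)) / 50)
  expect_equal(freq2, brute)
})

test_that("random-pathway sizes follow the supplied distribution", {
  sizes <- random_pathway_sizes(10000,
                                c(`2` = 0.1, `3` = 0.4, `4` = 0.3,
                                  `5` = 0.15, `6` = 0.05), seed = 9)
  expect_true(all(sizes >= 2 & sizes <= 6))
  obs <- table(factor(sizes, levels = 2:6))
  p <- chisq.test(obs, p = c(0.1, 0.4, 0.3, 0.15, 0.05))$p.value
  expect_gt(p, 0.01)
  expect_identical(random_pathway_sizes(100, seed = 5),
                   random_pathway_sizes(100, seed = 5))
  expect_error(random_pathway_sizes(10, c(`1` = 0.5, `3` = 0.5)),
               "\\[2, 6\\]")
})
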