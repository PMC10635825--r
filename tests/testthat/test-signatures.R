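test_that("GMT files round-trip and reject malformed collections", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f, descriptions = c(alpha = "first", beta = "second"))
  back <- read_gmt(f)
  expect_equal(back[], sets, ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions")[["alpha"]], "first")
  writeLines(c("a\td\tg1", "a\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate")
  writeLines("a\td\t", f)
  expect_error(read_gmt(f), "empty")
})

test_that("ssGSEA ranks a genuinely top-loaded set above random sets", {
  set.seed(31)
  ng <- 400
  expr <- matrix(rexp(ng * 3), ng, 3,
                 dimnames = list(paste0("g", 1:ng), paste0("s", 1:3)))
  top <- rownames(expr)[order(expr[, 1], decreasing = TRUE)][1:20]
  rand_sets <- lapply(1:200, function(i)
    sample(rownames(expr), 20))
  names(rand_sets) <- paste0("rand", 1:200)
  sc <- ssgsea(expr, c(list(top = top), rand_sets))
  expect_gt(mean(sc["top", 1] > sc[-1, 1]), 0.95)
})

test_that("ssGSEA depends only on within-sample ranks", {
  set.seed(5)
  expr <- matrix(rlnorm(200 * 4), 200, 4,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  expr[, 2] <- expr[, 1]  # identical rankings
  sets <- list(a = paste0("g", 1:15), b = paste0("g", 50:80))
  sc <- ssgsea(expr, sets)
  expect_equal(sc[, 1], sc[, 2], ignore_attr = TRUE)
  # strictly increasing transform of one sample
  expr2 <- expr
  expr2[, 3] <- exp(expr2[, 3] / max(expr2[, 3]) * 5)
  expect_equal(ssgsea(expr2, sets)[, 3], sc[, 3])
  # gene-order permutation of the matrix
  perm <- sample(nrow(expr))
  expect_equal(ssgsea(expr[perm, ], sets), sc)
  expect_warning(sc2 <- ssgsea(expr, list(missing = c("zz1", "zz2"))),
                 "insufficient overlap")
  expect_true(all(is.na(sc2)))
})

test_that("min-max normalization matches the formula and its invariances", {
  A <- matrix(c(0, 5, 10, 2.5), 2, 2)
  N <- normalize_scores(A)
  expect_equal(N, matrix(c(0, 0.5, 1, 0.25), 2, 2))
  expect_equal(min(N), 0)
  expect_equal(max(N), 1)
  expect_equal(normalize_scores(3 * A + 7), N)
  expect_error(normalize_scores(matrix(1, 2, 2)), "constant")
})

test_that("pseudobulk sums cells per sample invariantly to cell order", {
  cc <- rbind(c(1, 2), c(3, 4), c(10, 0))
  colnames(cc) <- c("gA", "gB")
  pb <- pseudobulk(cc, c("s1", "s1", "s2"))
  expect_equal(pb[, "s1"], c(gA = 4, gB = 6))
  expect_equal(pb[, "s2"], c(gA = 10, gB = 0))
  perm <- c(3, 1, 2)
  expect_equal(pseudobulk(cc[perm, ], c("s1", "s1", "s2")[perm]), pb)
  # one cell per sample is a transpose
  pb2 <- pseudobulk(cc, c("a", "b", "c"))
  expect_equal(unname(pb2), unname(t(cc)))
  expect_error(pseudobulk(cc, c("s1", NA, "s2")), "labeled")
  expect_error(pseudobulk(cc, c("s1", "s2")), "one label per cell")
})

test_that("preranked enrichment has sign symmetry and a permutation floor", {
  set.seed(8)
  stat <- setNames(rnorm(300), paste0("g", 1:300))
  topk <- names(sort(stat, decreasing = TRUE))[1:12]
  r <- preranked_gsea(stat, topk, n_perm = 200, seed = 4)
  expect_gt(r$es, 0.9)
  expect_equal(r$p_value, 1 / 201)
  r_neg <- preranked_gsea(-stat, topk, n_perm = 200, seed = 4)
  expect_equal(r_neg$es, -r$es, tolerance = 1e-12)
  expect_error(preranked_gsea(stat, c("g1", "zz"), n_perm = 200), "2 set")
  expect_error(preranked_gsea(stat, topk, n_perm = 10), "100")
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  set.seed(12)
  stat <- setNames(rnorm(500), paste0("g", 1:500))
  set <- sample(names(stat), 30)
  ours <- preranked_gsea(stat, set, n_perm = 100, seed = 1)$es
  sorted <- sort(stat, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(sorted,
                             selectedStats = which(names(sorted) %in% set),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("scorecard scores encode direction and significance", {
  expect_equal(scorecard_score(2, 0.01), 2)
  expect_equal(scorecard_score(-1.5, 0.001), -3)
  expect_equal(scorecard_score(2, 1), 0)
  expect_equal(scorecard_score(-0.5, 1), 0)
  expect_error(scorecard_score(1, 0), "p_value")
  tab <- scorecard(list(
    d1 = list(sigA = list(nes = 2, p_value = 0.01),
              sigB = list(nes = -1, p_value = 0.1)),
    d2 = list(sigA = list(nes = 1, p_value = 0.5))))
  expect_equal(tab["sigA", "d1"], 2)
  expect_equal(tab["sigB", "d1"], -1)
  expect_true(is.na(tab["sigB", "d2"]))
})

test_that("binomial overlap test is exact, monotone and matches brute force", {
  expect_equal(signif(overlap_binomial(13, 28, 742, 7548), 1), 7e-7)
  expect_equal(signif(overlap_binomial(15, 28, 751, 7548), 1), 1e-8)
  expect_equal(overlap_binomial(0, 28, 742, 7548), 1)
  brute <- function(k, n, p) sum(choose(n, k:n) * p^(k:n) *
                                   (1 - p)^(n - k:n))
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:30, 1); k <- sample(0:n, 1)
    m <- sample(1:50, 1); M <- m + sample(1:200, 1)
    expect_equal(overlap_binomial(k, n, m, M), brute(k, n, m / M),
                 tolerance = 1e-10)
  }
  p_by_k <- sapply(0:28, overlap_binomial, n = 28, m = 742, M = 7548)
  expect_true(all(diff(p_by_k) < 0))
  expect_error(overlap_binomial(5, 4, 10, 100), "invalid")
})

test_that("informative signatures dominate the scorecard on synthetic cohorts", {
  cohort <- gen_expression_cohort(n_per_group = c(10, 10), n_sets = 40,
                                  n_informative = 4, effect_size = 1,
                                  seed = 17)
  rk <- differential_stat(cohort$counts, cohort$labels)
  ranked <- setNames(rk$statistic, rk$gene)
  scores <- vapply(names(cohort$sets), function(nm) {
    r <- preranked_gsea(ranked, cohort$sets[[nm]], n_perm = 300,
                        seed = 2)
    abs(scorecard_score(r$nes, r$p_value))
  }, 0)
  inf <- scores[cohort$informative_sets]
  bg <- scores[setdiff(names(scores), cohort$informative_sets)]
  expect_gt(mean(min(inf) > bg), 0.95)
})
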