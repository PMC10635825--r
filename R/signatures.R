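#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: set name, description, then gene
#' identifiers. Gene lists are deduplicated; empty sets and duplicate set
#' names are errors.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors with a \code{descriptions}
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nms)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  names(sets) <- nms
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2), nms)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets),
                                                      names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' Per-sample enrichment score for each gene set: genes are ranked within
#' each sample, and the score is the integrated difference between the
#' rank-weighted empirical distribution of the set's genes and the uniform
#' distribution of the remaining genes, with rank weights \code{rank^alpha}.
#' Purely rank-based: strictly increasing transforms of a sample's
#' expression leave its scores unchanged. Ties receive average ranks.
#'
#' @param expr Numeric matrix, genes x samples, rownames = gene ids.
#' @param sets Named list of gene-id character vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param min_overlap Minimum genes of a set present in the matrix; sets
#'   below this score \code{NA} with a warning.
#' @return Matrix of scores, sets x samples.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, min_overlap = 1) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr needs gene rownames")
  if (anyDuplicated(rownames(expr))) stop("gene identifiers must be unique")
  ng <- nrow(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  memb <- lapply(sets, function(g) rownames(expr) %in% g)
  ok <- vapply(memb, sum, 0L) >= min_overlap
  if (any(!ok))
    warning("sets with insufficient overlap scored NA: ",
            paste(names(sets)[!ok], collapse = ", "))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    for (si in which(ok)) {
      inset <- memb[[si]][ord]
      m <- sum(inset)
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (ng - m)
      out[si, j] <- sum(p_in - p_out)
    }
  }
  out
}

#' Global min-max normalization of a score matrix
#'
#' N_ij = (A_ij - min(A)) / (max(A) - min(A)) over the whole matrix, so the
#' normalized scores lie in [0, 1] with both bounds attained.
#'
#' @param A Numeric matrix of signature scores (signatures x samples).
#' @return Normalized matrix, same shape.
#' @export
normalize_scores <- function(A) {
  A <- as.matrix(A)
  rng <- range(A, na.rm = TRUE)
  if (!(rng[2] > rng[1])) stop("constant score matrix: min equals max")
  (A - rng[1]) / (rng[2] - rng[1])
}

#' Pseudobulk aggregation of single-cell counts
#'
#' Sums raw counts of all cells per sample, yielding a genes x samples count
#' matrix. Sample column order follows the sorted unique labels.
#'
#' @param cell_counts Matrix, cells x genes (colnames = gene ids).
#' @param sample_labels Character/factor of length \code{nrow(cell_counts)}.
#' @return Matrix, genes x samples.
#' @export
pseudobulk <- function(cell_counts, sample_labels) {
  cell_counts <- as.matrix(cell_counts)
  if (length(sample_labels) != nrow(cell_counts))
    stop("one label per cell required")
  if (any(is.na(sample_labels))) stop("every cell must be labeled")
  labs <- sort(unique(as.character(sample_labels)))
  out <- vapply(labs, function(s) {
    rows <- which(as.character(sample_labels) == s)
    if (!length(rows)) stop("empty sample: ", s)
    colSums(cell_counts[rows, , drop = FALSE])
  }, numeric(ncol(cell_counts)))
  rownames(out) <- colnames(cell_counts)
  out
}

#' Welch-t differential ranking statistic
#'
#' Per-gene two-sided Welch t statistics comparing two groups on log-scale
#' expression (log2 counts-per-million with a 0.5 pseudocount when given
#' counts), with Benjamini-Hochberg FDR. Serves as the ranking statistic for
#' preranked enrichment of group contrasts.
#'
#' @param expr Genes x samples matrix.
#' @param group Logical/two-level vector over samples; statistics are signed
#'   so positive means higher in the \code{TRUE} (first) group.
#' @param is_counts If \code{TRUE} (default), log-CPM transform first.
#' @return data.frame: \code{gene}, \code{statistic}, \code{p_value},
#'   \code{fdr}, sorted by decreasing statistic.
#' @export
differential_stat <- function(expr, group, is_counts = TRUE) {
  expr <- as.matrix(expr)
  if (is.logical(group)) g1 <- group
  else {
    lv <- unique(as.character(group))
    if (length(lv) != 2) stop("group must have exactly two levels")
    g1 <- as.character(group) == lv[1]
  }
  if (sum(g1) < 2 || sum(!g1) < 2) stop("need >= 2 samples per group")
  x <- if (is_counts)
    log2(t(t(expr) / pmax(colSums(expr), 1)) * 1e6 + 0.5) else expr
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, !g1, drop = FALSE], 1, var)
  n1 <- sum(g1); n2 <- sum(!g1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(pmax(se2, .Machine$double.eps))
  df <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)),
                     .Machine$double.eps)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  out <- data.frame(gene = rownames(expr), statistic = tstat, p_value = p,
                    fdr = p.adjust(p, "BH"), row.names = NULL)
  out[order(-out$statistic), ]
}

#' Preranked gene set enrichment with permutation testing
#'
#' Classical running-sum enrichment score on a ranked gene list (weights
#' \code{|statistic|^weight_exp}), with gene-label permutations for
#' significance: NES is the observed ES divided by the mean absolute
#' permutation ES of the same sign, and P = (1 + #{|ES_perm| >= |ES|}) /
#' (n_perm + 1), so the smallest attainable P is 1/(n_perm + 1).
#'
#' @param ranked Named numeric vector (gene -> statistic), any order.
#' @param set Character vector of gene ids; at least 2 must be present.
#' @param n_perm Number of gene-label permutations (default 1000, min 100).
#' @param seed Integer seed.
#' @param weight_exp Weight exponent on the ranking statistic (default 1).
#' @return List of class \code{enrichment_result}: \code{es}, \code{nes},
#'   \code{p_value}, \code{size}.
#' @export
preranked_gsea <- function(ranked, set, n_perm = 1000, seed = 1,
                           weight_exp = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  stat <- sort(ranked, decreasing = TRUE)
  genes <- names(stat)
  inset <- genes %in% set
  m <- sum(inset)
  if (m < 2) stop("fewer than 2 set genes present in the ranking")
  es_of <- function(inset) {
    w <- abs(stat)^weight_exp * inset
    sw <- sum(w)
    if (sw == 0) return(0)
    hit <- cumsum(w) / sw
    miss <- cumsum(!inset) / (length(inset) - sum(inset))
    d <- hit - miss
    d[[which.max(abs(d))]]
  }
  es <- es_of(inset)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(genes), m)
    v <- logical(length(genes)); v[idx] <- TRUE
    es_of(v)
  }, 0)
  same_sign <- perm[sign(perm) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else
    sign(es) * abs(es) / mean(abs(perm))
  p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  structure(list(es = es, nes = nes, p_value = p, size = m),
            class = "enrichment_result")
}

#' Scorecard score: signed significance of differential enrichment
#'
#' score = -1 * sign(NES) * log10(P). With the convention that positive NES
#' means first-group enrichment, positive scores indicate first-group
#' enrichment with magnitude -log10 P.
#'
#' @param nes Normalized enrichment score(s).
#' @param p_value P value(s) in (0, 1].
#' @return Numeric score(s).
#' @export
scorecard_score <- function(nes, p_value) {
  if (any(p_value <= 0) || any(p_value > 1))
    stop("p_value must lie in (0, 1]")
  -1 * sign(nes) * log10(p_value)
}

#' Scorecard table across signatures and datasets
#'
#' @param results Nested list: dataset -> signature ->
#'   \code{enrichment_result} (or any list with \code{nes} and
#'   \code{p_value}).
#' @return data.frame signature x dataset of scorecard scores.
#' @export
scorecard <- function(results) {
  datasets <- names(results)
  sigs <- unique(unlist(lapply(results, names)))
  out <- matrix(NA_real_, length(sigs), length(datasets),
                dimnames = list(sigs, datasets))
  for (d in datasets) for (s in names(results[[d]])) {
    r <- results[[d]][[s]]
    out[s, d] <- scorecard_score(r$nes, r$p_value)
  }
  as.data.frame(out)
}

#' Exact one-sided binomial overlap test
#'
#' Probability of observing at least \code{k} significant gene sets among
#' \code{n} selected, when \code{m} of the \code{M} compendium sets are
#' significant: P(X >= k), X ~ Binomial(n, m/M).
#'
#' @param k Significant among selected (0 <= k <= n).
#' @param n Selected set count.
#' @param m Significant sets in the compendium.
#' @param M Compendium size.
#' @return Exact tail P value.
#' @export
overlap_binomial <- function(k, n, m, M) {
  if (k < 0 || k > n || m <= 0 || m > M || n < 1)
    stop("invalid counts: need 0 <= k <= n and 0 < m <= M")
  pbinom(k - 1, n, m / M, lower.tail = FALSE)
}
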