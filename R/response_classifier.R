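#' Assemble a feature table for response classification
#'
#' @param features Samples x features numeric matrix or data.frame
#'   (normalized signature scores or cell frequencies).
#' @param labels Logical (or two-level) vector: \code{TRUE} = responder.
#' @return data.frame of class \code{feature_table} with a \code{label}
#'   column followed by features.
#' @export
feature_table <- function(features, labels) {
  features <- as.data.frame(features)
  if (ncol(features) < 1) stop("need at least one feature")
  if (length(labels) != nrow(features))
    stop("one label per sample required")
  if (any(is.na(labels))) stop("labels must not be missing")
  lab <- if (is.logical(labels)) labels else {
    lv <- unique(as.character(labels))
    if (length(lv) != 2) stop("labels must have exactly two classes")
    as.character(labels) == lv[1]
  }
  if (all(lab) || !any(lab)) stop("labels must contain both classes")
  structure(cbind(data.frame(label = lab), features),
            class = c("feature_table", "data.frame"))
}

# Fast logistic fit on a design matrix; returns coef, aic, converged flag.
.logit_fit <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  eta <- drop(X %*% fit$coefficients)
  p <- plogis(eta)
  list(coefficients = fit$coefficients, aic = fit$aic,
       fitted = p, converged = fit$converged)
}

#' Fit a logistic response classifier on selected features
#'
#' Maximum-likelihood logistic regression of responder status on the given
#' feature subset, reporting AIC, training accuracy (0.5 probability
#' threshold) and a complete-separation flag.
#'
#' @param table A \code{\link{feature_table}}.
#' @param features Character vector of feature names (may be empty:
#'   intercept-only model).
#' @return List of class \code{cart_classifier}: \code{features},
#'   \code{coefficients}, \code{aic}, \code{train_accuracy},
#'   \code{separation}.
#' @export
fit_logistic <- function(table, features = setdiff(names(table), "label")) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$label
  if (all(y) || !any(y)) stop("training rows must contain both classes")
  bad <- setdiff(features, names(table))
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, features, drop = FALSE]))
  if (qr(X)$rank < ncol(X))
    stop("singular design; collinear features among: ",
         paste(features, collapse = ", "))
  f <- .logit_fit(X, y)
  pred <- f$fitted >= 0.5
  sep <- all(f$fitted[y] > 1 - 1e-6) && all(f$fitted[!y] < 1e-6)
  structure(list(features = features, coefficients = f$coefficients,
                 aic = f$aic, train_accuracy = mean(pred == y),
                 separation = sep),
            class = "cart_classifier")
}

#' Predict class labels from a fitted classifier
#'
#' @param object A \code{cart_classifier}.
#' @param newdata data.frame containing the model's features.
#' @param threshold Probability threshold (default 0.5).
#' @param ... Unused.
#' @return Logical vector of predicted responder status.
#' @export
predict.cart_classifier <- function(object, newdata, threshold = 0.5, ...) {
  X <- cbind(1, as.matrix(newdata[, object$features, drop = FALSE]))
  plogis(drop(X %*% object$coefficients)) >= threshold
}

#' Classification accuracy from a confusion summary
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN).
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Accuracy in [0, 1].
#' @export
confusion_accuracy <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("empty confusion summary")
  (tp + tn) / tot
}

#' Genetic-algorithm feature selection for the logistic classifier
#'
#' Selects the feature subset minimizing training AIC (training accuracy as
#' tie-break) with a generational genetic algorithm: population 100,
#' per-bit mutation rate 0.001, immigration rate 0.3 (fraction of each
#' generation replaced by random immigrants), reproduction rate 0.1
#' (elitist carry-over), uniform crossover, fitness-rank selection.
#' Subsets larger than \code{max_features} are penalized out. Deterministic
#' given \code{seed}.
#'
#' @param table A \code{\link{feature_table}} (training split).
#' @param candidates Candidate feature names (default: all features).
#' @param pop_size,mutation_rate,immigration_rate,reproduction_rate GA
#'   settings.
#' @param generations Maximum generations (default 25).
#' @param patience Stop after this many generations without improvement.
#' @param max_features Cap on subset size (default 8).
#' @param seed Integer seed.
#' @return List: \code{features} (selected subset), \code{aic},
#'   \code{train_accuracy}.
#' @export
ga_select <- function(table, candidates = setdiff(names(table), "label"),
                      pop_size = 100, mutation_rate = 0.001,
                      immigration_rate = 0.3, reproduction_rate = 0.1,
                      generations = 25, patience = 8, max_features = 8,
                      seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (!length(candidates)) stop("empty candidate feature pool")
  bad <- setdiff(candidates, names(table))
  if (length(bad)) stop("unknown candidates: ", paste(bad, collapse = ", "))
  y <- table$label
  Xall <- as.matrix(table[, candidates, drop = FALSE])
  nf <- length(candidates)
  eval_mask <- function(mask) {
    k <- sum(mask)
    if (k > max_features) return(c(Inf, 0))
    X <- cbind(1, Xall[, mask, drop = FALSE])
    if (k > 0 && qr(X)$rank < ncol(X)) return(c(Inf, 0))
    f <- tryCatch(.logit_fit(X, y), error = function(e) NULL)
    if (is.null(f)) return(c(Inf, 0))
    c(f$aic, mean((f$fitted >= 0.5) == y))
  }
  set.seed(seed)
  pop <- matrix(runif(pop_size * nf) < 0.15, pop_size, nf)
  cache <- new.env(hash = TRUE)
  score_pop <- function(pop) {
    t(apply(pop, 1, function(mask) {
      key <- paste0("k", paste(which(mask), collapse = ","))
      if (is.null(cache[[key]])) cache[[key]] <- eval_mask(mask)
      cache[[key]]
    }))
  }
  sc <- score_pop(pop)
  # order: AIC ascending, accuracy descending as tie-break
  rank_order <- function(sc) order(sc[, 1], -sc[, 2])
  best <- NULL; best_sc <- c(Inf, 0); stall <- 0
  for (gen in seq_len(generations)) {
    ord <- rank_order(sc)
    if (sc[ord[1], 1] < best_sc[1] - 1e-12 ||
        (abs(sc[ord[1], 1] - best_sc[1]) <= 1e-12 &&
         sc[ord[1], 2] > best_sc[2] + 1e-12)) {
      best <- pop[ord[1], ]; best_sc <- sc[ord[1], ]; stall <- 0
    } else stall <- stall + 1
    if (stall >= patience) break
    n_elite <- max(1, round(reproduction_rate * pop_size))
    n_imm <- round(immigration_rate * pop_size)
    n_cross <- pop_size - n_elite - n_imm
    elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    # rank-weighted parent selection
    w <- rev(seq_len(pop_size)) / sum(seq_len(pop_size))
    parents <- function(n) ord[sample.int(pop_size, n, replace = TRUE,
                                          prob = w)]
    p1 <- parents(n_cross); p2 <- parents(n_cross)
    cross_mask <- matrix(runif(n_cross * nf) < 0.5, n_cross, nf)
    children <- pop[p1, , drop = FALSE]
    children[cross_mask] <- pop[p2, , drop = FALSE][cross_mask]
    mut <- matrix(runif(n_cross * nf) < mutation_rate, n_cross, nf)
    children <- xor(children, mut)
    imm <- matrix(runif(n_imm * nf) < 0.15, n_imm, nf)
    pop <- rbind(elite, children, imm)
    sc <- score_pop(pop)
  }
  ord <- rank_order(sc)
  if (sc[ord[1], 1] < best_sc[1] ||
      (sc[ord[1], 1] == best_sc[1] && sc[ord[1], 2] > best_sc[2])) {
    best <- pop[ord[1], ]; best_sc <- sc[ord[1], ]
  }
  list(features = candidates[best], aic = best_sc[1],
       train_accuracy = best_sc[2])
}

# Stratified train/test split indices.
.stratified_split <- function(y, train_frac) {
  idx1 <- which(y); idx0 <- which(!y)
  n1 <- round(train_frac * length(idx1))
  n0 <- round(train_frac * length(idx0))
  n1 <- min(max(n1, 1), length(idx1) - 1)
  n0 <- min(max(n0, 1), length(idx0) - 1)
  train <- c(sample(idx1, n1), sample(idx0, n0))
  list(train = sort(train), test = setdiff(seq_along(y), train))
}

#' Cross-validated accuracy distribution
#'
#' Repeated stratified 60:40 train/test splits. Per iteration the feature
#' set is chosen according to \code{mode}: \code{"ga_transcriptome"} runs GA
#' selection over \code{candidates} on the training split;
#' \code{"fixed_bivariate"} uses exactly the two features in
#' \code{candidates} with no selection; \code{"random_pathway"} draws a
#' random subset of 2-6 features from \code{null_pool} (sizes from
#' \code{size_distribution}); \code{"null"} predicts labels at random,
#' ignoring features. The model is fit on the training split and accuracy
#' measured on the test split.
#'
#' @param table A \code{\link{feature_table}}.
#' @param mode One of \code{"ga_transcriptome"}, \code{"fixed_bivariate"},
#'   \code{"random_pathway"}, \code{"null"}.
#' @param candidates Feature names for GA / bivariate modes.
#' @param null_pool Feature names forming the uninformative pool for
#'   \code{"random_pathway"}.
#' @param size_distribution Named probabilities over subset sizes 2..6 for
#'   \code{"random_pathway"} (default uniform).
#' @param n_iter Iterations (published setting 2500).
#' @param train_frac Training fraction (default 0.6).
#' @param seed Integer seed.
#' @param ga_args List of overrides passed to \code{\link{ga_select}}.
#' @return List of class \code{accuracy_distribution}: \code{accuracy}
#'   (length \code{n_iter}), \code{selected} (list of per-iteration feature
#'   subsets), \code{mode}, \code{seed}.
#' @export
cv_accuracy <- function(table,
                        mode = c("ga_transcriptome", "fixed_bivariate",
                                 "random_pathway", "null"),
                        candidates = setdiff(names(table), "label"),
                        null_pool = NULL, size_distribution = NULL,
                        n_iter = 2500, train_frac = 0.6, seed = 1,
                        ga_args = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "feature_table"))
  y <- table$label
  if (min(sum(y), sum(!y)) < 2)
    stop("class too small for stratified splitting")
  if (mode == "fixed_bivariate" && length(candidates) != 2)
    stop("fixed_bivariate mode requires exactly 2 features")
  if (mode == "random_pathway") {
    if (is.null(null_pool)) stop("random_pathway mode needs null_pool")
    sizes <- random_pathway_sizes(n_iter, size_distribution, seed = seed)
  }
  set.seed(seed)
  iter_seeds <- sample.int(2^30, n_iter)
  acc <- numeric(n_iter)
  selected <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    sp <- .stratified_split(y, train_frac)
    train <- table[sp$train, , drop = FALSE]
    test <- table[sp$test, , drop = FALSE]
    if (mode == "null") {
      pred <- runif(nrow(test)) < 0.5
      selected[[i]] <- character(0)
    } else {
      feats <- switch(mode,
        ga_transcriptome = do.call(ga_select,
          c(list(table = train, candidates = candidates,
                 seed = iter_seeds[i]), ga_args))$features,
        fixed_bivariate = candidates,
        random_pathway = sample(null_pool, sizes[i]))
      selected[[i]] <- feats
      model <- tryCatch(fit_logistic(train, feats),
                        error = function(e) NULL)
      pred <- if (is.null(model)) rep(mean(train$label) >= 0.5,
                                      nrow(test))
              else predict(model, test)
    }
    acc[i] <- mean(pred == test$label)
  }
  structure(list(accuracy = acc, selected = selected, mode = mode,
                 seed = seed),
            class = "accuracy_distribution")
}

#' Compare two accuracy distributions
#'
#' Two-sided Wilcoxon rank-sum test (midranks for ties).
#'
#' @param a,b \code{accuracy_distribution}s or numeric vectors.
#' @return Two-sided P value.
#' @export
compare_accuracy <- function(a, b) {
  av <- if (inherits(a, "accuracy_distribution")) a$accuracy else a
  bv <- if (inherits(b, "accuracy_distribution")) b$accuracy else b
  if (!length(av) || !length(bv)) stop("empty accuracy distribution")
  if (length(unique(c(av, bv))) == 1L) return(1)
  suppressWarnings(wilcox.test(av, bv, exact = FALSE)$p.value)
}

#' Feature inclusion frequency across trained models
#'
#' @param runs List of character vectors (selected feature subsets), or an
#'   \code{accuracy_distribution} carrying them.
#' @param features Optional universe of features to report (default: union
#'   of all selected).
#' @return Named numeric vector of inclusion fractions in [0, 1].
#' @export
inclusion_frequency <- function(runs, features = NULL) {
  if (inherits(runs, "accuracy_distribution")) runs <- runs$selected
  if (!length(runs)) stop("need at least one run")
  if (is.null(features)) features <- sort(unique(unlist(runs)))
  counts <- vapply(features, function(f)
    sum(vapply(runs, function(r) f %in% r, TRUE)), 0)
  counts / length(runs)
}

#' Sample subset sizes for the random-pathway control
#'
#' Draws subset sizes in 2..6 from a supplied empirical distribution (e.g.
#' the observed sizes of GA-selected models), for building random-pathway
#' control classifiers from an uninformative compendium.
#'
#' @param n Number of draws.
#' @param size_distribution Named numeric vector of probabilities with names
#'   in "2".."6" (default uniform over 2..6).
#' @param seed Integer seed.
#' @return Integer vector of sizes in [2, 6].
#' @export
random_pathway_sizes <- function(n, size_distribution = NULL, seed = 1) {
  if (is.null(size_distribution))
    size_distribution <- setNames(rep(0.2, 5), 2:6)
  sz <- as.integer(names(size_distribution))
  if (any(is.na(sz)) || any(sz < 2) || any(sz > 6))
    stop("size distribution must cover sizes within [2, 6]")
  pr <- size_distribution / sum(size_distribution)
  set.seed(seed)
  sample(sz, n, replace = TRUE, prob = pr)
}
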