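#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as.logical(as.integer(factor(labels)) - 1L)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' L2-regularized logistic classifier trained by gradient descent
#'
#' The package's native default classifier for cross-validation. Features
#' are standardized with training-fold statistics inside `fit`; `score`
#' returns class-1 probabilities.
#'
#' @param lambda Ridge penalty (default 0.01).
#' @param lr Learning rate (default 0.5).
#' @param n_iter Gradient steps (default 500).
#' @return A classifier: list with `fit(x, y) -> model` and
#'   `score(model, x) -> prob` functions (x is samples x features).
#' @export
logistic_classifier <- function(lambda = 0.01, lr = 0.5, n_iter = 500L) {
  list(
    fit = function(x, y) {
      x <- as.matrix(x)
      mu <- colMeans(x)
      sd_ <- apply(x, 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      xs <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
      y <- as.numeric(as.integer(factor(y)) - 1L)
      n <- nrow(xs); p <- ncol(xs)
      w <- numeric(p); b <- 0
      for (it in seq_len(n_iter)) {
        eta <- drop(xs %*% w) + b
        prob <- 1 / (1 + exp(-eta))
        gw <- drop(crossprod(xs, prob - y)) / n + lambda * w
        gb <- mean(prob - y)
        w <- w - lr * gw
        b <- b - lr * gb
      }
      list(w = w, b = b, mu = mu, sd = sd_)
    },
    score = function(model, x) {
      x <- as.matrix(x)
      xs <- sweep(sweep(x, 2L, model$mu), 2L, model$sd, "/")
      1 / (1 + exp(-(drop(xs %*% model$w) + model$b)))
    })
}

# Seeded stratified fold assignment: within each class, shuffled indices
# are dealt round-robin, so fold class counts differ by at most one.
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) stop("class with fewer members than folds")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified repeated cross-validated classification
#'
#' Evaluates a classifier under stratified k-fold cross-validation with
#' repeats; repeat r uses seed `base_seed + r - 1` for its fold assignment.
#' AUC is computed on held-out scores; accuracy thresholds scores at 0.5.
#'
#' @param x Feature matrix, samples x features.
#' @param labels Binary labels over samples.
#' @param classifier A fit/score pair as from [logistic_classifier()]
#'   (the default).
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Repeats (default 10).
#' @param base_seed First repeat's seed (default 0).
#' @return List of class `cv_report`: `folds` (data.frame rep, fold, auc,
#'   accuracy), `summary` (mean and sd per metric), `seed_list`.
#' @export
stratified_cv_evaluate <- function(x, labels, classifier = logistic_classifier(),
                                   n_folds = 5L, n_repeats = 10L,
                                   base_seed = 0L) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop("labels must have exactly two classes")
  seeds <- base_seed + seq_len(n_repeats) - 1L
  rows <- list()
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds, seeds[r])
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- fold == f
      model <- classifier$fit(x[tr, , drop = FALSE], y[tr])
      sc <- classifier$score(model, x[te, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f,
        auc = auc(sc, y[te]),
        accuracy = mean((sc >= 0.5) == (y[te] == 1L)))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    summary = data.frame(
      metric = c("auc", "accuracy"),
      mean = c(mean(folds$auc), mean(folds$accuracy)),
      sd = c(stats::sd(folds$auc), stats::sd(folds$accuracy))),
    seed_list = seeds), class = "cv_report")
}

#' Permutation importance of features
#'
#' Model-agnostic importance: under stratified 5-fold splits, the drop in
#' held-out AUC when a feature's held-out column is permuted, averaged over
#' folds and permutations. Used to rank functional readouts by their
#' contribution to the classifier; importances are raw AUC drops, not
#' normalized.
#'
#' @param x Feature matrix, samples x features (named columns).
#' @param labels Binary labels.
#' @param classifier fit/score pair (default [logistic_classifier()]).
#' @param n_perms Permutations per feature per fold (default 20).
#' @param seed Seed for folds and permutations.
#' @return Named numeric vector of mean AUC drops per feature.
#' @export
permutation_importance <- function(x, labels,
                                   classifier = logistic_classifier(),
                                   n_perms = 20L, seed = 0L) {
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  fold <- stratified_folds(y, 5L, seed)
  set.seed(seed + 1L)
  imp <- matrix(0, nrow = 5L, ncol = ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (f in 1:5) {
    tr <- fold != f; te <- fold == f
    model <- classifier$fit(x[tr, , drop = FALSE], y[tr])
    base <- auc(classifier$score(model, x[te, , drop = FALSE]), y[te])
    for (j in seq_len(ncol(x))) {
      drops <- numeric(n_perms)
      for (pm in seq_len(n_perms)) {
        xp <- x[te, , drop = FALSE]
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        drops[pm] <- base - auc(classifier$score(model, xp), y[te])
      }
      imp[f, j] <- mean(drops)
    }
  }
  colMeans(imp)
}

#' Principal-component sample scores
#'
#' Column-centered (optionally unit-scaled) projection of the samples on
#' the top principal axes.
#'
#' @param x Feature matrix, samples x features.
#' @param n_components Number of components (default 2).
#' @param scale. Unit-scale features first? (default FALSE)
#' @return Samples x components score matrix.
#' @export
pca_scores <- function(x, n_components = 2L, scale. = FALSE) {
  x <- as.matrix(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
}

#' Partial least squares discriminant analysis scores
#'
#' NIPALS-style PLS1 on centered, unit-scaled features against the
#' centered 0/1 class response, with deflation after each component.
#' The weight vector of each component is iterated to a fixed point
#' (tolerance 1e-10, at most 500 iterations).
#'
#' @param x Feature matrix, samples x features.
#' @param labels Binary labels.
#' @param n_components Number of latent components (default 2).
#' @return List of class `plsda_fit`: `scores` (samples x components),
#'   `weights` (features x components).
#' @export
plsda_scores <- function(x, labels, n_components = 2L) {
  x <- as.matrix(x)
  y <- as.numeric(as.integer(factor(labels)) - 1L)
  if (length(unique(y)) != 2L) stop("labels must have exactly two classes")
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  yc <- y - mean(y)
  n <- nrow(xs); p <- ncol(xs)
  scores <- matrix(0, n, n_components)
  weights <- matrix(0, p, n_components)
  for (comp in seq_len(n_components)) {
    w <- drop(crossprod(xs, yc))
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(500L)) {
      t_ <- drop(xs %*% w)
      q <- sum(yc * t_) / sum(t_^2)
      w_new <- drop(crossprod(xs, yc)) * q
      nrm <- sqrt(sum(w_new^2))
      if (nrm == 0) stop("PLS convergence failure: zero weight vector")
      w_new <- w_new / nrm
      if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
      w <- w_new
      if (it == 500L) stop("PLS did not converge in 500 iterations")
    }
    t_ <- drop(xs %*% w)
    p_load <- drop(crossprod(xs, t_)) / sum(t_^2)
    q <- sum(yc * t_) / sum(t_^2)
    xs <- xs - t_ %o% p_load
    yc <- yc - t_ * q
    scores[, comp] <- t_
    weights[, comp] <- w
  }
  rownames(scores) <- rownames(x)
  rownames(weights) <- colnames(x)
  structure(list(scores = scores, weights = weights), class = "plsda_fit")
}
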