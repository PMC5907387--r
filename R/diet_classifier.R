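#' Rank-normalize features on a training set and map held-out samples
#'
#' Each feature's training values are replaced by their average ranks
#' scaled to (0, 1] (`rank / n_train`). Held-out values are mapped into
#' the training empirical distribution by linear interpolation between
#' observed (value, scaled rank) pairs, clipped to the smallest/largest
#' training rank outside the training range. A constant training feature
#' carries no order information and maps to 0.5 everywhere.
#'
#' @param train feature x sample matrix used to define the ranks.
#' @param apply_to optional feature x sample matrix of held-out samples
#'   (same features).
#' @return list with `train` and `apply_to` (NULL if not supplied), both
#'   rank-normalized.
#' @export
rank_normalize <- function(train, apply_to = NULL) {
  if (!is.null(apply_to) &&
      !identical(rownames(train), rownames(apply_to))) {
    stop("train and apply_to must share the same features")
  }
  n <- ncol(train)
  tr <- train
  ap <- apply_to
  for (f in seq_len(nrow(train))) {
    x <- train[f, ]
    if (length(unique(x)) == 1L) {
      tr[f, ] <- 0.5
      if (!is.null(ap)) ap[f, ] <- 0.5
      next
    }
    r <- rank(x, ties.method = "average") / n
    tr[f, ] <- r
    if (!is.null(ap)) {
      o <- order(x)
      # collapse duplicate training values to their (average) rank
      xs <- x[o]
      rs <- r[o]
      ux <- unique(xs)
      ur <- vapply(ux, function(v) mean(rs[xs == v]), numeric(1))
      ap[f, ] <- stats::approx(ux, ur, xout = ap[f, ], rule = 2)$y
    }
  }
  list(train = tr, apply_to = ap)
}

# Stratified fold assignment: samples of each class are dealt round-robin
# into folds after shuffling, so every fold sees both classes.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

# Balanced class weights: each class contributes equal total weight, so a
# leave-one-out training fold's slight class imbalance cannot bias the
# intercept (the classic LOO anti-learning artifact under the null).
class_weights <- function(y) {
  tab <- table(y)
  as.numeric(length(y) / (length(tab) * tab[as.character(y)]))
}

# Pick the penalty from `grid` by stratified inner CV on (x, y), scoring
# mean binomial deviance of held-out folds.
inner_cv_lambda <- function(x, y, grid, alpha, k = 5L) {
  fold <- stratified_folds(y, k)
  dev <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stop("class absent from a training fold")
    # suppress glmnet's advisory about small class counts: leave-one-out
    # at modest n triggers it on every fit
    fit <- suppressWarnings(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                     weights = class_weights(y[tr]),
                     alpha = alpha, lambda = grid, standardize = FALSE))
    pr <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response",
                         s = grid, exact = FALSE)
    eps <- 1e-12
    yy <- as.numeric(y[!tr] == levels(factor(y))[2])
    dev[f, ] <- colMeans(-2 * (yy * log(pmax(pr, eps)) +
                                 (1 - yy) * log(pmax(1 - pr, eps))))
  }
  grid[which.min(colMeans(dev))]
}

#' Leave-one-out penalized logistic diet classification
#'
#' For each sample in turn: hold it out, rank-normalize the features on the
#' remaining samples (mapping the held-out sample into that training
#' distribution), choose the penalty strength by stratified inner
#' cross-validation on the remainder only, fit the penalized logistic
#' model, and record the held-out sample's predicted probability. No
#' information from the held-out sample enters its own training fold.
#'
#' @param features feature x sample matrix.
#' @param labels binary per-sample labels (>= 6 per class).
#' @param penalty_grid penalty strengths searched by the inner CV.
#' @param alpha glmnet mixing parameter: 0 = ridge (default), 1 = lasso.
#' @param inner_folds inner CV fold count.
#' @param seed integer seed (inner fold assignment).
#' @return list of class `classification_report`: `scores` (out-of-fold
#'   probability of the second class level), `labels`, `positive_class`,
#'   `roc` and `auc` from [roc_auc()].
#' @export
loo_classify <- function(features, labels, penalty_grid = 10^seq(2, -4, -1),
                         alpha = 0, inner_folds = 5L, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must be binary")
  if (any(table(labels) < 6L)) stop("need >= 6 samples per class")
  n <- ncol(features)
  pos <- levels(labels)[2]
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)
  scores <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      tr_x <- features[, -i, drop = FALSE]
      tr_y <- labels[-i]
      rn <- rank_normalize(tr_x, features[, i, drop = FALSE])
      x <- t(rn$train)
      lam <- inner_cv_lambda(x, tr_y, penalty_grid, alpha, inner_folds)
      fit <- suppressWarnings(
        glmnet::glmnet(x, tr_y, family = "binomial", alpha = alpha,
                       weights = class_weights(tr_y),
                       lambda = penalty_grid, standardize = FALSE))
      as.numeric(stats::predict(fit, t(rn$apply_to), type = "response",
                                s = lam))
    }, numeric(1))
  })
  names(scores) <- colnames(features)
  rc <- roc_auc(scores, labels == pos)
  structure(list(scores = scores, labels = labels, positive_class = pos,
                 roc = rc$roc, auc = rc$auc),
            class = "classification_report")
}

#' Receiver operating characteristic and AUC
#'
#' Sweeps the decision threshold over the unique scores, collects
#' (false-positive rate, true-positive rate) points, and integrates the
#' curve by the trapezoidal rule; the result equals the Mann-Whitney
#' concordance probability U/(n1*n2).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or coercible) positive-class indicator; both
#'   classes must be present.
#' @return list with `roc` (data.frame fpr/tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(scores[labels] >= t) / n_pos,
                 numeric(1))
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}
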