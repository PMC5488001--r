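#' Gaussian naive Bayes classification
#'
#' Fits class priors (empirical frequencies) and per-class, per-metabolite
#' Gaussian parameters by maximum likelihood (variance denominator is the
#' class size), then scores new samples by accumulating log densities
#' under the conditional-independence assumption and normalising across
#' classes. Variances are floored at `1e-9` times the pooled variance of
#' the metabolite so constant-within-class metabolites cannot make the
#' density degenerate.
#'
#' @param X_train training abundance matrix.
#' @param y_train phenotype factor; every class needs at least 2 samples.
#' @param X_new matrix of samples to classify.
#' @return Matrix of posterior class probabilities (rows sum to 1),
#'   columns in factor-level order.
#' @export
fit_predict_nb <- function(X_train, y_train, X_new) {
  y_train <- droplevels(as.factor(y_train))
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  if (any(table(y_train) < 2L))
    stop("every class needs at least 2 training samples", call. = FALSE)
  levs <- levels(y_train)
  n <- nrow(X_train); p <- ncol(X_train)
  pooled_var <- colMeans(X_train^2) - colMeans(X_train)^2
  var_floor <- pmax(1e-9 * pooled_var, .Machine$double.xmin)
  log_post <- sapply(levs, function(g) {
    Xg <- X_train[y_train == g, , drop = FALSE]
    ng <- nrow(Xg)
    mu <- colMeans(Xg)
    # MLE variance (divide by class size), floored
    s2 <- pmax(colMeans(Xg^2) - mu^2, var_floor)
    ll <- rowSums(
      -0.5 * log(2 * pi * rep(s2, each = nrow(X_new))) -
        0.5 * sweep(X_new, 2, mu)^2 / rep(s2, each = nrow(X_new)))
    log(ng / n) + ll
  })
  log_post <- matrix(log_post, nrow = nrow(X_new),
                     dimnames = list(NULL, levs))
  softmax_rows(log_post)
}

#' k-nearest-neighbour classification
#'
#' For each query, the posterior probability of each phenotype is the
#' fraction of that phenotype among the `k` nearest training samples in
#' Euclidean distance. Distance ties at the k-th neighbour are broken by
#' taking the lowest-index training row first, so prediction is
#' deterministic. Probabilities are exact multiples of `1/k`; zeros are
#' left as zeros (any flooring is the evaluation's concern).
#'
#' @param X_train training abundance matrix.
#' @param y_train phenotype factor.
#' @param X_new matrix of samples to classify.
#' @param k neighbourhood size, `1 <= k <= nrow(X_train)`.
#' @return Matrix of class probabilities, columns in factor-level order.
#' @export
fit_predict_knn <- function(X_train, y_train, X_new, k = 5L) {
  y_train <- droplevels(as.factor(y_train))
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  n <- nrow(X_train)
  if (n < 1L) stop("empty training set", call. = FALSE)
  if (k < 1L || k > n)
    stop("`k` must lie between 1 and the number of training samples",
         call. = FALSE)
  levs <- levels(y_train)
  # full cross distance matrix (queries x train)
  d2 <- outer(rowSums(X_new^2), rowSums(X_train^2), "+") -
    2 * tcrossprod(X_new, X_train)
  probs <- t(apply(d2, 1, function(dr) {
    nb <- order(dr)[seq_len(k)]  # radix order is stable: lowest index first
    tabulate(as.integer(y_train[nb]), nbins = length(levs)) / k
  }))
  probs <- matrix(probs, nrow = nrow(X_new), dimnames = list(NULL, levs))
  probs
}
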