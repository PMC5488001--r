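#' Gaussian-kernel support vector machine classification
#'
#' One-against-one soft-margin SVM with the radial (Gaussian) kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)`, delegated to
#' \pkg{e1071} (libsvm) with Platt-scaled probability outputs. The cost
#' parameter is fixed at 1; only the kernel bandwidth `gamma` is tuned in
#' the benchmark.
#'
#' @param X_train training abundance matrix.
#' @param y_train phenotype factor with at least two classes.
#' @param X_new matrix of samples to classify.
#' @param gamma kernel bandwidth, `> 0`.
#' @param cost soft-margin cost, `> 0` (fixed at 1 in the benchmark).
#' @return Matrix of class probabilities (rows sum to 1), columns in
#'   factor-level order.
#' @export
fit_predict_svm <- function(X_train, y_train, X_new, gamma = 0.01,
                            cost = 1) {
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2L)
    stop("need at least two classes", call. = FALSE)
  if (gamma <= 0 || cost <= 0)
    stop("`gamma` and `cost` must be positive", call. = FALSE)
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  fit <- e1071::svm(X_train, y_train, kernel = "radial", gamma = gamma,
                    cost = cost, probability = TRUE, scale = FALSE)
  pr <- stats::predict(fit, X_new, probability = TRUE)
  probs <- attr(pr, "probabilities")[, levels(y_train), drop = FALSE]
  matrix(probs, nrow = nrow(X_new), dimnames = list(NULL, levels(y_train)))
}

#' Random Forest classification
#'
#' A 1000-tree ensemble of classification trees, each grown on a
#' bootstrap sample with a random subspace of `mtry` metabolites
#' considered at every split, delegated to \pkg{randomForest}. Predicted
#' probabilities are tree-vote fractions (exact multiples of
#' `1/n_trees`).
#'
#' @param X_train training abundance matrix.
#' @param y_train phenotype factor with at least two classes.
#' @param X_new matrix of samples to classify.
#' @param mtry random-subspace size per split, `1 <= mtry <= p`.
#' @param n_trees ensemble size (fixed at 1000 in the benchmark).
#' @return Matrix of vote-fraction class probabilities.
#' @export
fit_predict_rf <- function(X_train, y_train, X_new, mtry = NULL,
                           n_trees = 1000L) {
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2L)
    stop("need at least two classes", call. = FALSE)
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  p <- ncol(X_train)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry < 1L || mtry > p)
    stop("`mtry` must lie between 1 and the number of metabolites",
         call. = FALSE)
  fit <- randomForest::randomForest(X_train, y_train, ntree = n_trees,
                                    mtry = mtry)
  probs <- stats::predict(fit, X_new, type = "vote", norm.votes = TRUE)
  probs <- probs[, levels(y_train), drop = FALSE]
  matrix(probs, nrow = nrow(X_new), dimnames = list(NULL, levels(y_train)))
}

#' Feedforward neural-network classification (resilient backpropagation)
#'
#' A fully connected feedforward network with one or two logistic hidden
#' layers and a softmax output, trained full-batch by resilient
#' backpropagation (iRPROP-) minimising cross-entropy. Inputs are
#' standardised internally using training means and standard deviations.
#' If training diverges (non-finite loss) it is retried with a fresh
#' random initialisation up to 3 times, after which uniform
#' probabilities are returned with a warning.
#'
#' @param X_train training abundance matrix.
#' @param y_train phenotype factor with at least two classes.
#' @param X_new matrix of samples to classify.
#' @param n_hidden_layers 1 or 2.
#' @param nodes_per_layer hidden nodes per layer (the benchmark grid is
#'   15 to 100 by 5); two-layer networks use equal widths.
#' @param max_epochs full-batch RPROP epochs.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
fit_predict_nnet <- function(X_train, y_train, X_new, n_hidden_layers = 1L,
                             nodes_per_layer = 15L, max_epochs = 150L) {
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2L)
    stop("need at least two classes", call. = FALSE)
  if (!n_hidden_layers %in% c(1L, 2L))
    stop("`n_hidden_layers` must be 1 or 2", call. = FALSE)
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  centers <- colMeans(X_train)
  scales <- apply(X_train, 2, stats::sd)
  scales[scales == 0] <- 1
  Xs <- scale(X_train, center = centers, scale = scales)
  Xn <- scale(X_new, center = centers, scale = scales)
  Yind <- class_indicator(y_train)
  hidden <- rep(as.integer(nodes_per_layer), n_hidden_layers)
  fit <- NULL
  for (try in 1:3) {
    fit <- rprop_train(Xs, Yind, hidden, max_epochs = max_epochs)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    warning("neural network training diverged 3 times; returning uniform ",
            "probabilities", call. = FALSE)
    G <- nlevels(y_train)
    return(matrix(1 / G, nrow(X_new), G,
                  dimnames = list(NULL, levels(y_train))))
  }
  out <- nnet_forward(fit$layers, Xn)
  probs <- softmax_rows(out[[length(fit$layers) + 1L]])
  colnames(probs) <- levels(y_train)
  probs
}
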