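#' Misclassification rate (0-1 empirical risk)
#'
#' The predicted phenotype is the argmax class per row (ties go to the
#' lowest class index); the returned value is the fraction of samples
#' whose prediction differs from the truth.
#'
#' @param y_true phenotype factor (levels must match the probability
#'   columns).
#' @param prob_matrix matrix of class probabilities, one row per sample.
#' @return Misclassification fraction in [0, 1].
#' @export
misclassification_rate <- function(y_true, prob_matrix) {
  y_true <- as.factor(y_true)
  if (!is.matrix(prob_matrix)) prob_matrix <- matrix(prob_matrix, nrow = 1)
  if (nrow(prob_matrix) != length(y_true))
    stop("`y_true` and `prob_matrix` disagree in length", call. = FALSE)
  pred <- max.col(prob_matrix, ties.method = "first")
  mean(pred != as.integer(y_true))
}

#' Mean cross-entropy loss
#'
#' Per sample, `-log` of the predicted probability of the true class
#' (natural log), floored at `floor` so a zero probability yields
#' `-log(floor)` rather than infinity; the mean over samples is returned.
#' A confidently wrong prediction is punished far more than a borderline
#' one - the property that distinguishes this loss from the 0-1 loss.
#'
#' @param y_true phenotype factor.
#' @param prob_matrix matrix of class probabilities.
#' @param floor probability floor (default 1e-15). Vote- and
#'   neighbourhood-based classifiers can emit exact zeros, so their
#'   cross-entropy magnitude depends directly on this floor.
#' @return Mean loss in nats, `>= 0`.
#' @export
cross_entropy <- function(y_true, prob_matrix, floor = 1e-15) {
  y_true <- as.factor(y_true)
  if (!is.matrix(prob_matrix)) prob_matrix <- matrix(prob_matrix, nrow = 1)
  if (nrow(prob_matrix) != length(y_true))
    stop("`y_true` and `prob_matrix` disagree in length", call. = FALSE)
  p_true <- prob_matrix[cbind(seq_along(y_true), as.integer(y_true))]
  mean(-log(pmax(p_true, floor)))
}

#' Per-sample losses in one report
#'
#' Bundles both empirical risks for one set of predictions.
#'
#' @inheritParams cross_entropy
#' @return List of class `"loss_report"`: `misclassification` (fraction),
#'   `cross_entropy` (nats), `per_sample` (data frame of per-sample 0-1
#'   and log losses) and `n`.
#' @export
loss_report <- function(y_true, prob_matrix, floor = 1e-15) {
  y_true <- as.factor(y_true)
  pred <- max.col(prob_matrix, ties.method = "first")
  p_true <- prob_matrix[cbind(seq_along(y_true), as.integer(y_true))]
  structure(list(
    misclassification = mean(pred != as.integer(y_true)),
    cross_entropy = mean(-log(pmax(p_true, floor))),
    per_sample = data.frame(zero_one = as.integer(pred != as.integer(y_true)),
                            log_loss = -log(pmax(p_true, floor))),
    n = length(y_true)), class = "loss_report")
}

#' Repeated double (nested) cross-validation
#'
#' The honest error-estimation protocol for small studies: per repeat, a
#' stratified outer split is drawn; for each outer fold the entire
#' pipeline - filtering, imputation, tuning (inner CV), fitting - is
#' re-run on the outer training part only and evaluated on the held-out
#' part, so no information leaks from test samples into any modelling
#' choice. Held-out per-sample losses are pooled across outer folds
#' within a repeat and averaged across repeats.
#'
#' @param pipeline function `(X_train, y_train, X_test)` returning a
#'   probability matrix; it must encapsulate every data-dependent step,
#'   including its own inner-CV tuning.
#' @param X abundance matrix (may contain `NA`; the pipeline is
#'   responsible for imputation).
#' @param y phenotype factor.
#' @param outer_folds,repeats outer protocol sizes (defaults 5 and 10).
#' @param floor probability floor for the cross-entropy.
#' @return A `"loss_report"` whose losses are means over repeats; the
#'   element `per_repeat` holds the per-repeat pooled losses.
#' @export
repeated_double_cv <- function(pipeline, X, y, outer_folds = 5L,
                               repeats = 10L, floor = 1e-15) {
  y <- droplevels(as.factor(y))
  per_repeat <- data.frame(misclassification = numeric(repeats),
                           cross_entropy = numeric(repeats))
  for (r in seq_len(repeats)) {
    folds <- make_folds(y, outer_folds)
    pred <- matrix(NA_real_, length(y), nlevels(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      pred[!tr, ] <- pipeline(X[tr, , drop = FALSE], y[tr],
                              X[!tr, , drop = FALSE])
    }
    per_repeat$misclassification[r] <- misclassification_rate(y, pred)
    per_repeat$cross_entropy[r] <- cross_entropy(y, pred, floor = floor)
  }
  structure(list(
    misclassification = mean(per_repeat$misclassification),
    cross_entropy = mean(per_repeat$cross_entropy),
    per_repeat = per_repeat, n = length(y)), class = "loss_report")
}
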