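#' Read a user-supplied abundance table
#'
#' Expects delimited text with the first column holding sample ids, one
#' designated phenotype column, and all remaining columns numeric
#' metabolite abundances. Blank cells are treated as missing values.
#'
#' @param path file path (delimiter sniffed from the extension: `,` for
#'   `.csv`, tab otherwise).
#' @param label_column name of the phenotype column.
#' @return List with `X` (numeric matrix, rownames = sample ids) and `y`
#'   (phenotype factor).
#' @export
read_abundance_table <- function(path, label_column) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop("no column named '", label_column, "' in ", path, call. = FALSE)
  ids <- df[[1]]
  y <- factor(df[[label_column]])
  feat <- setdiff(names(df)[-1], label_column)
  X <- as.matrix(df[, feat, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  list(X = X, y = y)
}

#' Evaluate the benchmark classifiers on a real abundance table
#'
#' Runs the same pipeline as the simulation studies - half-minimum
#' imputation, optional significance filtering fitted on training
#' samples only, cross-validated tuning, evaluation with both losses -
#' on user-supplied data. Two protocols are available: a stratified
#' train/test split, or repeated double cross-validation for small
#' studies.
#'
#' @param X numeric abundance matrix (may contain `NA`).
#' @param y phenotype factor.
#' @param protocol `"train-test"` or `"double-cv"`.
#' @param classifiers classifier ids to evaluate.
#' @param filter apply significance filtering (`TRUE` evaluates the
#'   post-filter arm, `FALSE` the pre-filter arm).
#' @param filter_method `"t"` or `"wilcoxon"`.
#' @param test_fraction held-out fraction for `"train-test"`.
#' @param outer_folds,repeats protocol sizes for `"double-cv"`.
#' @param n_folds inner tuning folds.
#' @param coarse,coarse_max grid subsampling (see [parameter_grid()]).
#' @param seed integer seed governing splits and stochastic classifiers.
#' @param floor probability floor for cross-entropy.
#' @return Data frame with one row per classifier and both losses.
#' @export
evaluate_real <- function(X, y, protocol = c("train-test", "double-cv"),
                          classifiers = benchmark_classifiers(),
                          filter = TRUE, filter_method = "wilcoxon",
                          test_fraction = 1 / 3, outer_folds = 5L,
                          repeats = 3L, n_folds = 5L, coarse = TRUE,
                          coarse_max = 25L, seed = 1L, floor = 1e-15) {
  protocol <- match.arg(protocol)
  y <- droplevels(as.factor(y))
  set.seed(seed)
  pipeline_for <- function(cl) {
    function(X_tr, y_tr, X_te) {
      imp <- impute_missing(X_tr)
      keep0 <- setdiff(seq_len(ncol(X_tr)), imp$dropped)
      X_tr2 <- imp$X
      X_te2 <- apply_imputation(X_te[, keep0, drop = FALSE], imp$fill)
      if (filter) {
        kept <- significance_filter(X_tr2, y_tr, method = filter_method)
        X_tr2 <- X_tr2[, kept, drop = FALSE]
        X_te2 <- X_te2[, kept, drop = FALSE]
      }
      tune <- tune_classifier(cl, X_tr2, y_tr, n_folds = n_folds,
                              filtered = filter, coarse = coarse,
                              coarse_max = coarse_max, floor = floor)
      do.call(classifier_function(cl),
              c(list(X_tr2, y_tr, X_te2), tune$best))
    }
  }
  rows <- lapply(classifiers, function(cl) {
    pipe <- pipeline_for(cl)
    if (protocol == "train-test") {
      te_idx <- unlist(lapply(levels(y), function(g) {
        idx <- sample(which(y == g))
        idx[seq_len(max(1L, round(length(idx) * test_fraction)))]
      }))
      te <- seq_along(y) %in% te_idx
      probs <- pipe(X[!te, , drop = FALSE], droplevels(y[!te]),
                    X[te, , drop = FALSE])
      data.frame(classifier = cl,
                 misclassification = misclassification_rate(
                   factor(y[te], levels = levels(y)), probs),
                 cross_entropy = cross_entropy(
                   factor(y[te], levels = levels(y)), probs,
                   floor = floor))
    } else {
      rep_cv <- repeated_double_cv(pipe, X, y, outer_folds = outer_folds,
                                   repeats = repeats, floor = floor)
      data.frame(classifier = cl,
                 misclassification = rep_cv$misclassification,
                 cross_entropy = rep_cv$cross_entropy)
    }
  })
  do.call(rbind, rows)
}
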