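#' Run one complete simulation study
#'
#' Simulates a dataset under `config`, splits it into stratified training
#' and test halves, and evaluates every benchmark classifier in two
#' arms: before significance filtering (all metabolites) and after
#' filtering (metabolites selected on the training samples only - Welch
#' t-tests at alpha = 0.025 in the baseline scenario, Wilcoxon rank-sum
#' tests in the realistic scenario). In each arm, missing values are
#' imputed with training-derived half-minimum values, hyperparameters
#' are tuned by inner cross-validation on the training half, and both
#' losses are measured on the test half. A classifier failure is
#' recorded as `NA` for that cell and the study continues. The result is
#' fully determined by `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this study.
#' @param classifiers character vector of classifier ids (default all
#'   seven).
#' @param arms which filter arms to run: `"pre"`, `"post"` or both.
#' @param train_fraction fraction of samples in the training half.
#' @param n_folds inner CV folds for tuning.
#' @param coarse,coarse_max grid subsampling for scaled-down runs (see
#'   [parameter_grid()]).
#' @param floor probability floor for cross-entropy.
#' @param filter_alpha significance level of the filter.
#' @return An object of class `"study_result"`: a data frame `losses`
#'   (one row per classifier x arm with both losses and the selected
#'   parameters as a string), plus `seed`, `scenario`, `n_kept`
#'   (metabolites surviving the filter) and `config`.
#' @export
run_study <- function(config, seed, classifiers = benchmark_classifiers(),
                      arms = c("pre", "post"), train_fraction = 0.5,
                      n_folds = 5L, coarse = FALSE, coarse_max = 25L,
                      floor = 1e-15, filter_alpha = 0.025) {
  arms <- match.arg(arms, several.ok = TRUE)
  set.seed(seed)
  ds <- simulate_study(config)
  y <- ds$y
  # stratified train/test split
  tr_idx <- unlist(lapply(levels(y), function(g) {
    idx <- sample(which(y == g))
    idx[seq_len(round(length(idx) * train_fraction))]
  }))
  tr <- seq_along(y) %in% tr_idx
  X_tr_raw <- ds$X[tr, , drop = FALSE]
  X_te_raw <- ds$X[!tr, , drop = FALSE]
  # test labels keep the full level set so probability columns line up
  y_tr <- droplevels(y[tr]); y_te <- factor(y[!tr], levels = levels(y))

  # half-minimum imputation fitted on the training half only
  imp <- impute_missing(X_tr_raw)
  X_tr <- imp$X
  keep0 <- setdiff(seq_len(ncol(ds$X)), imp$dropped)
  X_te <- apply_imputation(X_te_raw[, keep0, drop = FALSE], imp$fill)

  filter_method <- if (config$scenario == "realistic") "wilcoxon" else "t"
  n_kept <- NA_integer_
  arm_data <- list()
  if ("pre" %in% arms) arm_data$pre <- list(X_tr = X_tr, X_te = X_te,
                                            filtered = FALSE)
  if ("post" %in% arms) {
    kept <- significance_filter(X_tr, y_tr, method = filter_method,
                                alpha = filter_alpha)
    n_kept <- length(kept)
    arm_data$post <- list(X_tr = X_tr[, kept, drop = FALSE],
                          X_te = X_te[, kept, drop = FALSE],
                          filtered = TRUE)
  }

  rows <- list()
  for (arm in names(arm_data)) {
    ad <- arm_data[[arm]]
    for (cl in classifiers) {
      res <- tryCatch({
        tune <- tune_classifier(cl, ad$X_tr, y_tr, n_folds = n_folds,
                                filtered = ad$filtered, coarse = coarse,
                                coarse_max = coarse_max, floor = floor)
        fp <- classifier_function(cl)
        probs <- do.call(fp, c(list(ad$X_tr, y_tr, ad$X_te), tune$best))
        list(mc = misclassification_rate(y_te, probs),
             ce = cross_entropy(y_te, probs, floor = floor),
             params = paste(names(tune$best),
                            vapply(tune$best, format, ""),
                            sep = "=", collapse = ";"))
      }, error = function(e) {
        warning("classifier ", cl, " (", arm, "-filter) failed: ",
                conditionMessage(e), call. = FALSE)
        list(mc = NA_real_, ce = NA_real_, params = NA_character_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, arm = arm, misclassification = res$mc,
        cross_entropy = res$ce, params = res$params,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(losses = do.call(rbind, rows), seed = seed,
                 scenario = config$scenario, n_kept = n_kept,
                 config = config), class = "study_result")
}

#' Run a batch of independent simulation studies
#'
#' Derives one seed per study from the master seed, then runs
#' [run_study()] for each. Because every study is governed solely by its
#' own seed, results do not depend on execution order.
#'
#' @inheritParams run_study
#' @param n_studies number of studies `B`.
#' @param seed master seed.
#' @param verbose print per-study progress to stderr.
#' @param ... further arguments passed to [run_study()].
#' @return List of `"study_result"` objects.
#' @export
run_studies <- function(config, n_studies, seed = 1L, verbose = FALSE,
                        ...) {
  set.seed(seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, n_studies)
  lapply(seq_len(n_studies), function(b) {
    if (verbose)
      message(sprintf("[%s] study %d/%d (scenario %s)",
                      format(Sys.time(), "%H:%M:%S"), b, n_studies,
                      config$scenario))
    run_study(config, seed = study_seeds[b], ...)
  })
}

#' Tidy per-study losses
#'
#' @param results list of `"study_result"` objects.
#' @return Data frame with one row per study x classifier x arm.
#' @export
study_losses <- function(results) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    df <- results[[i]]$losses
    df$study <- i
    df$scenario <- results[[i]]$scenario
    df
  }))
}

#' Summarise losses over studies
#'
#' Per technique x scenario x filter arm: mean, SD, median and
#' interquartile range of each loss, computed over the non-failed
#' studies (failures are excluded cell-wise, and counted). Quantiles use
#' linear interpolation (type 7). Misclassification is reported on the
#' 0-100 percent scale.
#'
#' @param results list of `"study_result"` objects.
#' @return Data frame of class `"summary_table"`.
#' @export
aggregate_summary <- function(results) {
  if (!length(results)) stop("no study results supplied", call. = FALSE)
  df <- study_losses(results)
  df$misclassification <- 100 * df$misclassification
  out <- do.call(rbind, lapply(
    split(df, list(df$classifier, df$scenario, df$arm), drop = TRUE),
    function(d) {
      s <- function(v) {
        v <- v[!is.na(v)]
        c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
          median = stats::median(v),
          iqr = stats::IQR(v, type = 7), n = length(v))
      }
      mc <- s(d$misclassification); ce <- s(d$cross_entropy)
      data.frame(classifier = d$classifier[1], scenario = d$scenario[1],
                 arm = d$arm[1],
                 mc_mean = mc[["mean"]], mc_sd = mc[["sd"]],
                 mc_median = mc[["median"]], mc_iqr = mc[["iqr"]],
                 ce_mean = ce[["mean"]], ce_sd = ce[["sd"]],
                 ce_median = ce[["median"]], ce_iqr = ce[["iqr"]],
                 n = mc[["n"]], stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Pairwise win proportions between techniques
#'
#' Entry `(a, b)` is the proportion of studies in which technique `a`
#' achieved strictly lower loss than technique `b`; exact ties contribute
#' 0.5 to each side, so `(a, b) + (b, a) = 1`. The diagonal is `NA`.
#' Studies where either technique failed are excluded pairwise.
#'
#' @param results list of `"study_result"` objects.
#' @param loss `"misclassification"` or `"cross_entropy"`.
#' @param arm filter arm to compare (`"pre"` or `"post"`).
#' @return Square matrix of proportions, techniques in
#'   [benchmark_classifiers()] order.
#' @export
pairwise_win_matrix <- function(results,
                                loss = c("misclassification",
                                         "cross_entropy"),
                                arm = c("post", "pre")) {
  loss <- match.arg(loss); arm <- match.arg(arm)
  df <- study_losses(results)
  df <- df[df$arm == arm, ]
  techs <- intersect(benchmark_classifiers(), unique(df$classifier))
  wide <- sapply(techs, function(cl) {
    v <- df[df$classifier == cl, ]
    v[[loss]][order(v$study)]
  })
  M <- matrix(NA_real_, length(techs), length(techs),
              dimnames = list(techs, techs))
  for (a in seq_along(techs)) for (b in seq_along(techs)) {
    if (a == b) next
    ok <- !is.na(wide[, a]) & !is.na(wide[, b])
    M[a, b] <- mean((wide[ok, a] < wide[ok, b]) +
                      0.5 * (wide[ok, a] == wide[ok, b]))
  }
  M
}
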