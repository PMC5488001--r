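#' Hyperparameter grid for a classifier
#'
#' Returns the benchmark's search grid as a data frame of grid points
#' (one row per candidate parameter set), plus attributes describing the
#' axes. The grids are: PLS-DA components 1-15; sparse PLS-DA components
#' 1-15 crossed with lambda 0.1-0.9 by 0.1; Random Forest `mtry` at 25
#' points evenly spaced over [5, p] (ensemble size fixed at 1000); SVM
#' Gaussian bandwidth at 1000 log-spaced points over 10^[-5, -1] before
#' significance filtering and 10^[-2, 0] after; neural networks 1 or 2
#' hidden layers crossed with 15-100 nodes by 5 (equal widths for two
#' layers); k-NN neighbours 1-20. Naive Bayes has no tuned parameter
#' (a single empty grid point).
#'
#' @param classifier one of `"plsda"`, `"splsda"`, `"svm"`, `"rf"`,
#'   `"nnet"`, `"knn"`, `"nb"`.
#' @param p number of metabolites (needed for the `mtry` grid).
#' @param filtered logical: has significance filtering been applied?
#'   (selects the SVM bandwidth range).
#' @param coarse logical: subsample the grid to at most `coarse_max`
#'   points (evenly in order, i.e. log-uniform on log-spaced axes) for
#'   scaled-down runs.
#' @param coarse_max maximum grid points in coarse mode.
#' @return A data frame of grid points; attribute `log_axes` names the
#'   axes smoothed on the log scale.
#' @export
parameter_grid <- function(classifier = c("plsda", "splsda", "svm", "rf",
                                          "nnet", "knn", "nb"),
                           p, filtered = FALSE, coarse = FALSE,
                           coarse_max = 25L) {
  classifier <- match.arg(classifier)
  grid <- switch(classifier,
    plsda = data.frame(ncomp = 1:15),
    splsda = expand.grid(ncomp = 1:15, lambda = seq(0.1, 0.9, by = 0.1)),
    svm = {
      rng <- if (filtered) c(-2, 0) else c(-5, -1)
      data.frame(gamma = 10^seq(rng[1], rng[2], length.out = 1000))
    },
    rf = {
      if (missing(p)) stop("`p` is required for the rf grid", call. = FALSE)
      data.frame(mtry = unique(as.integer(pmin(
        round(seq(5, p, length.out = 25)), p))))
    },
    nnet = expand.grid(n_hidden_layers = 1:2,
                       nodes_per_layer = seq(15L, 100L, by = 5L)),
    knn = data.frame(k = 1:20),
    nb = data.frame(row.names = 1))
  log_axes <- switch(classifier, svm = "gamma", splsda = "lambda",
                     character(0))
  if (coarse && nrow(grid) > coarse_max) {
    idx <- unique(as.integer(round(seq(1, nrow(grid),
                                       length.out = coarse_max))))
    grid <- grid[idx, , drop = FALSE]
    rownames(grid) <- NULL
  }
  attr(grid, "log_axes") <- log_axes
  attr(grid, "classifier") <- classifier
  grid
}

# stratified fold assignment; every training part keeps all classes
make_folds <- function(y, n_folds) {
  y <- as.factor(y)
  if (n_folds < 2L) stop("`n_folds` must be at least 2", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("too few samples per class for stratified folds", call. = FALSE)
  folds <- integer(length(y))
  for (g in levels(y)) {
    idx <- sample(which(y == g))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  # a class smaller than n_folds leaves some training folds intact
  # (the class sits in few test folds); check training coverage
  for (f in seq_len(n_folds)) {
    if (nlevels(droplevels(y[folds != f])) < nlevels(y))
      stop("a class is absent from a training fold; reduce `n_folds`",
           call. = FALSE)
  }
  folds
}

#' Cross-validated cross-entropy of one parameter set
#'
#' Stratified k-fold cross-validation: per fold the classifier is fitted
#' on the training part and the mean cross-entropy of its predicted
#' probabilities is computed on the held-out part; the fold mean is
#' returned.
#'
#' @param fit_predict function `(X_train, y_train, X_new, ...)` returning
#'   a probability matrix with columns in class-level order.
#' @param X abundance matrix; `y` phenotype factor.
#' @param params named list of classifier arguments for this grid point.
#' @param n_folds number of stratified folds (default 5).
#' @param folds optional precomputed fold assignment (to share folds
#'   across grid points).
#' @param floor probability floor inside the log.
#' @return Mean held-out cross-entropy (nats).
#' @export
cv_loss <- function(fit_predict, X, y, params = list(), n_folds = 5L,
                    folds = NULL, floor = 1e-15) {
  y <- droplevels(as.factor(y))
  if (is.null(folds)) folds <- make_folds(y, n_folds)
  losses <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    probs <- do.call(fit_predict,
                     c(list(X[tr, , drop = FALSE], y[tr],
                            X[!tr, , drop = FALSE]), params))
    cross_entropy(y[!tr], probs, floor = floor)
  }, numeric(1))
  mean(losses)
}

#' Kernel-smooth a loss surface and select the minimiser
#'
#' Nadaraya-Watson smoothing with a Gaussian product kernel over the
#' numeric grid axes (log10 scale for axes flagged `log_axes`, i.e. the
#' SVM bandwidth and the sparsity penalty). The bandwidth on each axis is
#' 1.5 times the median spacing of its sorted unique values. The grid
#' point minimising the smoothed loss is selected; exact ties go to the
#' smallest parameter values (grid order).
#'
#' @param grid data frame of grid points from [parameter_grid()].
#' @param losses numeric vector of raw CV losses, one per grid row.
#' @return An object of class `"tuning_result"`: list with `grid`,
#'   `losses`, `smoothed`, `best` (the selected row as a named list) and
#'   `best_index`.
#' @export
smooth_and_select <- function(grid, losses) {
  stopifnot(nrow(grid) == length(losses), nrow(grid) >= 1L)
  log_axes <- attr(grid, "log_axes")
  if (is.null(log_axes)) log_axes <- character(0)
  m <- nrow(grid)
  if (m == 1L || ncol(grid) == 0L) {
    smoothed <- losses
  } else {
    # coordinates used for the kernel, per axis
    Wk <- matrix(1, m, m)
    for (ax in names(grid)) {
      v <- as.numeric(grid[[ax]])
      if (ax %in% log_axes) v <- log10(v)
      u <- sort(unique(v))
      if (length(u) < 2L) next
      bw <- 1.5 * stats::median(diff(u))
      D <- outer(v, v, "-") / bw
      Wk <- Wk * exp(-0.5 * D^2)
    }
    smoothed <- as.numeric(Wk %*% losses) / rowSums(Wk)
  }
  # order grid rows by axes ascending so the first minimum is the
  # smallest parameter set
  if (ncol(grid) > 0) {
    ord <- do.call(order, unname(as.list(grid)))
  } else ord <- seq_len(m)
  best_index <- ord[which.min(smoothed[ord])]
  best <- if (ncol(grid) > 0) as.list(grid[best_index, , drop = FALSE])
          else list()
  best <- lapply(best, unname)
  structure(list(grid = grid, losses = losses, smoothed = smoothed,
                 best = best, best_index = best_index),
            class = "tuning_result")
}

#' Tune one classifier by cross-validated grid search
#'
#' Evaluates every grid point by [cv_loss()] (all points share one
#' stratified fold assignment), smooths the loss surface with
#' [smooth_and_select()] and returns the selected parameters. Component
#' grids (PLS-DA, sparse PLS-DA) and the k-NN neighbour grid are
#' evaluated efficiently: one model per fold (at the largest component
#' count, or one distance ranking) serves every grid point along that
#' axis.
#'
#' @param classifier classifier id as in [parameter_grid()].
#' @param X abundance matrix; `y` phenotype factor.
#' @param grid optional grid (defaults to
#'   `parameter_grid(classifier, p = ncol(X), ...)`).
#' @param n_folds stratified CV folds.
#' @param filtered,coarse,coarse_max passed to [parameter_grid()].
#' @param floor probability floor for the cross-entropy.
#' @return A `"tuning_result"` (see [smooth_and_select()]).
#' @export
tune_classifier <- function(classifier, X, y, grid = NULL, n_folds = 5L,
                            filtered = FALSE, coarse = FALSE,
                            coarse_max = 25L, floor = 1e-15) {
  y <- droplevels(as.factor(y))
  if (is.null(grid))
    grid <- parameter_grid(classifier, p = ncol(X), filtered = filtered,
                           coarse = coarse, coarse_max = coarse_max)
  folds <- make_folds(y, n_folds)
  fold_ids <- sort(unique(folds))
  losses <- rep(NA_real_, nrow(grid))

  if (classifier %in% c("plsda", "splsda")) {
    # fit once per fold (per lambda) at the largest ncomp and score
    # every truncation
    lambdas <- if (classifier == "splsda") unique(grid$lambda) else 0
    per_fold <- matrix(0, nrow(grid), length(fold_ids))
    for (fi in seq_along(fold_ids)) {
      tr <- folds != fold_ids[fi]
      for (lam in lambdas) {
        rows <- if (classifier == "splsda") which(grid$lambda == lam)
                else seq_len(nrow(grid))
        hmax <- max(grid$ncomp[rows])
        fit <- fit_plsda(X[tr, , drop = FALSE], y[tr], H = hmax,
                         lambda = lam)
        for (r in rows) {
          probs <- predict_plsda(fit, X[!tr, , drop = FALSE],
                                 ncomp = min(grid$ncomp[r], fit$H))
          per_fold[r, fi] <- cross_entropy(y[!tr], probs, floor = floor)
        }
      }
    }
    losses <- rowMeans(per_fold)
  } else if (classifier == "knn") {
    # k beyond the smallest training part is unfittable at this n
    min_train <- length(y) - max(table(folds))
    feasible <- which(grid$k <= min_train)
    if (!length(feasible))
      stop("no feasible k for this sample size", call. = FALSE)
    per_fold <- matrix(Inf, nrow(grid), length(fold_ids))
    for (fi in seq_along(fold_ids)) {
      tr <- folds != fold_ids[fi]
      for (r in feasible) {
        probs <- fit_predict_knn(X[tr, , drop = FALSE], y[tr],
                                 X[!tr, , drop = FALSE], k = grid$k[r])
        per_fold[r, fi] <- cross_entropy(y[!tr], probs, floor = floor)
      }
    }
    losses <- rowMeans(per_fold)
    if (length(feasible) < nrow(grid)) {
      grid <- grid[feasible, , drop = FALSE]
      rownames(grid) <- NULL
      attr(grid, "log_axes") <- character(0)
      losses <- losses[feasible]
    }
  } else {
    fp <- classifier_function(classifier)
    for (r in seq_len(nrow(grid))) {
      params <- if (ncol(grid) > 0)
        lapply(as.list(grid[r, , drop = FALSE]), unname) else list()
      losses[r] <- cv_loss(fp, X, y, params = params, folds = folds,
                           floor = floor)
    }
  }
  smooth_and_select(grid, losses)
}

#' Look up the fit-and-predict function of a classifier
#'
#' All classifiers in the benchmark share one contract:
#' `f(X_train, y_train, X_new, <params>)` returning a probability matrix
#' with one column per class (factor-level order, rows summing to 1).
#'
#' @param classifier classifier id.
#' @return The fit-and-predict function.
#' @export
classifier_function <- function(classifier) {
  switch(classifier,
    plsda = function(X_train, y_train, X_new, ncomp = 3L) {
      fit <- fit_plsda(X_train, y_train, H = ncomp)
      predict_plsda(fit, X_new)
    },
    splsda = function(X_train, y_train, X_new, ncomp = 3L, lambda = 0.5) {
      fit <- fit_splsda(X_train, y_train, H = ncomp, lambda = lambda)
      predict_plsda(fit, X_new)
    },
    svm = fit_predict_svm,
    rf = fit_predict_rf,
    nnet = fit_predict_nnet,
    knn = fit_predict_knn,
    nb = function(X_train, y_train, X_new) {
      fit_predict_nb(X_train, y_train, X_new)
    },
    stop("unknown classifier: ", classifier, call. = FALSE))
}

#' @rdname classifier_function
#' @export
benchmark_classifiers <- function() {
  c("plsda", "splsda", "svm", "nnet", "rf", "knn", "nb")
}
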