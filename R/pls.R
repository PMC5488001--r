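#' One NIPALS component
#'
#' Extracts a single pair of weight vectors by the nonlinear iterative
#' partial least squares algorithm: starting from `u` (the first column
#' of `Y`), repeat `w = X'u / u'u`, normalise `w`, `t = Xw`,
#' `c = Y't / t't`, normalise `c`, `u = Yc`, until the change in `w`
#' drops below `tol` or `max_iter` iterations. At the fixed point `w` is
#' the leading left singular vector of `X'Y`. The sign convention forces
#' the largest-magnitude entry of `w` positive so output is
#' deterministic.
#'
#' @param X centred (and typically unit-scaled) predictor matrix.
#' @param Y centred class-indicator matrix.
#' @param tol convergence tolerance on the change in `w`.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @return List with unit-norm `w` (p), `c` (G), and scores `t = Xw`
#'   (n), `u = Yc` (n).
#' @export
nipals_component <- function(X, Y, tol = 1e-8, max_iter = 500L) {
  u <- Y[, 1]
  w_old <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- crossprod(X, u) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t_sc <- X %*% w
    cc <- crossprod(Y, t_sc) / sum(t_sc^2)
    cc <- cc / sqrt(sum(cc^2))
    u <- Y %*% cc
    if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
    w_old <- w
  }
  if (!converged)
    warning("NIPALS did not converge in ", max_iter, " iterations",
            call. = FALSE)
  w <- drop(w); cc <- drop(cc)
  if (w[which.max(abs(w))] < 0) { w <- -w; cc <- -cc }
  t_sc <- drop(X %*% w)
  u <- drop(Y %*% cc)
  list(w = w, c = cc, t = t_sc, u = u)
}

# indicator matrix of a factor, one column per level
class_indicator <- function(y) {
  y <- as.factor(y)
  Y <- outer(y, levels(y), "==") * 1
  colnames(Y) <- levels(y)
  Y
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Fit a (sparse) PLS-DA model
#'
#' Regresses a centred class-indicator matrix on centred, unit-scaled
#' abundances, extracting `H` components. Plain PLS-DA (`lambda = 0`)
#' uses [nipals_component()]; sparse PLS-DA obtains each weight vector
#' from the leading singular vectors of `X_h' Y_h` and soft-thresholds it
#' entrywise at `lambda * max(abs(f))` before renormalising, so
#' metabolites with zero weight drop out of the component. After each
#' component, loadings `p = X't/t't` and `q = Y't/t't` are found by least
#' squares and both matrices are deflated by the score. Class prediction
#' uses nearest centroids in score space.
#'
#' @param X abundance matrix, samples x metabolites.
#' @param y phenotype factor.
#' @param H number of components (default 3; reduced with a warning when
#'   it exceeds what the data can support).
#' @param lambda sparsity in [0, 1): the soft-threshold as a fraction of
#'   the largest absolute weight entry; 0 gives plain PLS-DA.
#' @param tol,max_iter passed to [nipals_component()].
#' @return An object of class `"pls_model"` with weight matrix `W`
#'   (p x H), response weights `C`, scores `T`, `U`, loadings `P`, `Q`,
#'   the projection matrix `Wstar = W (P'W)^{-1}`, per-class centroids in
#'   score space, centering/scaling vectors, `H` and `lambda`.
#' @export
fit_plsda <- function(X, y, H = 3L, lambda = 0, tol = 1e-8, max_iter = 500L) {
  stopifnot(is.matrix(X))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  if (lambda < 0 || lambda >= 1) stop("`lambda` must be in [0, 1)", call. = FALSE)

  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  keep_cols <- which(scales > 0)
  if (!length(keep_cols)) stop("all metabolites are constant", call. = FALSE)
  Xs <- scale(X[, keep_cols, drop = FALSE], center = centers[keep_cols],
              scale = scales[keep_cols])
  Y0 <- class_indicator(y)
  y_centers <- colMeans(Y0)
  Ys <- scale(Y0, center = y_centers, scale = FALSE)

  n <- nrow(Xs); p <- ncol(Xs); G <- ncol(Ys)
  H_max <- min(n - 1L, p)
  if (H > H_max) {
    warning("reducing H from ", H, " to ", H_max, call. = FALSE)
    H <- H_max
  }
  W <- matrix(0, p, H); C <- matrix(0, G, H)
  Tm <- matrix(0, n, H); U <- matrix(0, n, H)
  P <- matrix(0, p, H); Q <- matrix(0, G, H)
  Xh <- Xs; Yh <- Ys
  for (h in seq_len(H)) {
    if (lambda == 0) {
      comp <- nipals_component(Xh, Yh, tol = tol, max_iter = max_iter)
      w <- comp$w; cc <- comp$c; u <- comp$u
    } else {
      sv <- svd(crossprod(Xh, Yh), nu = 1, nv = 1)
      f <- drop(sv$u); g <- drop(sv$v)
      lam <- lambda
      repeat {
        w <- soft_threshold(f, lam * max(abs(f)))
        if (any(w != 0)) break
        warning("all weights thresholded to zero; reducing lambda for ",
                "component ", h, call. = FALSE)
        lam <- lam / 2
      }
      w <- w / sqrt(sum(w^2))
      if (w[which.max(abs(w))] < 0) { w <- -w; g <- -g }
      cc <- g
      u <- drop(Yh %*% cc)
    }
    t_sc <- drop(Xh %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) { H <- h - 1L; break }
    p_load <- drop(crossprod(Xh, t_sc)) / tt
    q_load <- drop(crossprod(Yh, t_sc)) / tt
    Xh <- Xh - tcrossprod(t_sc, p_load)
    Yh <- Yh - tcrossprod(t_sc, q_load)
    W[, h] <- w; C[, h] <- cc; Tm[, h] <- t_sc
    U[, h] <- u; P[, h] <- p_load; Q[, h] <- q_load
  }
  if (H < 1L) stop("no usable PLS component could be extracted", call. = FALSE)
  W <- W[, seq_len(H), drop = FALSE]; C <- C[, seq_len(H), drop = FALSE]
  Tm <- Tm[, seq_len(H), drop = FALSE]; U <- U[, seq_len(H), drop = FALSE]
  P <- P[, seq_len(H), drop = FALSE]; Q <- Q[, seq_len(H), drop = FALSE]
  # projection giving new-sample scores under deflation:
  # r_h = (I - w_1 p_1') ... (I - w_{h-1} p_{h-1}') w_h, so truncating to
  # the first k columns reproduces a k-component fit exactly
  Wstar <- matrix(0, p, H)
  for (h in seq_len(H)) {
    v <- W[, h]
    if (h > 1L) for (l in (h - 1L):1L) v <- v - W[, l] * sum(P[, l] * v)
    Wstar[, h] <- v
  }
  centroids <- apply(Tm, 2, function(col) tapply(col, y, mean))
  centroids <- matrix(centroids, nrow = nlevels(y),
                      dimnames = list(levels(y), NULL))
  structure(list(
    H = H, lambda = lambda, W = W, C = C, T = Tm, U = U, P = P, Q = Q,
    Wstar = Wstar, centroids = centroids, levels = levels(y),
    centers = centers[keep_cols], scales = scales[keep_cols],
    keep_cols = keep_cols, p_full = ncol(X)),
    class = "pls_model")
}

#' @rdname fit_plsda
#' @export
fit_splsda <- function(X, y, H = 3L, lambda = 0.5, tol = 1e-8,
                       max_iter = 500L) {
  fit_plsda(X, y, H = H, lambda = lambda, tol = tol, max_iter = max_iter)
}

#' Predict phenotype probabilities from a PLS-DA model
#'
#' Projects new samples into score space with the projection matrix
#' `Wstar` (which accounts for deflation) and converts negative squared
#' Euclidean distances to the per-class training centroids into
#' probabilities by softmax. A point equidistant from all centroids gets
#' uniform probabilities.
#'
#' @param model a `"pls_model"` from [fit_plsda()] / [fit_splsda()].
#' @param X_new matrix of new samples (same metabolites as training).
#' @param ncomp number of components to use (default all fitted);
#'   truncation is exact because deflation makes components sequential.
#' @return Matrix of class probabilities, one row per sample, columns in
#'   training class order; rows sum to 1.
#' @export
predict_plsda <- function(model, X_new, ncomp = model$H) {
  stopifnot(inherits(model, "pls_model"))
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  if (ncol(X_new) != model$p_full)
    stop("`X_new` has ", ncol(X_new), " metabolites; model expects ",
         model$p_full, call. = FALSE)
  ncomp <- min(ncomp, model$H)
  Xs <- scale(X_new[, model$keep_cols, drop = FALSE],
              center = model$centers, scale = model$scales)
  scores <- Xs %*% model$Wstar[, seq_len(ncomp), drop = FALSE]
  cents <- model$centroids[, seq_len(ncomp), drop = FALSE]
  d2 <- outer(rowSums(scores^2), rowSums(cents^2), "+") -
    2 * tcrossprod(scores, cents)
  probs <- softmax_rows(-d2)
  colnames(probs) <- model$levels
  probs
}

# row-wise softmax with the usual max shift for stability
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
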