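#' Sample the partial correlations of a C-vine
#'
#' Draws the `d(d-1)/2` partial correlations of a canonical vine (C-vine)
#' layer by layer, following the Lewandowski-Kurowicka-Joe construction.
#' The shape parameter starts at `beta = eta + (d - 1) / 2` and is
#' decremented by 1/2 at the top of each layer; every layer-`k` partial
#' correlation `rho[k, i; 1..k-1]` is drawn `Beta(beta, beta)` on (0, 1)
#' and rescaled to (-1, 1). With `eta = 1` the implied distribution over
#' full correlation matrices is uniform; larger `eta` concentrates mass
#' near the identity.
#'
#' @param d matrix dimension (number of metabolites in the block).
#' @param eta concentration parameter, `> 0`.
#' @return An object of class `"partial_correlation_vine"`: a list with
#'   elements `d`, `eta` and `partials`, a `d x d` matrix whose strict
#'   upper triangle `[k, i]` holds `rho[k, i; 1..k-1]`.
#' @references Lewandowski, Kurowicka and Joe (2009) J. Multivariate Anal.
#' @seealso [vine_to_correlation()], [sample_correlation_matrix()]
#' @examples
#' v <- sample_partial_correlations(5, eta = 1)
#' R <- vine_to_correlation(v)
#' @export
sample_partial_correlations <- function(d, eta = 1) {
  if (length(d) != 1L || !is.finite(d) || d < 1 || d != round(d))
    stop("`d` must be a positive integer", call. = FALSE)
  if (length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a positive number", call. = FALSE)
  d <- as.integer(d)
  partials <- matrix(NA_real_, d, d)
  if (d > 1L) {
    beta <- eta + (d - 1) / 2
    for (k in seq_len(d - 1L)) {
      beta <- beta - 1 / 2
      idx <- (k + 1L):d
      partials[k, idx] <- 2 * stats::rbeta(length(idx), beta, beta) - 1
    }
  }
  structure(list(d = d, eta = eta, partials = partials),
            class = "partial_correlation_vine")
}

#' Build the full correlation matrix encoded by a C-vine
#'
#' Inverts the partial-correlation recursion
#' `rho[ij;L] = rho[ij;kL] * sqrt((1 - rho[ik;L]^2) (1 - rho[jk;L]^2)) +
#' rho[ik;L] rho[jk;L]`, peeling conditioning variables from the deepest
#' layer outwards. The result is symmetric, unit-diagonal and positive
#' definite for every valid vine; a marginally indefinite result from
#' floating point is repaired by eigenvalue clipping at 1e-10.
#'
#' @param vine a `"partial_correlation_vine"` from
#'   [sample_partial_correlations()].
#' @return A `d x d` correlation matrix.
#' @export
vine_to_correlation <- function(vine) {
  stopifnot(inherits(vine, "partial_correlation_vine"))
  d <- vine$d
  prho <- vine$partials
  R <- diag(d)
  if (d > 1L) {
    for (k in seq_len(d - 1L)) {
      for (i in (k + 1L):d) {
        p <- prho[k, i]
        if (k > 1L) {
          for (l in (k - 1L):1L) {
            p <- p * sqrt((1 - prho[l, i]^2) * (1 - prho[l, k]^2)) +
              prho[l, i] * prho[l, k]
          }
        }
        R[k, i] <- R[i, k] <- p
      }
    }
  }
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) <= -1e-10)
    stop("vine produced a non positive-definite matrix", call. = FALSE)
  if (min(ev$values) < 1e-10) {
    # clip tiny/negative eigenvalues from floating point and renormalise
    vals <- pmax(ev$values, 1e-10)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    D <- 1 / sqrt(diag(R))
    R <- D * R * rep(D, each = d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
  }
  R
}

#' Recover C-vine partial correlations from a correlation matrix
#'
#' Applies the partial-correlation recursion in the forward direction,
#' conditioning variables `1..k-1` out of the correlation between
#' variables `k` and `i`. Used to verify the round trip with
#' [vine_to_correlation()].
#'
#' @param R a correlation matrix.
#' @return A `d x d` matrix whose strict upper triangle holds the partial
#'   correlations, matching the layout of
#'   [sample_partial_correlations()].
#' @export
partial_correlations_from_matrix <- function(R) {
  d <- nrow(R)
  stopifnot(is.matrix(R), ncol(R) == d)
  prho <- matrix(NA_real_, d, d)
  if (d < 2L) return(prho)
  # cond[[l]] holds rho[i, j; 1..l-1] for all pairs; build layers upward
  cur <- R
  prho[1, 2:d] <- R[1, 2:d]
  if (d > 2L) {
    for (k in 2:(d - 1L)) {
      prev <- cur
      cur <- matrix(NA_real_, d, d)
      for (i in k:d) {
        for (j in k:d) {
          if (i == j) { cur[i, j] <- 1; next }
          cur[i, j] <- (prev[i, j] - prev[i, k - 1L] * prev[j, k - 1L]) /
            sqrt((1 - prev[i, k - 1L]^2) * (1 - prev[j, k - 1L]^2))
        }
      }
      prho[k, (k + 1L):d] <- cur[k, (k + 1L):d]
    }
  }
  prho
}

#' Sample a random correlation matrix by the C-vine construction
#'
#' Convenience wrapper: draws a vine with [sample_partial_correlations()]
#' and converts it with [vine_to_correlation()].
#'
#' @inheritParams sample_partial_correlations
#' @return A `d x d` random correlation matrix, positive definite.
#' @export
sample_correlation_matrix <- function(d, eta = 1) {
  vine_to_correlation(sample_partial_correlations(d, eta))
}
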