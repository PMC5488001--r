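#' Univariate significance filtering of metabolites
#'
#' For every metabolite, all `G(G-1)/2` pairwise two-sample tests between
#' phenotype groups are run (Welch t-tests or Wilcoxon rank-sum tests);
#' a metabolite is kept when any pairwise p-value falls below `alpha`.
#' Constant metabolites (no separation possible) get p = 1 and are
#' excluded. No multiple-testing correction is applied - the threshold is
#' a raw significance level. If nothing survives, the 10 metabolites with
#' the smallest minimum p-value are kept (with a warning) so downstream
#' classifiers remain fittable.
#'
#' @param X numeric abundance matrix, samples x metabolites, complete
#'   (impute first).
#' @param y factor of phenotype labels, at least two levels with two or
#'   more samples each.
#' @param method `"t"` for Welch t-tests (baseline scenarios) or
#'   `"wilcoxon"` for rank-sum tests (realistic scenarios).
#' @param alpha raw significance level; the benchmark uses 0.025.
#' @return Sorted integer indices of the kept metabolites.
#' @export
significance_filter <- function(X, y, method = c("t", "wilcoxon"),
                                alpha = 0.025) {
  method <- match.arg(method)
  y <- droplevels(as.factor(y))
  G <- nlevels(y)
  if (G < 2L) stop("need at least two phenotype groups", call. = FALSE)
  if (any(table(y) < 2L))
    stop("every phenotype needs at least two samples", call. = FALSE)
  if (anyNA(X)) stop("`X` contains missing values; impute first", call. = FALSE)
  pairs <- utils::combn(levels(y), 2, simplify = FALSE)
  min_p <- apply(X, 2, function(v) {
    if (stats::var(v) == 0) return(1)
    p <- vapply(pairs, function(pr) {
      a <- v[y == pr[1]]; b <- v[y == pr[2]]
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        # degenerate: both groups constant - p undefined; perfect
        # separation when the constants differ
        return(if (a[1] == b[1]) 1 else 0)
      }
      if (method == "t") {
        stats::t.test(a, b)$p.value
      } else {
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      }
    }, numeric(1))
    min(p)
  })
  keep <- which(min_p < alpha)
  if (!length(keep)) {
    warning("significance filter kept nothing; falling back to the 10 ",
            "smallest-p metabolites", call. = FALSE)
    keep <- order(min_p)[seq_len(min(10L, ncol(X)))]
  }
  sort(keep)
}
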