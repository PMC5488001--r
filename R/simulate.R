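#' Configuration of one simulated metabolomics study
#'
#' Collects every knob of the data generator. The defaults encode the
#' study conditions used throughout: 40 blocks of 25 metabolites
#' (p = 1000), three phenotypes, 120 samples per study, between 1 and 5
#' perturbed blocks per comparator phenotype with block effects
#' `theta ~ Exp(rate 1/2)` and random sign, and - in the realistic
#' scenario - per-block generalized Gaussian marginals, biological and
#' technical outliers, Dirichlet-multinomial phenotype allocation and a
#' per-metabolite limit of detection.
#'
#' @param n_blocks number of metabolite blocks (biological processes).
#' @param block_size metabolites per block.
#' @param n_phenotypes number of phenotype classes (first is reference).
#' @param n_samples total samples per study.
#' @param scenario `"baseline"` (multivariate normal, balanced, complete)
#'   or `"realistic"` (skewed marginals, outliers, unbalance, missing).
#' @param eta C-vine concentration; 1 is uniform over correlation
#'   matrices.
#' @param perturb_range integer bounds of the discrete-uniform count of
#'   perturbed blocks per comparator phenotype.
#' @param theta_rate exponential rate of the block effect size (rate 1/2
#'   gives mean effect 2).
#' @param sign_prob probability that a block effect has negative sign.
#' @param ggd_kappa_range interval the per-block GGD shape is drawn from.
#' @param ggd_alpha GGD scale.
#' @param outlier_rates length-2 vector: Bernoulli rates of biological
#'   (per sample-block) and technical (per sample-metabolite) outliers.
#' @param outlier_magnitudes length-2 vector: outlier shifts in units of
#'   the metabolite standard deviation (biological, technical); signs are
#'   random.
#' @param lod_quantile per-metabolite missingness quantile `q` in
#'   [0, 0.5]: values below the pooled `q`-quantile are censored (MNAR).
#' @param dirichlet_alpha Dirichlet concentration vector for unbalanced
#'   allocation (recycled to `n_phenotypes`).
#' @param min_per_class floor on class counts under unbalanced
#'   allocation.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_blocks = 40L, block_size = 25L, n_phenotypes = 3L,
                       n_samples = 120L,
                       scenario = c("baseline", "realistic"),
                       eta = 1, perturb_range = c(1L, 5L),
                       theta_rate = 1 / 2, sign_prob = 1 / 2,
                       ggd_kappa_range = c(-0.4, 0.4), ggd_alpha = 1,
                       outlier_rates = c(biological = 0.02, technical = 0.01),
                       outlier_magnitudes = c(biological = 4, technical = 6),
                       lod_quantile = 0.05,
                       dirichlet_alpha = c(4, 4, 4),
                       min_per_class = 10L) {
  scenario <- match.arg(scenario)
  cfg <- list(
    n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
    n_phenotypes = as.integer(n_phenotypes),
    n_samples = as.integer(n_samples), scenario = scenario, eta = eta,
    perturb_range = as.integer(perturb_range), theta_rate = theta_rate,
    sign_prob = sign_prob, ggd_kappa_range = ggd_kappa_range,
    ggd_alpha = ggd_alpha, outlier_rates = outlier_rates,
    outlier_magnitudes = outlier_magnitudes, lod_quantile = lod_quantile,
    dirichlet_alpha = rep_len(dirichlet_alpha, n_phenotypes),
    min_per_class = as.integer(min_per_class))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_blocks < 1L || block_size < 1L)
      stop("block counts must be positive", call. = FALSE)
    if (n_phenotypes < 2L)
      stop("need at least 2 phenotypes", call. = FALSE)
    if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
    if (theta_rate <= 0) stop("`theta_rate` must be positive", call. = FALSE)
    if (any(outlier_rates < 0 | outlier_rates > 1) ||
        sign_prob < 0 || sign_prob > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    if (lod_quantile < 0 || lod_quantile > 0.5)
      stop("`lod_quantile` must lie in [0, 0.5]", call. = FALSE)
    if (perturb_range[1] < 1L || perturb_range[2] > n_blocks ||
        perturb_range[1] > perturb_range[2])
      stop("invalid `perturb_range`", call. = FALSE)
    if (n_samples < n_phenotypes * min_per_class)
      stop("`n_samples` too small for `min_per_class`", call. = FALSE)
  })
  invisible(cfg)
}

#' Draw the hierarchical phenotype mean structure
#'
#' The reference phenotype has mean zero everywhere. Each comparator
#' phenotype perturbs a discrete-uniform number of blocks (default 1-5):
#' per perturbed block a signed effect `theta ~ Exp(theta_rate)` (sign
#' flipped with probability `sign_prob`) is drawn, and the block's
#' metabolite means are `N(theta, 1)`. All other means are zero.
#'
#' @param config a [sim_config()].
#' @return A list of class `"phenotype_means"`: `mu` (G x p matrix of
#'   phenotype means), `perturbed_blocks` (list of block-id vectors, one
#'   per phenotype) and `theta` (list of signed block effects).
#' @export
draw_perturbed_means <- function(config) {
  p <- config$n_blocks * config$block_size
  G <- config$n_phenotypes
  mu <- matrix(0, G, p)
  perturbed <- vector("list", G)
  theta <- vector("list", G)
  perturbed[[1]] <- integer(0)
  theta[[1]] <- numeric(0)
  for (g in seq_len(G)[-1]) {
    lo <- config$perturb_range[1]; hi <- config$perturb_range[2]
    n_pert <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    blocks <- sort(sample.int(config$n_blocks, n_pert))
    th <- stats::rexp(n_pert, rate = config$theta_rate)
    th <- th * ifelse(stats::runif(n_pert) < config$sign_prob, -1, 1)
    for (b in seq_along(blocks)) {
      cols <- block_columns(blocks[b], config$block_size)
      mu[g, cols] <- stats::rnorm(config$block_size, mean = th[b], sd = 1)
    }
    perturbed[[g]] <- blocks
    theta[[g]] <- th
  }
  structure(list(mu = mu, perturbed_blocks = perturbed, theta = theta),
            class = "phenotype_means")
}

block_columns <- function(block, block_size) {
  ((block - 1L) * block_size + 1L):(block * block_size)
}

#' Draw phenotype class counts
#'
#' Balanced allocation in the baseline scenario (as equal as `n_samples`
#' allows). In the realistic scenario, class proportions are drawn from
#' `Dirichlet(dirichlet_alpha)` and counts from a multinomial, redrawn
#' until every class has at least `min_per_class` samples.
#'
#' @param config a [sim_config()].
#' @return Integer vector of class counts summing to `n_samples`.
#' @export
draw_phenotype_allocation <- function(config) {
  G <- config$n_phenotypes
  N <- config$n_samples
  if (config$scenario == "baseline") {
    base <- N %/% G
    counts <- rep(base, G)
    extra <- N - base * G
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    return(as.integer(counts))
  }
  if (N < G * config$min_per_class)
    stop("`n_samples` too small for `min_per_class`", call. = FALSE)
  repeat {
    gam <- stats::rgamma(G, shape = config$dirichlet_alpha, rate = 1)
    props <- gam / sum(gam)
    counts <- as.integer(stats::rmultinom(1, N, props))
    if (min(counts) >= config$min_per_class) return(counts)
  }
}

#' Simulate a baseline (multivariate-normal) metabolomics dataset
#'
#' Generates `n_blocks` independent blocks of `block_size` metabolites.
#' Each block has its own random C-vine correlation matrix; rows are
#' multivariate normal with the block's phenotype-specific means. Blocks
#' are concatenated columnwise, so the population cross-block correlation
#' is zero.
#'
#' @param config a [sim_config()].
#' @return An object of class `"simulated_dataset"`: list with `X`
#'   (N x p abundance matrix), `y` (factor of phenotype labels
#'   `P1..PG`), `block_of` (integer vector mapping metabolites to
#'   blocks), `truth` (the [draw_perturbed_means()] object),
#'   `correlations` (list of per-block correlation matrices),
#'   `missing_mask` (all `FALSE` here), `outlier_flags`, `scenario` and
#'   `config`.
#' @export
simulate_baseline <- function(config) {
  validate_sim_config(config)
  K <- config$n_blocks; d <- config$block_size
  G <- config$n_phenotypes; N <- config$n_samples
  p <- K * d
  truth <- draw_perturbed_means(config)
  counts <- draw_phenotype_allocation(config)
  y <- factor(rep(paste0("P", seq_len(G)), counts),
              levels = paste0("P", seq_len(G)))
  X <- matrix(NA_real_, N, p)
  correlations <- vector("list", K)
  for (k in seq_len(K)) {
    R <- sample_correlation_matrix(d, config$eta)
    correlations[[k]] <- R
    L <- chol(R)
    cols <- block_columns(k, d)
    Z <- matrix(stats::rnorm(N * d), N, d) %*% L
    X[, cols] <- Z + truth$mu[as.integer(y), cols, drop = FALSE]
  }
  colnames(X) <- paste0("m", seq_len(p))
  structure(list(
    X = X, y = y, block_of = rep(seq_len(K), each = d), truth = truth,
    correlations = correlations,
    missing_mask = matrix(FALSE, N, p),
    outlier_flags = list(
      biological = matrix(FALSE, N, K),
      technical = matrix(FALSE, N, p)),
    lod_thresholds = rep(NA_real_, p),
    X_premask = NULL,
    scenario = "baseline", config = config),
    class = "simulated_dataset")
}

#' Add realistic metabolomics artifacts to a baseline dataset
#'
#' Applies, in order: (1) biological outliers - per (sample, block) with
#' the biological rate, every value of that block for that sample is
#' shifted by the biological magnitude (in per-metabolite SD units,
#' random sign); (2) technical outliers - per (sample, metabolite) with
#' the technical rate, a single value is shifted by the technical
#' magnitude; (3) a per-block generalized Gaussian quantile transform -
#' one `(kappa, alpha)` pair per block, each metabolite mapped through
#' [ggd_quantile()] of its rescaled empirical CDF rank `rank / (n + 1)`
#' (rank-preserving, hence Spearman correlations are untouched); (4) a
#' per-metabolite limit of detection at the pooled `lod_quantile`
#' quantile - values strictly below it become `NA` (missing not at
#' random). Pre-masking values are retained in `X_premask` so the MNAR
#' mechanism can be audited against ground truth.
#'
#' @param dataset a baseline `"simulated_dataset"`.
#' @param config a [sim_config()]; defaults to the dataset's own.
#' @return The transformed `"simulated_dataset"` with `scenario =
#'   "realistic"`, updated `missing_mask`, `outlier_flags`,
#'   `lod_thresholds`, `ggd_params` and `X_premask`.
#' @export
apply_realistic_transforms <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  X <- dataset$X
  N <- nrow(X); p <- ncol(X)
  K <- config$n_blocks; d <- config$block_size
  p_b <- config$outlier_rates[[1]]; p_t <- config$outlier_rates[[2]]
  m_b <- config$outlier_magnitudes[[1]]; m_t <- config$outlier_magnitudes[[2]]

  bio <- matrix(stats::runif(N * K) < p_b, N, K)
  col_sd <- apply(X, 2, stats::sd)
  for (k in seq_len(K)) {
    hits <- which(bio[, k])
    if (!length(hits)) next
    cols <- block_columns(k, d)
    for (i in hits) {
      s <- if (stats::runif(1) < 0.5) -1 else 1
      X[i, cols] <- X[i, cols] + s * m_b * col_sd[cols]
    }
  }
  tech <- matrix(stats::runif(N * p) < p_t, N, p)
  if (any(tech)) {
    idx <- which(tech)
    s <- ifelse(stats::runif(length(idx)) < 0.5, -1, 1)
    X[idx] <- X[idx] + s * m_t * rep(col_sd, each = N)[idx]
  }

  ggd_params <- matrix(NA_real_, K, 2, dimnames = list(NULL, c("kappa", "alpha")))
  for (k in seq_len(K)) {
    kappa <- stats::runif(1, config$ggd_kappa_range[1], config$ggd_kappa_range[2])
    alpha <- config$ggd_alpha
    ggd_params[k, ] <- c(kappa, alpha)
    cols <- block_columns(k, d)
    for (j in cols) {
      u <- rank(X[, j], ties.method = "average") / (N + 1)
      X[, j] <- ggd_quantile(u, kappa, alpha)
    }
  }

  q <- config$lod_quantile
  thresholds <- apply(X, 2, stats::quantile, probs = q, names = FALSE)
  mask <- sweep(X, 2, thresholds, "<")
  X_premask <- X
  X[mask] <- NA_real_

  dataset$X <- X
  dataset$X_premask <- X_premask
  dataset$missing_mask <- mask
  dataset$outlier_flags <- list(biological = bio, technical = tech)
  dataset$lod_thresholds <- thresholds
  dataset$ggd_params <- ggd_params
  dataset$scenario <- "realistic"
  dataset$config <- config
  dataset
}

#' Simulate one study dataset under a configuration
#'
#' Runs [simulate_baseline()] and, when `config$scenario` is
#' `"realistic"`, also [apply_realistic_transforms()].
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when given, the draw is fully
#'   reproducible.
#' @return A `"simulated_dataset"`.
#' @export
simulate_study <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- simulate_baseline(config)
  if (config$scenario == "realistic") ds <- apply_realistic_transforms(ds, config)
  ds
}

#' Half-minimum imputation of limit-of-detection missingness
#'
#' Replaces each missing entry by half the observed minimum of its
#' metabolite - the conventional stand-in for an abundance below the
#' limit of detection. Metabolites with no observed values are dropped
#' and reported. The per-column fill values are returned so that new
#' (e.g. test) data can be imputed with training-derived values via
#' `apply_imputation()`.
#'
#' @param X numeric matrix, possibly with `NA` entries.
#' @return List with `X` (complete matrix, all-missing columns removed),
#'   `fill` (named vector of imputation values for the kept columns) and
#'   `dropped` (indices of all-missing columns).
#' @export
impute_missing <- function(X) {
  stopifnot(is.matrix(X))
  all_na <- apply(X, 2, function(v) all(is.na(v)))
  dropped <- which(all_na)
  if (length(dropped)) {
    warning(sprintf("dropping %d metabolite(s) with no observed values",
                    length(dropped)), call. = FALSE)
    X <- X[, !all_na, drop = FALSE]
  }
  fill <- apply(X, 2, function(v) min(v, na.rm = TRUE) / 2)
  for (j in which(colSums(is.na(X)) > 0)) {
    X[is.na(X[, j]), j] <- fill[j]
  }
  list(X = X, fill = fill, dropped = dropped)
}

#' @rdname impute_missing
#' @param fill named vector of fill values from [impute_missing()].
#' @export
apply_imputation <- function(X, fill) {
  stopifnot(is.matrix(X), ncol(X) == length(fill))
  for (j in which(colSums(is.na(X)) > 0)) {
    X[is.na(X[, j]), j] <- fill[j]
  }
  X
}
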