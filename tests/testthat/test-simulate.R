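test_that("default configuration gives 40 blocks of 25 metabolites", {
  cfg <- sim_config()
  expect_identical(cfg$n_blocks * cfg$block_size, 1000L)
  set.seed(1)
  ds <- simulate_baseline(cfg)
  expect_identical(dim(ds$X), c(120L, 1000L))
  expect_identical(length(unique(ds$block_of)), 40L)
  expect_false(anyNA(ds$X))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_phenotypes = 1), "phenotypes")
  expect_error(sim_config(eta = 0), "eta")
  expect_error(sim_config(lod_quantile = 0.7), "lod_quantile")
  expect_error(sim_config(n_samples = 20, min_per_class = 10), "n_samples")
})

test_that("reference phenotype has zero means; comparators perturb 1-5 blocks", {
  cfg <- sim_config()
  set.seed(5)
  for (i in 1:10) {
    tr <- draw_perturbed_means(cfg)
    expect_equal(tr$mu[1, ], rep(0, 1000))
    for (g in 2:3) {
      expect_gte(length(tr$perturbed_blocks[[g]]), 1)
      expect_lte(length(tr$perturbed_blocks[[g]]), 5)
    }
  }
})

test_that("block effect sizes average to the exponential mean of 2", {
  cfg <- sim_config()
  set.seed(6)
  th <- unlist(replicate(2000, abs(draw_perturbed_means(cfg)$theta[[2]])))
  expect_equal(mean(th), 2, tolerance = 0.1)
})

test_that("metabolite means outside perturbed blocks match across phenotypes", {
  cfg <- sim_config()
  set.seed(8)
  tr <- draw_perturbed_means(cfg)
  pert_cols <- unlist(lapply(unlist(tr$perturbed_blocks), function(b)
    ((b - 1) * 25 + 1):(b * 25)))
  quiet <- setdiff(seq_len(1000), pert_cols)
  expect_true(all(tr$mu[, quiet] == 0))
})

test_that("baseline allocation is balanced; realistic respects the floor", {
  cfg <- sim_config()
  expect_identical(draw_phenotype_allocation(cfg), rep(40L, 3))
  cfgr <- sim_config(scenario = "realistic")
  set.seed(9)
  for (i in 1:20) {
    counts <- draw_phenotype_allocation(cfgr)
    expect_identical(sum(counts), 120L)
    expect_gte(min(counts), 10L)
  }
})

test_that("symmetric Dirichlet allocation is balanced in expectation, and a
           heavy first concentration dominates", {
  set.seed(10)
  cfg1 <- sim_config(scenario = "realistic", dirichlet_alpha = c(1, 1, 1),
                     min_per_class = 1L)
  props <- rowMeans(replicate(2000, draw_phenotype_allocation(cfg1) / 120))
  expect_equal(props, rep(1 / 3, 3), tolerance = 0.03)
  cfg2 <- sim_config(scenario = "realistic", dirichlet_alpha = c(8, 1, 1),
                     min_per_class = 1L)
  counts <- rowMeans(replicate(500, draw_phenotype_allocation(cfg2)))
  expect_true(all(counts[1] > counts[2:3]))
})

test_that("identity-covariance baseline columns are standard normal", {
  cfg <- sim_config(n_blocks = 1L, block_size = 10L, n_samples = 4000L,
                    eta = 1e8, perturb_range = c(1L, 1L))  # huge eta: identity
  set.seed(11)
  ds <- simulate_baseline(cfg)
  ref <- ds$y == "P1"
  expect_equal(unname(colMeans(ds$X[ref, ])), rep(0, 10), tolerance = 0.15)
  expect_equal(unname(apply(ds$X[ref, ], 2, sd)), rep(1, 10), tolerance = 0.1)
})

test_that("large-sample correlation of one block approaches its target", {
  cfg <- sim_config(n_blocks = 1L, block_size = 8L, n_samples = 5000L,
                    n_phenotypes = 2L, dirichlet_alpha = c(1, 1),
                    perturb_range = c(1L, 1L))
  set.seed(12)
  ds <- simulate_baseline(cfg)
  ref <- ds$y == "P1"
  emp <- cor(ds$X[ref, ])
  expect_lt(max(abs(emp - ds$correlations[[1]])), 0.08)
})

test_that("cross-block sample correlation vanishes with sample size", {
  cfg <- sim_config(n_blocks = 2L, block_size = 5L, n_samples = 4000L,
                    perturb_range = c(1L, 2L))
  set.seed(13)
  ds <- simulate_baseline(cfg)
  ref <- ds$y == "P1"
  cross <- cor(ds$X[ref, 1:5], ds$X[ref, 6:10])
  expect_lt(max(abs(cross)), 0.08)
})

test_that("GGD quantile matches closed forms and is continuous at kappa 0", {
  expect_equal(ggd_quantile(0.5, 0.7, 3), 0)
  expect_equal(ggd_quantile(pnorm(1), 0, 2), 2)
  expect_equal(ggd_quantile(pnorm(1), 0.5, 1), 0.7869387, tolerance = 1e-6)
  expect_equal(ggd_quantile(0.3, 1e-9, 1), ggd_quantile(0.3, 0, 1),
               tolerance = 1e-6)
  expect_error(ggd_quantile(1.2, 0, 1), "inside")
  expect_error(ggd_quantile(0.5, 0, -1), "positive")
})

test_that("realistic transform preserves within-block rank correlations
           before masking", {
  cfg <- smoke_config("realistic", lod_quantile = 0, outlier_rates = c(0, 0))
  set.seed(14)
  base <- simulate_baseline(cfg)
  real <- apply_realistic_transforms(base, cfg)
  expect_false(anyNA(real$X))
  sp_base <- cor(base$X[, 1:10], method = "spearman")
  sp_real <- cor(real$X[, 1:10], method = "spearman")
  expect_equal(sp_real, sp_base, tolerance = 1e-12)
})

test_that("LOD masking censors about q of each metabolite, always below the
           threshold", {
  cfg <- smoke_config("realistic", lod_quantile = 0.1)
  set.seed(15)
  ds <- simulate_study(cfg)
  miss_frac <- colMeans(ds$missing_mask)
  expect_equal(mean(miss_frac), 0.1, tolerance = 0.02)
  # every masked pre-mask value lies below its metabolite threshold
  for (j in which(colSums(ds$missing_mask) > 0)) {
    expect_true(all(ds$X_premask[ds$missing_mask[, j], j] <
                      ds$lod_thresholds[j]))
  }
  # and every observed value does not
  expect_true(all(ds$X[!is.na(ds$X)] >=
                    rep(ds$lod_thresholds, each = nrow(ds$X))[!is.na(ds$X)]))
})

test_that("outlier flags appear at the configured Bernoulli rates", {
  cfg <- smoke_config("realistic", outlier_rates = c(0.05, 0.02),
                      n_samples = 90L)
  set.seed(16)
  bio <- c(); tech <- c()
  for (i in 1:20) {
    ds <- simulate_study(cfg)
    bio <- c(bio, mean(ds$outlier_flags$biological))
    tech <- c(tech, mean(ds$outlier_flags$technical))
  }
  expect_lt(abs(mean(bio) - 0.05), 0.005)
  expect_lt(abs(mean(tech) - 0.02), 0.002)
})

test_that("simulation is bit-reproducible from (config, seed)", {
  cfg <- smoke_config("realistic")
  a <- simulate_study(cfg, seed = 99)
  b <- simulate_study(cfg, seed = 99)
  expect_identical(a, b)
})

test_that("half-minimum imputation fills below the LOD and drops empty
           columns", {
  X <- matrix(c(4, 8, NA, 2, NA, NA, 1, 1, 1), 3, 3)
  expect_warning(imp <- impute_missing(cbind(X, NA)), "no observed")
  expect_identical(imp$dropped, 4L)
  expect_equal(imp$X[3, 1], 2)      # half of observed min 4
  expect_equal(imp$X[c(2, 3), 2], c(1, 1))
  expect_equal(unname(imp$fill), c(2, 1, 0.5))
  # unchanged when complete
  Xc <- matrix(rnorm(12), 3, 4)
  expect_equal(impute_missing(Xc)$X, Xc)
})

test_that("imputed values are half the observed minimum and stay below the
           LOD threshold for nonnegative metabolites", {
  cfg <- smoke_config("realistic", lod_quantile = 0.2)
  set.seed(17)
  ds <- simulate_study(cfg)
  imp <- impute_missing(ds$X)
  expect_length(imp$dropped, 0)
  obs_min <- apply(ds$X, 2, min, na.rm = TRUE)
  masked <- ds$missing_mask
  filled <- imp$X[masked]
  expect_equal(filled, unname(rep(obs_min / 2, each = nrow(ds$X))[masked]))
  # half-minimum stays below the censoring threshold whenever the
  # observed minimum is nonnegative (abundance-scale data); a negative
  # minimum halves toward zero instead
  pos <- obs_min >= 0
  if (any(pos & colSums(masked) > 0)) {
    sel <- masked & rep(pos, each = nrow(ds$X))
    thr <- rep(ds$lod_thresholds, each = nrow(ds$X))
    expect_true(all(imp$X[sel] <= thr[sel]))
  }
})
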