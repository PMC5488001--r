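# Shared fixtures, generated in code under fixed seeds.

# small three-class dataset with a strong mean shift in the first
# metabolites of class B and a weaker one in class C
make_shifted_classes <- function(n_per = 20L, p = 40L, shift = 2,
                                 seed = 101L) {
  set.seed(seed)
  y <- factor(rep(c("A", "B", "C"), each = n_per))
  X <- matrix(rnorm(3 * n_per * p), 3 * n_per, p)
  b_cols <- seq_len(min(5L, ceiling(p / 2)))
  c_cols <- seq(max(b_cols) + 1L, min(10L, p))
  X[y == "B", b_cols] <- X[y == "B", b_cols] + shift
  X[y == "C", c_cols] <- X[y == "C", c_cols] + shift / 2
  list(X = X, y = y)
}

# fixed 8 x 5 predictor block and 8 x 3 indicator for PLS oracles
make_pls_fixture <- function(seed = 7L) {
  set.seed(seed)
  X <- matrix(rnorm(40), 8, 5)
  y <- factor(c("a", "a", "a", "b", "b", "b", "c", "c"))
  list(X = X, y = y)
}

# a classifier that ignores features and returns fixed probabilities
uniform_classifier <- function(X_train, y_train, X_new) {
  G <- nlevels(droplevels(as.factor(y_train)))
  matrix(1 / G, nrow(X_new), G,
         dimnames = list(NULL, levels(droplevels(as.factor(y_train)))))
}

oracle_classifier <- function(X_train, y_train, X_new, truth) {
  # probability 1 on the true class of each new sample (test plumbing)
  lv <- levels(droplevels(as.factor(y_train)))
  P <- matrix(0, nrow(X_new), length(lv), dimnames = list(NULL, lv))
  P[cbind(seq_len(nrow(X_new)), as.integer(truth))] <- 1
  P
}

smoke_config <- function(scenario = "baseline", ...) {
  # reduced problem size for fast unit tests (full size is exercised in
  # the acceptance suite); dots override the smoke defaults
  args <- utils::modifyList(
    list(n_blocks = 8L, block_size = 10L, n_samples = 60L,
         scenario = scenario),
    list(...))
  do.call(sim_config, args)
}
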