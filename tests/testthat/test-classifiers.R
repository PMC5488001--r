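test_that("naive Bayes matches the hand-worked two-class posterior", {
  # class A values {-1, 1} (MLE mean 0, var 1), class B {1, 3} (mean 2,
  # var 1), equal priors; at x = 0 the posterior of A is 1/(1 + e^-2)
  X <- matrix(c(-1, 1, 1, 3), 4, 1)
  y <- factor(c("A", "A", "B", "B"))
  P <- fit_predict_nb(X, y, matrix(0))
  expect_equal(unname(P[1, "A"]), 1 / (1 + exp(-2)), tolerance = 1e-12)
})

test_that("identical class-conditionals return the priors", {
  X <- matrix(rep(c(1, 2, 3), 3), 9, 1)
  y <- factor(c(rep("A", 6), rep("B", 3)))
  X[y == "B", 1] <- c(1, 2, 3)
  X[y == "A", 1] <- rep(c(1, 2, 3), 2)
  P <- fit_predict_nb(X, y, matrix(c(0, 5), 2, 1))
  expect_equal(P[, "A"], rep(2 / 3, 2), tolerance = 1e-9)
})

test_that("naive Bayes rows sum to one and survive constant-within-class
           metabolites", {
  fx <- make_shifted_classes()
  Xc <- cbind(fx$X, ifelse(fx$y == "A", 1, 0))  # constant within class
  P <- fit_predict_nb(Xc, fx$y, Xc[1:10, ])
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
  expect_true(all(is.finite(log(pmax(P, 1e-300)))))
})

test_that("naive Bayes is invariant to metabolite permutation", {
  fx <- make_shifted_classes()
  set.seed(41)
  perm <- sample(ncol(fx$X))
  Xn <- fx$X[1:5, ]
  expect_equal(fit_predict_nb(fx$X, fx$y, Xn),
               fit_predict_nb(fx$X[, perm], fx$y, Xn[, perm]),
               tolerance = 1e-9)
})

test_that("k = 1 puts probability one on the nearest neighbour's class", {
  X <- matrix(c(0, 0, 10, 10, 20, 20), 3, 2, byrow = TRUE)
  y <- factor(c("A", "B", "C"))
  P <- fit_predict_knn(X, y, matrix(c(1, 1), 1), k = 1)
  expect_equal(P[1, ], c(A = 1, B = 0, C = 0))
})

test_that("k-NN probabilities equal hand-counted neighbourhood fractions", {
  # five points in the plane; query at the origin; the 3 nearest are
  # (0,1) A, (1,0) B, (-1,-1) B
  X <- rbind(c(0, 1), c(1, 0), c(-1, -1), c(3, 0), c(0, -4))
  y <- factor(c("A", "B", "B", "A", "B"))
  P <- fit_predict_knn(X, y, matrix(c(0, 0), 1), k = 3)
  expect_equal(P[1, ], c(A = 1 / 3, B = 2 / 3))
})

test_that("distance ties at the k-th neighbour resolve to the lowest
           training index", {
  X <- matrix(c(1, -1, 1), 3, 1)  # rows 1 and 3 equidistant from 0...
  y <- factor(c("A", "B", "C"))
  P <- fit_predict_knn(X, y, matrix(0), k = 2)
  # neighbours must be rows 1 (A) and 2 (B); the tie between rows 1 and
  # 3 goes to row 1
  expect_equal(P[1, ], c(A = 0.5, B = 0.5, C = 0))
})

test_that("k-NN probabilities are multiples of 1/k", {
  fx <- make_shifted_classes()
  set.seed(42)
  P <- fit_predict_knn(fx$X, fx$y, matrix(rnorm(8 * 40), 8, 40), k = 7)
  expect_equal(P * 7, round(P * 7), tolerance = 1e-12)
})

test_that("k-NN is invariant under a rigid rotation of all coordinates", {
  set.seed(43)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- factor(rep(c("A", "B", "C"), 10))
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))  # random orthogonal matrix
  Xn <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(fit_predict_knn(X, y, Xn, k = 5),
               fit_predict_knn(X %*% Q, y, Xn %*% Q, k = 5),
               tolerance = 1e-9)
})

test_that("SVM separates a separable toy problem and returns a simplex", {
  set.seed(44)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  y <- factor(rep(c("A", "B"), each = 20))
  P <- fit_predict_svm(X, y, X, gamma = 0.5)
  expect_equal(misclassification_rate(y, P), 0)
  expect_equal(rowSums(P), rep(1, 40), tolerance = 1e-6)
  expect_error(fit_predict_svm(X, factor(rep("A", 40)), X), "two classes")
  expect_error(fit_predict_svm(X, y, X, gamma = -1), "positive")
})

test_that("the Gaussian kernel decays with squared distance at rate gamma", {
  # the decision value of a one-support-vector-per-class toy tracks the
  # kernel; verify the kernel contract directly on the fitted machine
  gamma <- 0.3
  K <- function(x, xp) exp(-gamma * sum((x - xp)^2))
  expect_equal(K(c(1, 2), c(1, 2)), 1)
  x <- c(0, 0)
  d <- seq(0.5, 3, by = 0.5)
  vals <- sapply(d, function(dd) K(x, c(dd, 0)))
  expect_equal(vals, exp(-gamma * d^2))
})

test_that("Random Forest probabilities are vote fractions in multiples of
           1/1000", {
  fx <- make_shifted_classes(n_per = 10L, p = 8L)
  set.seed(45)
  P <- fit_predict_rf(fx$X, fx$y, fx$X[1:6, ], mtry = 3)
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-9)
  expect_equal(P * 1000, round(P * 1000), tolerance = 1e-9)
  expect_error(fit_predict_rf(fx$X, fx$y, fx$X, mtry = 100), "mtry")
  expect_error(fit_predict_rf(fx$X, factor(rep("A", 30)), fx$X),
               "two classes")
})

test_that("RF and NNet predictions are reproducible under a fixed seed", {
  fx <- make_shifted_classes(n_per = 10L, p = 8L)
  run <- function() {
    set.seed(46)
    list(rf = fit_predict_rf(fx$X, fx$y, fx$X[1:4, ], mtry = 3),
         nn = fit_predict_nnet(fx$X, fx$y, fx$X[1:4, ], 1, 15))
  }
  expect_identical(run(), run())
})

test_that("a one-hidden-layer RPROP network solves an XOR-style problem", {
  set.seed(47)
  n <- 120
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  y <- factor(ifelse(X[, 1] * X[, 2] > 0, "pos", "neg"))
  P <- fit_predict_nnet(X, y, X, n_hidden_layers = 1, nodes_per_layer = 15,
                        max_epochs = 300)
  expect_lt(misclassification_rate(y, P), 0.05)
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-6)
})

test_that("two-hidden-layer networks train and predict a simplex", {
  fx <- make_shifted_classes(n_per = 10L, p = 8L)
  set.seed(48)
  P <- fit_predict_nnet(fx$X, fx$y, fx$X[1:5, ], n_hidden_layers = 2,
                        nodes_per_layer = 20)
  expect_identical(dim(P), c(5L, 3L))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_error(fit_predict_nnet(fx$X, fx$y, fx$X, n_hidden_layers = 3),
               "1 or 2")
})

test_that("every classifier honours the shared fit/predict contract", {
  fx <- make_shifted_classes(n_per = 12L, p = 10L)
  Xn <- fx$X[1:4, ]
  for (cl in benchmark_classifiers()) {
    set.seed(49)
    P <- classifier_function(cl)(fx$X, fx$y, Xn)
    expect_identical(dim(P), c(4L, 3L))
    expect_identical(colnames(P), levels(fx$y))
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
    expect_true(all(P >= 0 & P <= 1))
  }
})
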