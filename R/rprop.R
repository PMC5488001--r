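# Feedforward network trained by resilient backpropagation (RPROP).
#
# Small, dense, full-batch implementation: logistic hidden units (one or
# two layers), linear output passed through softmax, cross-entropy
# objective. RPROP adapts a per-weight step size from the sign of the
# gradient only (increase by 1.2 on sign agreement, halve on sign flip,
# iRPROP- variant: zero the gradient after a flip), which makes training
# insensitive to the gradient magnitude.

logistic <- function(z) 1 / (1 + exp(-z))

nnet_init <- function(sizes) {
  # sizes: c(p, hidden..., G); weights U(-r, r) with r = 1/sqrt(fan-in)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    r <- 1 / sqrt(sizes[l])
    list(W = matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                    sizes[l], sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

nnet_forward <- function(layers, X) {
  acts <- list(X)
  A <- X
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- A %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(A))
    A <- if (l < L) logistic(Z) else Z  # linear output, softmax later
    acts[[l + 1L]] <- A
  }
  acts
}

nnet_gradients <- function(layers, acts, Yind) {
  L <- length(layers)
  n <- nrow(Yind)
  P <- softmax_rows(acts[[L + 1L]])
  delta <- (P - Yind) / n  # d(mean CE)/d(output activations)
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      A <- acts[[l]]
      delta <- (delta %*% t(layers[[l]]$W)) * A * (1 - A)
    }
  }
  grads
}

rprop_train <- function(X, Yind, hidden, max_epochs = 150L,
                        delta0 = 0.1, delta_min = 1e-6, delta_max = 50,
                        eta_plus = 1.2, eta_minus = 0.5,
                        reltol = 1e-6) {
  sizes <- c(ncol(X), hidden, ncol(Yind))
  layers <- nnet_init(sizes)
  steps <- lapply(layers, function(l)
    list(W = matrix(delta0, nrow(l$W), ncol(l$W)),
         b = rep(delta0, length(l$b))))
  prev <- lapply(layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b))))
  loss_old <- Inf
  stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    acts <- nnet_forward(layers, X)
    P <- softmax_rows(acts[[length(layers) + 1L]])
    loss <- -mean(log(pmax(P[Yind == 1], 1e-15)))
    if (!is.finite(loss)) return(NULL)  # diverged; caller retries
    if (loss_old - loss < reltol * max(loss_old, 1)) stall <- stall + 1L
    else stall <- 0L
    if (stall >= 10L) break
    loss_old <- loss
    grads <- nnet_gradients(layers, acts, Yind)
    for (l in seq_along(layers)) {
      for (nm in c("W", "b")) {
        g <- grads[[l]][[nm]]
        s <- g * prev[[l]][[nm]]
        st <- steps[[l]][[nm]]
        st[s > 0] <- pmin(st[s > 0] * eta_plus, delta_max)
        st[s < 0] <- pmax(st[s < 0] * eta_minus, delta_min)
        g[s < 0] <- 0  # iRPROP-: skip update after a sign flip
        layers[[l]][[nm]] <- layers[[l]][[nm]] - sign(g) * st
        steps[[l]][[nm]] <- st
        prev[[l]][[nm]] <- g
      }
    }
  }
  list(layers = layers, loss = loss_old)
}
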