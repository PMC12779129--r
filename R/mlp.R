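# Small feed-forward network (two tanh hidden layers, full-batch Adam).
# Stands in for the "deep learning" learner family; the sigmoid output head
# is used for binary targets, a linear head otherwise.

mlp_init <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0, 1 / sqrt(sizes[i])),
                    sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

mlp_forward <- function(layers, x) {
  a <- list(x)
  L <- length(layers)
  for (i in seq_len(L)) {
    z <- sweep(a[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    a[[i + 1]] <- if (i < L) tanh(z) else z
  }
  a
}

mlp_fit <- function(x, y, hidden = c(16L, 8L), epochs = 150L, lr = 0.01,
                    l2 = 1e-4, binary = TRUE) {
  n <- nrow(x)
  layers <- mlp_init(ncol(x), hidden)
  L <- length(layers)
  m <- v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    a <- mlp_forward(layers, x)
    f <- a[[L + 1]][, 1]
    # gradient of mean loss wrt pre-activation output
    delta <- matrix(if (binary) (inv_logit(f) - y) / n else (f - y) / n, ncol = 1)
    for (i in rev(seq_len(L))) {
      gW <- crossprod(a[[i]], delta) + l2 * layers[[i]]$W
      gb <- colSums(delta)
      if (i > 1) delta <- (delta %*% t(layers[[i]]$W)) * (1 - a[[i]]^2)
      m[[i]]$W <- b1 * m[[i]]$W + (1 - b1) * gW
      m[[i]]$b <- b1 * m[[i]]$b + (1 - b1) * gb
      v[[i]]$W <- b2 * v[[i]]$W + (1 - b2) * gW^2
      v[[i]]$b <- b2 * v[[i]]$b + (1 - b2) * gb^2
      mhW <- m[[i]]$W / (1 - b1^ep); vhW <- v[[i]]$W / (1 - b2^ep)
      mhb <- m[[i]]$b / (1 - b1^ep); vhb <- v[[i]]$b / (1 - b2^ep)
      layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
      layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(layers = layers, binary = binary)
}

mlp_predict <- function(fit, x) {
  f <- mlp_forward(fit$layers, x)[[length(fit$layers) + 1]][, 1]
  if (fit$binary) inv_logit(f) else f
}
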