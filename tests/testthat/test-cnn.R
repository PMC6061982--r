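# cnn: activations, dropout, layer forward oracles, full forward/backward.

test_that("relu clamps negatives elementwise", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  m <- matrix(c(-1, 2, 0, -3), 2)
  expect_equal(relu(m), matrix(c(0, 2, 0, 0), 2))
})

test_that("dropout implements the inverted mean network", {
  x <- rep(1, 1e5)
  expect_identical(dropout(x, 0, "train"), x)
  expect_identical(dropout(x, 0.5, "inference"), x)
  expect_error(dropout(x, 1, "train"), "rate")

  set.seed(1)
  y <- dropout(x, 0.5, "train")
  frac <- mean(y == 0)
  expect_lt(abs(frac - 0.5), 0.01)

  # Monte-Carlo mean-network property: E[dropout(x)] = x within 2%
  set.seed(2)
  v <- c(2, -1, 0.5, 3, -2)
  acc <- numeric(5)
  for (i in 1:10000) acc <- acc + dropout(v, 0.5, "train")
  expect_lt(max(abs(acc / 10000 - v) / abs(v)), 0.02)
})

test_that("conv_forward matches a four-nested-loop oracle", {
  # selection case: h=1, one-hot kernel picks one column of each sub-vector
  A <- matrix(rnorm(24), 4, 6)
  K <- list(matrix(c(0, 1), 1))       # selects column 2 of each 2-wide slot
  cv <- conv_forward(A, K, bias = 0, stride = 2, activation = "identity")
  expect_equal(cv$z[, 1, 1], A[, 2])
  expect_equal(cv$z[, 2, 1], A[, 4])
  expect_equal(cv$z[, 3, 1], A[, 6])

  # all-zero kernel with ReLU -> all-zero maps
  cv0 <- conv_forward(A, list(matrix(0, 1, 2)), bias = 0, stride = 2,
                      activation = "relu")
  expect_true(all(cv0$a == 0))

  # 100 random instances vs brute force
  set.seed(77)
  for (rep in 1:100) {
    d <- sample(2:4, 1); L <- sample(3:7, 1); h <- sample(1:2, 1)
    nk <- sample(1:3, 1)
    A <- matrix(rnorm(L * 4 * d), L, 4 * d)
    Ks <- lapply(seq_len(nk), function(i) matrix(rnorm(h * d), h, d))
    bias <- rnorm(nk)
    cv <- conv_forward(A, Ks, bias, stride = d, activation = "identity")
    P <- L - h + 1
    for (ki in seq_len(nk)) for (q in 1:4) for (p in seq_len(P)) {
      s <- bias[ki]
      for (i in seq_len(h)) for (j in seq_len(d))
        s <- s + A[p + i - 1, (q - 1) * d + j] * Ks[[ki]][i, j]
      expect_lt(abs(cv$z[p, q, ki] - s), 1e-10)
    }
  }
  expect_error(conv_forward(matrix(0, 2, 4), list(matrix(0, 3, 2)), 0, 2),
               "height")
})

test_that("pool_forward keeps the k largest in original order", {
  a <- array(c(1, 3, 2), c(3, 1, 1))
  expect_equal(as.numeric(pool_forward(a, 1, 1, 0, "identity")$out), 3)
  expect_equal(as.numeric(pool_forward(a, 2, 1, 0, "identity")$out),
               c(3, 2))
  # beta = 0 -> f(bias) everywhere
  expect_equal(as.numeric(pool_forward(a, 2, 0, -1.5, "identity")$out),
               c(-1.5, -1.5))
  expect_error(pool_forward(a, 4, 1, 0), "exceeds")

  # sort-and-reorder oracle over random maps
  set.seed(31)
  for (rep in 1:100) {
    P <- sample(3:9, 1); k <- sample(seq_len(P), 1)
    v <- rnorm(P)
    out <- as.numeric(pool_forward(array(v, c(P, 1, 1)), k, 1, 0,
                                   "identity")$out)
    sel <- sort(order(v, decreasing = TRUE)[seq_len(k)])
    expect_equal(out, v[sel])
    # order preserving: output is a subsequence of the input
    expect_true(all(diff(match(out, v)) > 0) || k == 1)
  }
})

test_that("pooling is permutation-covariant along the feature-map axis", {
  set.seed(4)
  a <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  perm <- c(3, 1, 2)
  p1 <- pool_forward(a[, perm, , drop = FALSE], 2, c(1, 1), c(0, 0),
                     "identity")$out
  p2 <- pool_forward(a, 2, c(1, 1), c(0, 0), "identity")$out
  expect_equal(p1, p2[, perm, , drop = FALSE])
})

test_that("fc_forward matches direct matrix multiplication", {
  x <- c(1, -2, 0.5)
  W0 <- matrix(0, 2, 3)
  expect_equal(fc_forward(x, W0, c(1, -1), "identity")$a, c(1, -1))
  expect_equal(fc_forward(x, diag(3), rep(0, 3), "identity")$a, x)
  set.seed(12)
  W <- matrix(rnorm(12), 4, 3); b <- rnorm(4)
  expect_lt(max(abs(fc_forward(x, W, b, "identity")$a -
                      as.numeric(W %*% x + b))), 1e-12)
  expect_error(fc_forward(c(1, 2), W, b), "mismatch")
})

test_that("cnn_forward is deterministic in inference mode", {
  cfg <- cnn_config(L = 4, d = 2,
                    stages = list(list(n_kernels = 2, h = 2, pool_k = 2)),
                    fc = c(4, 3), dropout_rate = 0.5)
  par <- cnn_init(cfg, seed = 5)
  A <- matrix(rnorm(4 * 8), 4, 8)
  y1 <- cnn_forward(A, par, cfg)$y
  y2 <- cnn_forward(A, par, cfg)$y
  expect_identical(y1, y2)
  expect_length(y1, 3L)
  # zero input, zero biases -> y = sigmoid(fc chain of zeros)
  par0 <- par
  for (s in seq_along(par0$conv)) {
    par0$conv[[s]]$bias[] <- 0; par0$conv[[s]]$pool_bias[] <- 0
  }
  for (l in seq_along(par0$fc)) par0$fc[[l]]$b[] <- 0
  y0 <- cnn_forward(matrix(0, 4, 8), par0, cfg)$y
  expect_equal(y0, rep(0.5, 3))      # relu(0)=0 chain, final sigmoid(0)
})

test_that("tiny full forward matches a straight-line hand computation", {
  cfg <- cnn_config(L = 4, d = 2,
                    stages = list(list(n_kernels = 1, h = 2, pool_k = 1)),
                    fc = c(2), dropout_rate = 0)
  par <- cnn_init(cfg, seed = 9)
  A <- matrix(seq(-0.8, 0.75, length.out = 32), 4, 8)
  y <- cnn_forward(A, par, cfg)$y
  # by hand: conv (3 positions x 4 offsets), relu, 1-max pool per offset,
  # beta/bias, relu, flatten (4), fc sigmoid
  K <- par$conv[[1]]$kernels[[1]]
  z <- matrix(0, 3, 4)
  for (p in 1:3) for (q in 1:4)
    z[p, q] <- sum(A[p:(p + 1), (2 * q - 1):(2 * q)] * K) +
      par$conv[[1]]$bias
  a <- pmax(z, 0)
  pooled <- apply(a, 2, max) * par$conv[[1]]$beta + par$conv[[1]]$pool_bias
  flat <- pmax(pooled, 0)
  expect_equal(y,
               as.numeric(1 / (1 + exp(-(par$fc[[1]]$W %*% flat +
                                           par$fc[[1]]$b)))))
})

test_that("backward pass survives central finite-difference checks", {
  set.seed(55)
  for (rep in 1:3) {
    cfg <- cnn_config(L = 5, d = 2,
                      stages = list(list(n_kernels = 2, h = 2, pool_k = 2)),
                      fc = c(4, 3), dropout_rate = 0)
    par <- cnn_init(cfg, seed = rep)
    # move biases and gains off their exact-zero/one initialisation so no
    # ReLU pre-activation sits exactly on the kink (the finite-difference
    # quotient is one-sided there while relu'(0) = 0 by convention)
    par$conv[[1]]$bias <- rnorm(2, sd = 0.3)
    par$conv[[1]]$pool_bias <- rnorm(2, sd = 0.3)
    par$conv[[1]]$beta <- 1 + rnorm(2, sd = 0.2)
    par$fc[[1]]$b <- rnorm(4, sd = 0.3)
    par$fc[[2]]$b <- rnorm(3, sd = 0.3)
    A <- matrix(rnorm(5 * 8), 5, 8)
    r <- rnorm(3)
    fw <- cnn_forward(A, par, cfg)
    g <- cnn_backward(r, fw$cache, par, cfg)
    loss_at <- function(p) sum(cnn_forward(A, p, cfg)$y * r)

    checks <- list(
      list(get = function(p) as.numeric(p$conv[[1]]$kernels[[1]]),
           set = function(p, v) { p$conv[[1]]$kernels[[1]][] <- v; p },
           an = as.numeric(g$conv[[1]]$kernels[[1]])),
      list(get = function(p) p$conv[[1]]$bias,
           set = function(p, v) { p$conv[[1]]$bias <- v; p },
           an = g$conv[[1]]$bias),
      list(get = function(p) p$conv[[1]]$beta,
           set = function(p, v) { p$conv[[1]]$beta <- v; p },
           an = g$conv[[1]]$beta),
      list(get = function(p) p$conv[[1]]$pool_bias,
           set = function(p, v) { p$conv[[1]]$pool_bias <- v; p },
           an = g$conv[[1]]$pool_bias),
      list(get = function(p) as.numeric(p$fc[[1]]$W),
           set = function(p, v) { p$fc[[1]]$W[] <- v; p },
           an = as.numeric(g$fc[[1]]$W)),
      list(get = function(p) as.numeric(p$fc[[2]]$W),
           set = function(p, v) { p$fc[[2]]$W[] <- v; p },
           an = as.numeric(g$fc[[2]]$W)),
      list(get = function(p) p$fc[[2]]$b,
           set = function(p, v) { p$fc[[2]]$b <- v; p },
           an = g$fc[[2]]$b))
    for (ch in checks) {
      num <- numeric_grad(function(v) loss_at(ch$set(par, v)),
                          ch$get(par))
      expect_lt(rel_err(num, ch$an), 1e-4)
    }
    # gradient w.r.t. the input matrix
    numA <- numeric_grad(function(v) {
      Av <- A; Av[] <- v; loss_at_A <- sum(cnn_forward(Av, par, cfg)$y * r)
    }, as.numeric(A))
    expect_lt(rel_err(numA, as.numeric(g$dA)), 1e-4)
  }
})

test_that("two-stage configurations are shape-consistent end to end", {
  cfg <- cnn_config(L = 8, d = 2,
                    stages = list(list(n_kernels = 2, h = 2, pool_k = 4),
                                  list(n_kernels = 3, h = 2, pool_k = 2)),
                    fc = c(5, 2), dropout_rate = 0)
  par <- cnn_init(cfg, seed = 2)
  A <- matrix(rnorm(8 * 8), 8, 8)
  fw <- cnn_forward(A, par, cfg)
  expect_length(fw$y, 2L)
  g <- cnn_backward(c(1, -1), fw$cache, par, cfg)
  expect_equal(dim(g$dA), dim(A))
  # finite-difference spot check on the stage-2 kernel
  r <- c(1, -1)
  num <- numeric_grad(function(v) {
    p <- par; p$conv[[2]]$kernels[[1]][] <- v
    sum(cnn_forward(A, p, cfg)$y * r)
  }, as.numeric(par$conv[[2]]$kernels[[1]]))
  expect_lt(rel_err(num, as.numeric(g$conv[[2]]$kernels[[1]])), 1e-4)
})

test_that("cnn_config validates shapes", {
  expect_error(cnn_config(3, 2, stages = list(list(n_kernels = 1, h = 5,
                                                   pool_k = 1))),
               "exceeds")
  expect_error(cnn_config(4, 2, stages = list(list(n_kernels = 1, h = 2,
                                                   pool_k = 9))),
               "pool")
})
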