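# hierarchy: label clustering, coarse/fine losses, gated prediction, and
# the flat two-node baseline.

test_that("cluster_labels is deterministic and recovers planted blobs", {
  set.seed(20)
  emb1 <- matrix(rnorm(5 * 3), 5, 3,
                 dimnames = list(paste0("L", 1:5), NULL))
  p1 <- cluster_labels(emb1, 1, seed = 2)
  expect_true(all(p1$assignment == 1L))
  expect_error(cluster_labels(emb1, 6, seed = 2), "C=6")

  # two planted blobs, centers 10 apart, noise 0.1
  centers <- rbind(c(5, 0, 0), c(-5, 0, 0))
  planted <- rep(1:2, each = 8)
  emb <- centers[planted, ] + matrix(rnorm(16 * 3, sd = 0.1), 16)
  rownames(emb) <- sprintf("L%02d", 1:16)
  part <- cluster_labels(emb, 2, seed = 3)
  expect_equal(adjusted_rand_index(part$assignment, planted), 1.0)
  part2 <- cluster_labels(emb, 2, seed = 3)
  expect_identical(part$assignment, part2$assignment)
})

test_that("coarse_loss evaluates the stated instance and its gradient", {
  # engineered weights giving f = (1, 0) for y = (0, 1): E = 1
  X <- matrix(1, 1, 1)
  W <- matrix(c(1000, -1000), 2, 1)
  b <- c(0, 0)
  Y <- matrix(c(0, 1), 1, 2)
  out <- coarse_loss(X, W, b, Y)
  expect_equal(out$E, 1)
  # perfect outputs -> 0
  expect_equal(coarse_loss(X, W, b, matrix(c(1, 0), 1, 2))$E, 0,
               tolerance = 1e-12)
  expect_error(coarse_loss(X[0, , drop = FALSE], W, b, Y[0, , drop = FALSE]),
               "N = 0")

  # gradient vs central finite differences on random instances
  set.seed(21)
  for (rep in 1:20) {
    N <- sample(2:5, 1); C <- sample(2:4, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(N * p), N)
    W <- matrix(rnorm(C * p), C); b <- rnorm(C)
    Y <- matrix(rbinom(N * C, 1, 0.4), N)
    out <- coarse_loss(X, W, b, Y)
    num <- numeric_grad(function(v) {
      coarse_loss(X, matrix(v, C), b, Y)$E
    }, as.numeric(W))
    expect_lt(rel_err(num, as.numeric(out$dW)), 1e-4)
    numb <- numeric_grad(function(v) coarse_loss(X, W, v, Y)$E, b)
    expect_lt(rel_err(numb, out$db), 1e-4)
    numx <- numeric_grad(function(v)
      coarse_loss(matrix(v, N), W, b, Y)$E, as.numeric(X))
    expect_lt(rel_err(numx, as.numeric(out$dX)), 1e-4)
  }
})

test_that("fine_loss evaluates the stated instance and its gradient", {
  # n_k = 2 labels, f = (1, 1), y = (1, 0): J = 1/2
  X <- matrix(1, 1, 1)
  Wk <- matrix(c(1000, 1000), 2, 1)
  bk <- c(0, 0)
  Yk <- matrix(c(1, 0), 1, 2)
  expect_equal(fine_loss(X, Wk, bk, Yk)$J, 0.5)
  expect_equal(fine_loss(X, Wk, bk, matrix(c(1, 1), 1, 2))$J, 0,
               tolerance = 1e-12)
  expect_error(fine_loss(X, Wk[0, , drop = FALSE], numeric(0),
                         Yk[, 0, drop = FALSE]), "empty")

  set.seed(22)
  for (rep in 1:20) {
    N <- sample(1:4, 1); nk <- sample(2:4, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(N * p), N)
    Wk <- matrix(rnorm(nk * p), nk); bk <- rnorm(nk)
    Yk <- matrix(rbinom(N * nk, 1, 0.4), N)
    out <- fine_loss(X, Wk, bk, Yk)
    num <- numeric_grad(function(v)
      fine_loss(X, matrix(v, nk), bk, Yk)$J, as.numeric(Wk))
    expect_lt(rel_err(num, as.numeric(out$dW)), 1e-4)
  }
})

test_that("losses are non-negative and vanish only at the targets", {
  set.seed(23)
  for (rep in 1:20) {
    X <- matrix(rnorm(6), 2)
    W <- matrix(rnorm(6), 2); b <- rnorm(2)
    Y <- matrix(rbinom(4, 1, 0.5), 2)
    expect_gte(coarse_loss(X, W, b, Y)$E, 0)
    expect_gte(fine_loss(X, W, b, Y)$J, 0)
  }
})

# Build a hierarchy by hand: 2 clusters x 2 labels, feature dim 2.
make_hand_hierarchy <- function(tau = 0.5) {
  emb <- rbind(L1 = c(1, 0), L2 = c(1.1, 0), L3 = c(-1, 0),
               L4 = c(-1.1, 0))
  part <- cluster_labels(emb, 2, seed = 1)
  h <- hierarchy_init(part, 2, seed = 1, tau_coarse = tau, tau_fine = tau)
  h
}

test_that("predict_labels applies coarse gating and fallbacks", {
  h <- make_hand_hierarchy()
  k1 <- h$partition$assignment[["L1"]]   # cluster containing L1, L2
  k2 <- h$partition$assignment[["L3"]]
  # engineer: cluster k1 passes, labels L1 passes, L2 fails; cluster k2
  # fails coarse but its fine scores are high (must be excluded)
  h$W <- matrix(0, 2, 2); h$b <- c(0, 0)
  h$b[k1] <- 10; h$b[k2] <- -10
  for (k in c(k1, k2)) {
    blk <- h$fine[[k]]
    h$fine[[k]]$W <- matrix(0, length(blk$labels), 2)
    h$fine[[k]]$b <- rep(10, length(blk$labels))   # all fine scores ~1
  }
  i1 <- match("L1", h$fine[[k1]]$labels)
  h$fine[[k1]]$b[-i1] <- -10                       # only L1 passes in k1
  out <- predict_labels(c(0.3, 0.4), h)
  expect_identical(as.character(out), "L1")        # 0.99 label in k2 excluded

  # no coarse passes and no fine passes: single argmax-fallback label
  h2 <- make_hand_hierarchy()
  h2$W <- matrix(0, 2, 2); h2$b <- c(-5, -6)
  for (k in 1:2) {
    h2$fine[[k]]$W <- matrix(0, length(h2$fine[[k]]$labels), 2)
    h2$fine[[k]]$b <- c(-3, -4)[seq_along(h2$fine[[k]]$labels)]
  }
  out2 <- predict_labels(c(1, 1), h2)
  expect_length(as.character(out2), 1L)
  # fallback label lives in the argmax coarse cluster
  expect_equal(unname(h2$partition$assignment[[as.character(out2)]]),
               which.max(c(-5, -6) * 0 + c(-5, -6)))

  # two passing labels in one passing cluster: exactly those two
  h3 <- make_hand_hierarchy()
  h3$W <- matrix(0, 2, 2); h3$b <- c(0, 0)
  h3$b[k1] <- 10; h3$b[k2] <- -10
  h3$fine[[k1]]$W <- matrix(0, 2, 2); h3$fine[[k1]]$b <- c(10, 10)
  h3$fine[[k2]]$W <- matrix(0, 2, 2); h3$fine[[k2]]$b <- c(10, 10)
  out3 <- predict_labels(c(0, 0), h3)
  expect_setequal(as.character(out3), h3$fine[[k1]]$labels)
})

test_that("predicted labels always lie in selected clusters (property)", {
  set.seed(24)
  for (rep in 1:50) {
    h <- make_hand_hierarchy()
    h$W <- matrix(rnorm(4), 2); h$b <- rnorm(2)
    for (k in 1:2) {
      h$fine[[k]]$W <- matrix(rnorm(4), 2); h$fine[[k]]$b <- rnorm(2)
    }
    x <- rnorm(2)
    out <- as.character(predict_labels(x, h))
    cs <- as.numeric(logistic(h$W %*% x + h$b))
    sel <- which(cs >= h$tau_coarse)
    if (length(sel) == 0L) sel <- which.max(cs)
    allowed <- unlist(lapply(sel, function(k) h$fine[[k]]$labels))
    expect_true(all(out %in% allowed))
  }
})

test_that("dbc_predict compares the two nodes per label", {
  dbc <- dbc_init(c("A", "B", "C"), 2, seed = 1)
  mk <- function(v1, v2) {
    # weights making the two nodes output logistic(v1), logistic(v2)
    list(W = matrix(0, 2, 2), b = c(v1, v2))
  }
  dbc$heads[[1]] <- mk(2, -2)    # member
  dbc$heads[[2]] <- mk(-2, 2)    # non-member
  dbc$heads[[3]] <- mk(1, 1)     # tie -> excluded
  out <- dbc_predict(c(0, 0), dbc)
  expect_identical(as.character(out), "A")
})

test_that("hierarchical beats flat on separable features (5 seeds)", {
  # linearly separable features: one-hot cluster signal + noise
  wins <- 0
  f1h <- f1d <- numeric(5)
  for (seed in 1:5) {
    set.seed(seed)
    emb <- rbind(L1 = c(6, 0), L2 = c(6.4, 0), L3 = c(-6, 0),
                 L4 = c(-6.4, 0))
    part <- cluster_labels(emb, 2, seed = seed)
    n <- 120
    gold <- lapply(seq_len(n), function(i)
      sample(rownames(emb), sample(1:2, 1, prob = c(0.7, 0.3))))
    X <- t(vapply(gold, function(g) {
      x <- colSums(emb[g, , drop = FALSE]) / length(g) / 6
      x + rnorm(2, sd = 0.15)
    }, numeric(2)))
    h <- hierarchy_init(part, 2, seed = seed)
    h <- train_hierarchy(h, X, gold, epochs = 300, learning_rate = 3)
    d <- dbc_init(rownames(emb), 2, seed = seed)
    d <- train_dbc(d, X, gold, epochs = 300, learning_rate = 3)
    ph <- lapply(seq_len(n), function(i)
      as.character(predict_labels(X[i, ], h)))
    pd <- lapply(seq_len(n), function(i)
      as.character(dbc_predict(X[i, ], d)))
    f1h[seed] <- micro_metrics(class_counts(ph, gold, rownames(emb)))$MiF1
    f1d[seed] <- micro_metrics(class_counts(pd, gold, rownames(emb)))$MiF1
  }
  expect_gte(mean(f1h), mean(f1d))
})
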