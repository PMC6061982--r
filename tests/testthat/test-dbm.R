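# dbm: stable logistic, fusion, energy, sampling passes, contrastive
# training, pretraining, prediction, and the differentiable test chain.

test_that("logistic is stable and symmetric", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(710), 1)                  # no overflow
  expect_equal(logistic(-710), 0)
  set.seed(1)
  x <- rnorm(50, sd = 20)
  expect_equal(logistic(-x), 1 - logistic(x), tolerance = 1e-12)
  expect_true(all(logistic(x) > 0 & logistic(x) < 1 | abs(x) > 30))
})

test_that("fuse_inputs implements V = sigmoid(C yc + E ye)", {
  p <- dbm_params(3, 2, 2, 2, 2, 2, seed = 1)
  p$C[] <- 0; p$E[] <- 0
  expect_equal(as.numeric(fuse_inputs(c(1, 2), c(3, 4), p)), rep(0.5, 3))
  set.seed(2)
  p$C[] <- rnorm(6); p$E[] <- 0
  yc <- runif(2)
  expect_lt(max(abs(fuse_inputs(yc, c(0, 0), p) -
                      matrix(logistic(as.numeric(p$C %*% yc)), 1))), 1e-12)
  p$E[] <- rnorm(6); ye <- runif(2)
  hand <- logistic(as.numeric(p$C %*% yc + p$E %*% ye))
  expect_lt(max(abs(fuse_inputs(yc, ye, p) - matrix(hand, 1))), 1e-12)
  expect_error(fuse_inputs(c(1, 2, 3), ye, p), "mismatch")
})

test_that("dbm_energy equals the triple-loop summation oracle", {
  p <- dbm_params(2, 2, 2, 2, 2, 2, seed = 3, init_scale = 1)
  expect_equal(dbm_energy(rep(0, 2), rep(0, 2), rep(0, 2), rep(0, 2), p), 0)
  set.seed(4)
  V <- runif(2); h1 <- runif(2); h2 <- runif(2); tar <- c(1, 0)
  e <- 0
  for (i in 1:2) for (j in 1:2) e <- e - V[i] * p$W1[i, j] * h1[j]
  for (i in 1:2) for (j in 1:2) e <- e - h1[i] * p$W2[i, j] * h2[j]
  for (i in 1:2) for (j in 1:2) e <- e - tar[i] * p$Wlab[i, j] * h2[j]
  expect_lt(abs(dbm_energy(V, h1, h2, tar, p) - e), 1e-12)
  # negating W1 negates only the first term
  p2 <- p; p2$W1 <- -p$W1
  first <- -sum(outer(V, h1) * p$W1)
  expect_equal(dbm_energy(V, h1, h2, tar, p2),
               dbm_energy(V, h1, h2, tar, p) - 2 * first)
  # label term omitted when tar is NULL
  expect_equal(dbm_energy(V, h1, h2, NULL, p),
               dbm_energy(V, h1, h2, tar, p) + sum(tar %*% p$Wlab %*% h2))
})

test_that("up_pass and resample_h1 match hand computation", {
  p <- dbm_params(3, 2, 2, 2, 2, 2, seed = 5)
  p0 <- p
  for (nm in c("W1", "W2", "Wlab")) p0[[nm]][] <- 0
  up <- up_pass(c(0.2, 0.8, 0.5), c(1, 0), p0)
  expect_equal(as.numeric(up$h1), c(0.5, 0.5))
  expect_equal(as.numeric(up$h2), c(0.5, 0.5))

  set.seed(6)
  p$W1[] <- rnorm(6); p$W2[] <- rnorm(4); p$Wlab[] <- rnorm(4)
  p$bias1[] <- rnorm(2); p$bias2[] <- rnorm(2)
  V <- runif(3); tar <- c(0, 1)
  up <- up_pass(V, tar, p)
  h1_hand <- logistic(as.numeric(V %*% p$W1))
  h2_hand <- logistic(as.numeric(h1_hand %*% p$W2 + tar %*% p$Wlab +
                                   p$bias1))
  expect_lt(max(abs(as.numeric(up$h1) - h1_hand)), 1e-12)
  expect_lt(max(abs(as.numeric(up$h2) - h2_hand)), 1e-12)

  # doubled flag equals undoubled pass with 2*W1
  pd <- p; pd$W1 <- 2 * p$W1
  expect_equal(up_pass(V, tar, p, doubled = TRUE)$h1,
               up_pass(V, tar, pd, doubled = FALSE)$h1)

  h2 <- runif(2)
  h1p_hand <- logistic(as.numeric(V %*% p$W1 + h2 %*% t(p$W2) + p$bias2))
  expect_lt(max(abs(as.numeric(resample_h1(V, h2, p)) - h1p_hand)), 1e-12)
  # W2 = 0 reduces to bottom-up plus bias
  pz <- p; pz$W2[] <- 0
  expect_equal(as.numeric(resample_h1(V, h2, pz)),
               logistic(as.numeric(V %*% p$W1 + p$bias2)))
})

test_that("identical positive and negative states give exactly zero updates", {
  set.seed(7)
  V <- matrix(runif(12), 3); h1 <- matrix(runif(6), 3)
  h2 <- matrix(runif(9), 3); tar <- matrix(rbinom(6, 1, 0.5), 3)
  upd <- dbm_contrastive_updates(V, h1, h2, V, h1, h2, tar)
  for (nm in names(upd)) expect_true(all(upd[[nm]] == 0))
})

test_that("learning rate zero leaves parameters unchanged", {
  p <- dbm_params(6, 4, 4, 4, 3, 3, seed = 7)
  set.seed(8)
  batch <- list(V = matrix(runif(48), 8), tar = matrix(rbinom(24, 1, 0.5), 8))
  batch$tar[rowSums(batch$tar) == 0, 1] <- 1
  st <- dbm_train_step(batch, p, learning_rate = 0)
  for (nm in c("W1", "W2", "Wlab", "bias1", "bias2", "bias3", "vbias"))
    expect_identical(st$params[[nm]], p[[nm]])
})

test_that("contrastive training reduces reconstruction error (5 seeds)", {
  # fixed toy batch: 8 samples, |V|=6, |h1|=4, |h2|=3
  for (seed in 1:5) {
    set.seed(seed)
    V <- matrix(runif(48), 8, 6)
    tar <- matrix(rbinom(24, 1, 0.5), 8, 3)
    tar[rowSums(tar) == 0, 1] <- 1
    p <- dbm_params(6, 4, 4, 4, 3, 3, seed = 7)
    first <- NULL
    last <- NULL
    for (e in 1:50) {
      st <- dbm_train_step(list(V = V, tar = tar), p, learning_rate = 0.5)
      p <- st$params
      if (is.null(first)) first <- st$rec_v
      last <- st$rec_v
    }
    expect_lt(last, first)
  }
})

test_that("pretraining is seed-deterministic and reduces reconstruction", {
  p0 <- dbm_params(6, 4, 4, 4, 3, 3, seed = 11)
  set.seed(12)
  V <- matrix(runif(120), 20, 6)
  # epochs 0: unchanged seeded init
  out0 <- dbm_pretrain(p0, V, epochs = 0)
  expect_identical(out0$params, p0)
  expect_identical(dbm_params(6, 4, 4, 4, 3, 3, seed = 11), p0)

  out <- dbm_pretrain(p0, V, epochs = 30, learning_rate = 0.3)
  expect_lt(utils::tail(out$rec1, 1), out$rec1[1])
})

test_that("dbm_predict is a deterministic five-step chain", {
  p <- dbm_params(4, 3, 3, 3, 2, 5, seed = 13, init_scale = 0.3)
  set.seed(14)
  V <- matrix(runif(4), 1)
  s1 <- dbm_predict(V, p)
  s2 <- dbm_predict(V, p)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(1L, 5L))

  # Wlab = 0 -> all scores 0.5
  pz <- p; pz$Wlab[] <- 0
  expect_equal(as.numeric(dbm_predict(V, pz)), rep(0.5, 5))

  # straight-line oracle
  h1 <- logistic(V %*% (2 * p$W1))
  h2 <- logistic(h1 %*% p$W2 + matrix(p$bias1, 1, 2))
  h1p <- logistic(V %*% p$W1 + h2 %*% t(p$W2) + matrix(p$bias2, 1, 3))
  h2p <- logistic(h1p %*% p$W2 + matrix(p$bias3, 1, 2))
  expect_lt(max(abs(s1 - logistic(h2p %*% t(p$Wlab)))), 1e-12)
})

test_that("activations stay in [0,1] and energy stays finite", {
  set.seed(15)
  p <- dbm_params(5, 3, 3, 4, 3, 4, seed = 15, init_scale = 2)
  for (rep in 1:20) {
    yc <- matrix(runif(3), 1); ye <- matrix(runif(3), 1)
    fw <- dbm_forward(yc, ye, p)
    for (nm in c("V", "h1", "h2", "h1p", "h2p", "S")) {
      v <- fw$cache[[nm]]
      expect_true(all(v >= 0 & v <= 1))
    }
    e <- dbm_energy(as.numeric(fw$cache$V), as.numeric(fw$cache$h1),
                    as.numeric(fw$cache$h2), NULL, p)
    expect_true(is.finite(e))
  }
})

test_that("dbm_backward matches finite differences for every parameter", {
  set.seed(16)
  p <- dbm_params(5, 4, 4, 3, 3, 6, seed = 2, init_scale = 0.4)
  yc <- matrix(runif(8), 2, 4); ye <- matrix(runif(8), 2, 4)
  r <- matrix(rnorm(12), 2, 6)
  fw <- dbm_forward(yc, ye, p)
  bk <- dbm_backward(r, fw$cache, p)
  loss <- function(pp) sum(dbm_forward(yc, ye, pp)$scores * r)
  for (nm in c("C", "E", "W1", "W2", "Wlab", "bias1", "bias2", "bias3")) {
    num <- numeric_grad(function(v) {
      pp <- p; pp[[nm]][] <- v; loss(pp)
    }, as.numeric(p[[nm]]))
    expect_lt(rel_err(num, as.numeric(bk[[nm]])), 1e-4)
  }
  # gradient w.r.t. the CNN output
  num <- numeric_grad(function(v) {
    y <- yc; y[] <- v; sum(dbm_forward(y, ye, p)$scores * r)
  }, as.numeric(yc))
  expect_lt(rel_err(num, as.numeric(bk$dyc)), 1e-4)

  # h2-representation variant
  r2 <- matrix(rnorm(6), 2, 3)
  bk2 <- dbm_backward(r2, fw$cache, p, wrt = "h2")
  num2 <- numeric_grad(function(v) {
    pp <- p; pp$W1[] <- v; sum(dbm_forward(yc, ye, pp)$cache$h2p * r2)
  }, as.numeric(p$W1))
  expect_lt(rel_err(num2, as.numeric(bk2$W1)), 1e-4)
})
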