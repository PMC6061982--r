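# Two-hidden-layer deep Boltzmann machine with label units.
#
# The visible layer V fuses the CNN output y_c with the global entity vector
# y_e: V = sigmoid(C y_c + E y_e). Hidden layers h1, h2 are connected by W1
# (visible-h1) and W2 (h1-h2); label units connect to h2 through Wlab. All
# states are mean-field activations in [0, 1] (no Bernoulli sampling), which
# keeps training and prediction deterministic; a `sample` flag on
# dbm_train_step() exists for fidelity experiments. Row-vector convention
# throughout: a batch is a matrix with one sample per row.
#
# Energy of a state (two-layer machine, the label layer standing in for the
# third hidden layer): E = -V'W1 h1 - h1'W2 h2 - tar'Wlab h2.

#' Numerically stable logistic function
#'
#' `1/(1+exp(-x))`, computed without overflow for any finite input
#' (|x| >= 500 included).
#'
#' @param x numeric vector/matrix.
#' @return values in `(0, 1)`, same shape.
#' @export
logistic <- function(x) {
  out <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Initialise DBM parameters
#'
#' All weights are seeded Gaussians scaled by `init_scale`; biases start at
#' zero.
#'
#' @param n_visible,n_yc,n_ye,n_h1,n_h2,n_labels layer sizes.
#' @param seed integer seed.
#' @param init_scale standard deviation of the initial weights.
#' @return an `si_dbm_params` list with fusion matrices `C` (`|V| x |y_c|`)
#'   and `E` (`|V| x |y_e|`), weights `W1` (`|V| x |h1|`), `W2`
#'   (`|h1| x |h2|`), `Wlab` (`|labels| x |h2|`), biases `bias1`, `bias3`
#'   (h2), `bias2` (h1) and `vbias` (visible).
#' @export
dbm_params <- function(n_visible, n_yc, n_ye, n_h1, n_h2, n_labels,
                       seed = 1L, init_scale = 0.01) {
  with_seed(derive_seed(seed, 202L), {
    rn <- function(r, c) matrix(stats::rnorm(r * c, sd = init_scale),
                                nrow = r)
    structure(list(C = rn(n_visible, n_yc), E = rn(n_visible, n_ye),
                   W1 = rn(n_visible, n_h1), W2 = rn(n_h1, n_h2),
                   Wlab = rn(n_labels, n_h2),
                   bias1 = numeric(n_h2), bias2 = numeric(n_h1),
                   bias3 = numeric(n_h2), vbias = numeric(n_visible)),
              class = "si_dbm_params")
  })
}

.as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

#' Fuse CNN output and entity feature into the visible layer
#'
#' `V = sigmoid(C y_c + E y_e)`.
#'
#' @param yc CNN output, vector or batch matrix (rows = samples).
#' @param ye entity feature, same batch shape.
#' @param params an `si_dbm_params`.
#' @return batch matrix of visible activations in `(0, 1)`.
#' @export
fuse_inputs <- function(yc, ye, params) {
  yc <- .as_row(yc); ye <- .as_row(ye)
  if (ncol(yc) != ncol(params$C) || ncol(ye) != ncol(params$E))
    stop("fusion shape mismatch")
  logistic(yc %*% t(params$C) + ye %*% t(params$E))
}

#' DBM state energy
#'
#' `E = -V'W1 h1 - h1'W2 h2 - tar'Wlab h2`; the label term is omitted when
#' `tar` is `NULL`.
#'
#' @param V,h1,h2 state vectors.
#' @param tar binary label-indicator vector or `NULL`.
#' @param params an `si_dbm_params`.
#' @return scalar energy.
#' @export
dbm_energy <- function(V, h1, h2, tar = NULL, params) {
  e <- -as.numeric(V %*% params$W1 %*% h1) -
    as.numeric(h1 %*% params$W2 %*% h2)
  if (!is.null(tar)) e <- e - as.numeric(tar %*% params$Wlab %*% h2)
  e
}

#' Bottom-up pass through both hidden layers
#'
#' `h1 = sigmoid(V (2 W1))` when `doubled` (the test-time doubling of the
#' visible-h1 weights; training uses single weights), else
#' `h1 = sigmoid(V W1)`; then `h2 = sigmoid(h1 W2 + tar Wlab + bias1)` with
#' the label term dropped when `tar` is `NULL`.
#'
#' @param V visible batch matrix.
#' @param tar binary label batch matrix or `NULL` (test time).
#' @param params an `si_dbm_params`.
#' @param doubled logical; double the visible-h1 weights.
#' @return list with `h1` and `h2` batch matrices.
#' @export
up_pass <- function(V, tar = NULL, params, doubled = FALSE) {
  V <- .as_row(V)
  W1 <- if (doubled) 2 * params$W1 else params$W1
  h1 <- logistic(V %*% W1)
  z2 <- h1 %*% params$W2 +
    matrix(params$bias1, nrow(h1), length(params$bias1), byrow = TRUE)
  if (!is.null(tar)) z2 <- z2 + .as_row(tar) %*% params$Wlab
  list(h1 = h1, h2 = logistic(z2))
}

#' Re-sample the first hidden layer from both neighbours
#'
#' `h1' = sigmoid(V W1 + h2 W2' + bias2)`.
#'
#' @param V visible batch matrix.
#' @param h2 second-hidden-layer batch matrix.
#' @param params an `si_dbm_params`.
#' @return batch matrix `h1'`.
#' @export
resample_h1 <- function(V, h2, params) {
  V <- .as_row(V); h2 <- .as_row(h2)
  logistic(V %*% params$W1 + h2 %*% t(params$W2) +
             matrix(params$bias2, nrow(V), length(params$bias2),
                    byrow = TRUE))
}

#' Contrastive parameter updates from positive/negative states
#'
#' Pure difference form: identical positive and negative states give exactly
#' zero updates for every parameter.
#'
#' @param V,h1,h2 positive-phase batch matrices.
#' @param Vp,h1p,h2p negative-phase (reconstruction) batch matrices.
#' @param tar binary label batch matrix.
#' @return list of deltas (per-sample averages) named like the parameters.
#' @export
dbm_contrastive_updates <- function(V, h1, h2, Vp, h1p, h2p, tar) {
  n <- nrow(.as_row(V))
  V <- .as_row(V); h1 <- .as_row(h1); h2 <- .as_row(h2)
  Vp <- .as_row(Vp); h1p <- .as_row(h1p); h2p <- .as_row(h2p)
  tar <- .as_row(tar)
  list(W1 = (t(V) %*% h1 - t(Vp) %*% h1p) / n,
       W2 = (t(h1) %*% h2 - t(h1p) %*% h2p) / n,
       Wlab = (t(tar) %*% h2 - t(tar) %*% h2p) / n,
       vbias = colMeans(V - Vp),
       bias2 = colMeans(h1 - h1p),
       bias1 = colMeans(h2 - h2p),
       bias3 = colMeans(h2 - h2p))
}

#' One contrastive training step
#'
#' Mean-field CD-1-style step: bottom-up `h1`, `h2` (with labels);
#' reconstruction `V' = sigmoid(h1 W1' + vbias)`; `h1'` from `V` and `h2`;
#' `h2'` from `h1'` and the labels (with `bias3`); then difference-form
#' updates scaled by `learning_rate`.
#'
#' @param batch list with `V` (or `yc`/`ye` to be fused) and `tar`.
#' @param params an `si_dbm_params`.
#' @param learning_rate non-negative step size.
#' @param sample logical; if `TRUE`, binarise hidden states by Bernoulli
#'   draws (uses current RNG) instead of mean-field values.
#' @return list with updated `params` and reconstruction errors
#'   `rec_v = mean ||V' - V||`, `rec_h1 = mean ||h1' - h1||`.
#' @export
dbm_train_step <- function(batch, params, learning_rate,
                           sample = FALSE) {
  V <- .as_row(if (!is.null(batch$V)) batch$V
               else fuse_inputs(batch$yc, batch$ye, params))
  tar <- .as_row(batch$tar)
  up <- up_pass(V, tar, params, doubled = FALSE)
  h1 <- up$h1; h2 <- up$h2
  if (sample) {
    h1 <- (matrix(stats::runif(length(h1)), nrow(h1)) < h1) * 1
    h2 <- (matrix(stats::runif(length(h2)), nrow(h2)) < h2) * 1
  }
  Vp <- logistic(h1 %*% t(params$W1) +
                   matrix(params$vbias, nrow(h1), length(params$vbias),
                          byrow = TRUE))
  h1p <- resample_h1(V, h2, params)
  h2p <- logistic(h1p %*% params$W2 + tar %*% params$Wlab +
                    matrix(params$bias3, nrow(h1p), length(params$bias3),
                           byrow = TRUE))
  upd <- dbm_contrastive_updates(V, h1, h2, Vp, h1p, h2p, tar)
  for (nm in names(upd))
    params[[nm]] <- params[[nm]] + learning_rate * upd[[nm]]
  rec_v <- mean(sqrt(rowSums((Vp - V)^2)))
  rec_h1 <- mean(sqrt(rowSums((h1p - h1)^2)))
  list(params = params, rec_v = rec_v, rec_h1 = rec_h1)
}

# One CD-1 step for a plain RBM (used by layer-wise pretraining).
.rbm_cd1 <- function(Vis, W, vb, hb, lr) {
  n <- nrow(Vis)
  H <- logistic(Vis %*% W + matrix(hb, n, length(hb), byrow = TRUE))
  Vp <- logistic(H %*% t(W) + matrix(vb, n, length(vb), byrow = TRUE))
  Hp <- logistic(Vp %*% W + matrix(hb, n, length(hb), byrow = TRUE))
  list(W = W + lr * (t(Vis) %*% H - t(Vp) %*% Hp) / n,
       vb = vb + lr * colMeans(Vis - Vp),
       hb = hb + lr * colMeans(H - Hp),
       rec = mean(sqrt(rowSums((Vp - Vis)^2))))
}

#' Layer-wise RBM pretraining
#'
#' Pretrains the (V, h1) RBM with CD-1 (weights `W1`, biases `vbias`/`bias2`)
#' then the (h1, h2) RBM (weights `W2`, bias `bias1`), each for `epochs`
#' passes over the data. `epochs = 0` returns the parameters unchanged (the
#' seeded random initialisation).
#'
#' @param params an `si_dbm_params`.
#' @param Vdata visible data batch matrix.
#' @param epochs non-negative integer.
#' @param learning_rate step size.
#' @return list with `params` and per-epoch reconstruction errors `rec1`,
#'   `rec2`.
#' @export
dbm_pretrain <- function(params, Vdata, epochs, learning_rate = 0.1) {
  rec1 <- rec2 <- numeric(0)
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      st <- .rbm_cd1(Vdata, params$W1, params$vbias, params$bias2,
                     learning_rate)
      params$W1 <- st$W; params$vbias <- st$vb; params$bias2 <- st$hb
      rec1 <- c(rec1, st$rec)
    }
    H1 <- logistic(Vdata %*% params$W1 +
                     matrix(params$bias2, nrow(Vdata),
                            length(params$bias2), byrow = TRUE))
    for (e in seq_len(epochs)) {
      st <- .rbm_cd1(H1, params$W2, numeric(ncol(H1)), params$bias1,
                     learning_rate)
      params$W2 <- st$W; params$bias1 <- st$hb
      rec2 <- c(rec2, st$rec)
    }
  }
  list(params = params, rec1 = rec1, rec2 = rec2)
}

#' Label scores for test inputs
#'
#' Deterministic mean-field test procedure: bottom-up with doubled
#' visible-h1 weights and no labels, re-sample `h1'` from both neighbours,
#' re-compute `h2'`, then score every label through the label weights:
#' `scores = sigmoid(h2' Wlab')`. A pure function of `(V, params)`.
#'
#' @param V visible batch matrix (from [fuse_inputs()]).
#' @param params an `si_dbm_params`.
#' @return batch matrix of per-label scores in `(0, 1)`.
#' @export
dbm_predict <- function(V, params) {
  V <- .as_row(V)
  up <- up_pass(V, tar = NULL, params, doubled = TRUE)
  h1p <- resample_h1(V, up$h2, params)
  h2p <- logistic(h1p %*% params$W2 +
                    matrix(params$bias3, nrow(h1p), length(params$bias3),
                           byrow = TRUE))
  logistic(h2p %*% t(params$Wlab))
}

#' Forward pass of the test-time chain with cache (for joint training)
#'
#' Same computation as [dbm_predict()] starting from `(y_c, y_e)`, but keeps
#' every intermediate activation so gradients can be backpropagated.
#'
#' @param yc,ye batch matrices.
#' @param params an `si_dbm_params`.
#' @return list with `scores` and `cache`.
#' @export
dbm_forward <- function(yc, ye, params) {
  yc <- .as_row(yc); ye <- .as_row(ye)
  V <- fuse_inputs(yc, ye, params)
  h1 <- logistic(V %*% (2 * params$W1))
  h2 <- logistic(h1 %*% params$W2 +
                   matrix(params$bias1, nrow(h1), length(params$bias1),
                          byrow = TRUE))
  h1p <- resample_h1(V, h2, params)
  h2p <- logistic(h1p %*% params$W2 +
                    matrix(params$bias3, nrow(h1p), length(params$bias3),
                           byrow = TRUE))
  S <- logistic(h2p %*% t(params$Wlab))
  list(scores = S,
       cache = list(yc = yc, ye = ye, V = V, h1 = h1, h2 = h2,
                    h1p = h1p, h2p = h2p, S = S))
}

#' Backward pass through the test-time chain
#'
#' Given `dS = dL/dscores`, returns gradients for every DBM parameter and
#' for the CNN output `yc` (checked against finite differences in the test
#' suite).
#'
#' @param dS gradient batch matrix: w.r.t. the scores (`wrt = "scores"`) or
#'   w.r.t. the `h2'` representation (`wrt = "h2"`).
#' @param cache cache from [dbm_forward()].
#' @param params an `si_dbm_params`.
#' @param wrt which output `dS` differentiates.
#' @return list of gradients: `C`, `E`, `W1`, `W2`, `Wlab`, `bias1`,
#'   `bias2`, `bias3`, `dyc`.
#' @export
dbm_backward <- function(dS, cache, params, wrt = c("scores", "h2")) {
  wrt <- match.arg(wrt)
  sg <- function(a) a * (1 - a)
  dS <- .as_row(dS)
  if (wrt == "scores") {
    zS <- dS * sg(cache$S)
    gWlab <- t(zS) %*% cache$h2p
    dh2p <- zS %*% params$Wlab
  } else {
    gWlab <- matrix(0, nrow(params$Wlab), ncol(params$Wlab))
    dh2p <- dS
  }
  z2p <- dh2p * sg(cache$h2p)
  gW2 <- t(cache$h1p) %*% z2p
  gb3 <- colSums(z2p)
  dh1p <- z2p %*% t(params$W2)
  z1p <- dh1p * sg(cache$h1p)
  gW2 <- gW2 + t(z1p) %*% cache$h2    # h2 W2' term inside h1'
  gW1 <- t(cache$V) %*% z1p
  gb2 <- colSums(z1p)
  dV <- z1p %*% t(params$W1)
  dh2 <- z1p %*% params$W2
  z2 <- dh2 * sg(cache$h2)
  gW2 <- gW2 + t(cache$h1) %*% z2
  gb1 <- colSums(z2)
  dh1 <- z2 %*% t(params$W2)
  z1 <- dh1 * sg(cache$h1)
  gW1 <- gW1 + 2 * t(cache$V) %*% z1
  dV <- dV + z1 %*% t(2 * params$W1)
  zV <- dV * sg(cache$V)
  gC <- t(zV) %*% cache$yc
  gE <- t(zV) %*% cache$ye
  dyc <- zV %*% params$C
  list(C = gC, E = gE, W1 = gW1, W2 = gW2, Wlab = gWlab,
       bias1 = gb1, bias2 = gb2, bias3 = gb3, dyc = dyc)
}
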