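# Convolutional feature extractor over DSE document matrices.
#
# Geometry: a document matrix has L position rows and 4*d feature columns
# (4 stacked d-length sub-vectors per position). First-stage kernels span
# h positions x d feature columns and slide with stride d along the feature
# axis -- windows are aligned with whole sub-vectors, so a window never cuts
# a word embedding -- and stride 1 down positions, valid (no-padding)
# convolution. Deeper stages see a positions x channels matrix and use
# full-width kernels (one feature offset). Each convolution is followed by
# k-max pooling (the k largest values along the position axis, original order
# preserved), a per-map gain/bias, and the activation; pooled maps of the
# last stage are flattened and passed through fully-connected layers.
# Hidden activations are ReLU; the final fully-connected layer is sigmoid
# (its output feeds the Boltzmann fusion). Inverted dropout is applied to
# convolutional and hidden fully-connected activations in training mode, so
# inference is the identity ("mean network").

#' Rectified linear unit
#'
#' @param x numeric vector/matrix/array.
#' @return `pmax(x, 0)`, elementwise, preserving shape.
#' @export
relu <- function(x) {
  out <- pmax(x, 0)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

.act <- function(z, type) {
  switch(type,
         relu = relu(z),
         sigmoid = logistic(z),
         identity = z,
         stop("unknown activation: ", type))
}

# derivative w.r.t. pre-activation, given z and a = .act(z)
.act_grad <- function(z, a, type) {
  switch(type,
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a),
         identity = array(1, dim = dim(a) %||% length(a)),
         stop("unknown activation: ", type))
}

#' Inverted dropout
#'
#' In training mode each unit is zeroed independently with probability
#' `rate` and survivors are scaled by `1/(1-rate)`, so the expected output
#' equals the input and inference is the identity mean network. Uses the
#' current RNG stream; seed it for reproducibility.
#'
#' @param x numeric vector/matrix/array.
#' @param rate drop probability in `[0, 1)`.
#' @param mode `"train"` or `"inference"`.
#' @return tensor of the same shape; in training mode the applied mask
#'   (already scaled) is attached as attribute `"mask"`.
#' @export
dropout <- function(x, rate, mode = c("train", "inference")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)")
  if (mode == "inference" || rate == 0) return(x)
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  out <- x * mask
  if (!is.null(dim(x))) dim(out) <- dim(x)
  attr(out, "mask") <- mask
  out
}

#' CNN configuration
#'
#' Builds and shape-checks a stage/FC layout for inputs of `L` positions and
#' `4*d` features. `stages` is a list of `list(n_kernels, h, pool_k)`; the
#' first stage uses kernel width `d` and feature stride `d` (4 sub-vector
#' slots), deeper stages use full-width kernels. `fc` gives the sizes of the
#' fully-connected layers; the last entry is the output length `|y_c|`.
#'
#' @param L input positions (document length after fitting).
#' @param d word-embedding dimension.
#' @param stages list of per-stage settings.
#' @param fc integer vector of fully-connected layer sizes.
#' @param dropout_rate drop probability for conv/hidden-FC activations.
#' @param hidden_activation,final_activation activation names.
#' @return an `si_cnn_config` with derived shapes.
#' @export
cnn_config <- function(L, d,
                       stages = list(list(n_kernels = 4L, h = 2L,
                                          pool_k = 2L)),
                       fc = c(16L, 8L),
                       dropout_rate = 0.5,
                       hidden_activation = "relu",
                       final_activation = "sigmoid") {
  in_pos <- as.integer(L)
  in_width <- 4L * as.integer(d)
  stride <- as.integer(d)
  shapes <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    h <- as.integer(st$h)
    nk <- as.integer(st$n_kernels)
    kw <- if (s == 1L) stride else in_width
    str <- if (s == 1L) stride else in_width
    if (in_width %% str != 0L) stop("feature width not a multiple of stride")
    Q <- in_width %/% str
    if (h > in_pos)
      stop(sprintf("stage %d: kernel height %d exceeds %d positions",
                   s, h, in_pos))
    P <- in_pos - h + 1L
    k <- as.integer(st$pool_k)
    if (k < 1L || k > P)
      stop(sprintf("stage %d: pool k=%d not in [1, %d]", s, k, P))
    shapes[[s]] <- list(n_kernels = nk, h = h, kernel_width = kw,
                        stride = str, Q = Q, in_positions = in_pos,
                        in_width = in_width, conv_positions = P, pool_k = k)
    in_pos <- k
    in_width <- Q * nk
  }
  flat <- in_pos * in_width
  structure(list(L = as.integer(L), d = as.integer(d), stages = shapes,
                 fc = as.integer(fc), flat_size = flat,
                 dropout_rate = dropout_rate,
                 hidden_activation = hidden_activation,
                 final_activation = final_activation),
            class = "si_cnn_config")
}

#' Initialise CNN parameters
#'
#' Kernels and FC weights are drawn from seeded Gaussians scaled by fan-in;
#' biases start at zero and pooling gains at one.
#'
#' @param config an `si_cnn_config`.
#' @param seed integer seed.
#' @return an `si_cnn_params` list with `conv` (per stage: `kernels`,
#'   `bias`, `beta`, `pool_bias`) and `fc` (per layer: `W`, `b`).
#' @export
cnn_init <- function(config, seed = 1L) {
  with_seed(derive_seed(seed, 101L), {
    conv <- lapply(config$stages, function(st) {
      fan <- st$h * st$kernel_width
      list(kernels = lapply(seq_len(st$n_kernels), function(i)
             matrix(stats::rnorm(st$h * st$kernel_width, sd = 1 / sqrt(fan)),
                    nrow = st$h)),
           bias = numeric(st$n_kernels),
           beta = rep(1, st$n_kernels),
           pool_bias = numeric(st$n_kernels))
    })
    sizes <- c(config$flat_size, config$fc)
    fc <- lapply(seq_len(length(sizes) - 1L), function(i)
      list(W = matrix(stats::rnorm(sizes[i + 1L] * sizes[i],
                                   sd = 1 / sqrt(sizes[i])),
                      nrow = sizes[i + 1L]),
           b = numeric(sizes[i + 1L])))
    structure(list(conv = conv, fc = fc), class = "si_cnn_params")
  })
}

#' Convolution layer forward pass
#'
#' `map[p, q, i] = f(sum(A[p:(p+h-1), cols_q] * K_i) + bias_i)` where
#' `cols_q` are the `kernel_width` columns at feature offset `(q-1)*stride`.
#' Valid positions only.
#'
#' @param A input matrix (positions x features).
#' @param kernels list of `h x kernel_width` matrices.
#' @param bias numeric, one per kernel.
#' @param stride feature-axis stride (equal to the kernel width).
#' @param activation activation name.
#' @return list with pre-activation `z` and activation `a`, both
#'   `P x Q x n_kernels` arrays.
#' @export
conv_forward <- function(A, kernels, bias, stride,
                         activation = "relu") {
  h <- nrow(kernels[[1L]])
  w <- ncol(kernels[[1L]])
  if (h > nrow(A)) stop("kernel height exceeds position count")
  if (ncol(A) %% stride != 0L) stop("feature width not a multiple of stride")
  P <- nrow(A) - h + 1L
  Q <- ncol(A) %/% stride
  nk <- length(kernels)
  z <- array(0, dim = c(P, Q, nk))
  for (ki in seq_len(nk)) {
    K <- kernels[[ki]]
    for (q in seq_len(Q)) {
      cols <- ((q - 1L) * stride + 1L):((q - 1L) * stride + w)
      acc <- rep(bias[ki], P)
      for (i in seq_len(h))
        acc <- acc + as.numeric(A[i:(i + P - 1L), cols, drop = FALSE] %*%
                                  K[i, ])
      z[, q, ki] <- acc
    }
  }
  list(z = z, a = .act(z, activation))
}

#' k-max pooling layer forward pass
#'
#' Takes the `k` largest values along the position axis of each feature map
#' (original order preserved; ties broken by earliest position), applies the
#' per-map gain `beta` and bias, then the activation.
#'
#' @param a conv activations, `P x Q x n_kernels` array.
#' @param k number of values kept per map column.
#' @param beta,pool_bias numeric, one per kernel.
#' @param activation activation name.
#' @return list with pooled pre-activation `z`, activation `out`
#'   (`k x Q x n_kernels`), and the selected position indices `idx`.
#' @export
pool_forward <- function(a, k, beta, pool_bias, activation = "relu") {
  dims <- dim(a)
  P <- dims[1L]; Q <- dims[2L]; nk <- dims[3L]
  if (k > P) stop(sprintf("pool k=%d exceeds map length %d", k, P))
  z <- array(0, dim = c(k, Q, nk))
  idx <- array(0L, dim = c(k, Q, nk))
  for (ki in seq_len(nk)) for (q in seq_len(Q)) {
    v <- a[, q, ki]
    sel <- sort(order(v, decreasing = TRUE)[seq_len(k)])
    idx[, q, ki] <- sel
    z[, q, ki] <- beta[ki] * v[sel] + pool_bias[ki]
  }
  list(z = z, out = .act(z, activation), idx = idx)
}

#' Fully-connected layer forward pass
#'
#' @param x input vector.
#' @param W weight matrix (`out x in`).
#' @param b bias vector.
#' @param activation activation name.
#' @return list with `z` and `a`.
#' @export
fc_forward <- function(x, W, b, activation = "relu") {
  if (ncol(W) != length(x)) stop("fc shape mismatch")
  z <- as.numeric(W %*% x + b)
  list(z = z, a = .act(z, activation))
}

#' CNN forward pass
#'
#' Applies the configured conv+pool stages, flattens, then the FC layers.
#' In training mode, inverted dropout is applied to every conv activation and
#' to hidden FC activations (uses the current RNG stream). Inference mode is
#' deterministic.
#'
#' @param A document matrix (`L x 4d`).
#' @param params an `si_cnn_params`.
#' @param config an `si_cnn_config`.
#' @param mode `"inference"` or `"train"`.
#' @return list with output `y` (length `|y_c|`) and `cache` for
#'   [cnn_backward()].
#' @export
cnn_forward <- function(A, params, config, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  hact <- config$hidden_activation
  stage_cache <- vector("list", length(config$stages))
  X <- A
  for (s in seq_along(config$stages)) {
    st <- config$stages[[s]]
    cv <- conv_forward(X, params$conv[[s]]$kernels, params$conv[[s]]$bias,
                       st$stride, activation = hact)
    a_used <- cv$a
    mask <- NULL
    if (mode == "train" && config$dropout_rate > 0) {
      a_used <- dropout(cv$a, config$dropout_rate, "train")
      mask <- attr(a_used, "mask")
      attr(a_used, "mask") <- NULL
    }
    pl <- pool_forward(a_used, st$pool_k, params$conv[[s]]$beta,
                       params$conv[[s]]$pool_bias, activation = hact)
    stage_cache[[s]] <- list(input = X, conv = cv, mask = mask, pool = pl)
    X <- matrix(as.numeric(pl$out), nrow = st$pool_k)  # k x (Q*nk)
  }
  x <- as.numeric(X)
  nfc <- length(params$fc)
  fc_cache <- vector("list", nfc)
  for (l in seq_len(nfc)) {
    act <- if (l == nfc) config$final_activation else hact
    f <- fc_forward(x, params$fc[[l]]$W, params$fc[[l]]$b, activation = act)
    a_used <- f$a
    mask <- NULL
    if (mode == "train" && l < nfc && config$dropout_rate > 0) {
      a_used <- dropout(f$a, config$dropout_rate, "train")
      mask <- attr(a_used, "mask")
      attr(a_used, "mask") <- NULL
    }
    fc_cache[[l]] <- list(x = x, z = f$z, a = f$a, mask = mask)
    x <- as.numeric(a_used)
  }
  list(y = x, cache = list(stages = stage_cache, fc = fc_cache,
                           mode = mode))
}

#' CNN backward pass
#'
#' Backpropagates `dy` (gradient of a scalar loss w.r.t. the output) through
#' the cached forward pass, returning gradients for every parameter and for
#' the input matrix.
#'
#' @param dy numeric vector, `dL/dy`.
#' @param cache the cache returned by [cnn_forward()].
#' @param params,config as in [cnn_forward()].
#' @return list with `conv` and `fc` gradient structures mirroring `params`,
#'   plus `dA` (gradient w.r.t. the input matrix).
#' @export
cnn_backward <- function(dy, cache, params, config) {
  hact <- config$hidden_activation
  nfc <- length(params$fc)
  gfc <- vector("list", nfc)
  dx <- dy
  for (l in rev(seq_len(nfc))) {
    fcache <- cache$fc[[l]]
    act <- if (l == nfc) config$final_activation else hact
    if (l < nfc && !is.null(fcache$mask)) dx <- dx * fcache$mask
    dz <- dx * .act_grad(fcache$z, fcache$a, act)
    gfc[[l]] <- list(W = outer(dz, fcache$x), b = dz)
    dx <- as.numeric(t(params$fc[[l]]$W) %*% dz)
  }
  ns <- length(config$stages)
  gconv <- vector("list", ns)
  for (s in rev(seq_len(ns))) {
    st <- config$stages[[s]]
    scache <- cache$stages[[s]]
    dpool_out <- array(dx, dim = c(st$pool_k, st$Q, st$n_kernels))
    pl <- scache$pool
    dz2 <- dpool_out * .act_grad(pl$z, pl$out, hact)
    dbeta <- numeric(st$n_kernels)
    dpb <- numeric(st$n_kernels)
    da1 <- array(0, dim = dim(scache$conv$a))
    a_used <- scache$conv$a
    if (!is.null(scache$mask)) a_used <- a_used * scache$mask
    for (ki in seq_len(st$n_kernels)) for (q in seq_len(st$Q)) {
      sel <- pl$idx[, q, ki]
      v <- a_used[sel, q, ki]
      dbeta[ki] <- dbeta[ki] + sum(dz2[, q, ki] * v)
      dpb[ki] <- dpb[ki] + sum(dz2[, q, ki])
      da1[sel, q, ki] <- da1[sel, q, ki] +
        dz2[, q, ki] * params$conv[[s]]$beta[ki]
    }
    if (!is.null(scache$mask)) da1 <- da1 * scache$mask
    dzc <- da1 * .act_grad(scache$conv$z, scache$conv$a, hact)
    A <- scache$input
    h <- st$h; w <- st$kernel_width; P <- st$conv_positions
    dK <- lapply(seq_len(st$n_kernels), function(i) matrix(0, h, w))
    db1 <- numeric(st$n_kernels)
    dA <- matrix(0, nrow = nrow(A), ncol = ncol(A))
    for (ki in seq_len(st$n_kernels)) {
      K <- params$conv[[s]]$kernels[[ki]]
      db1[ki] <- sum(dzc[, , ki])
      for (q in seq_len(st$Q)) {
        cols <- ((q - 1L) * st$stride + 1L):((q - 1L) * st$stride + w)
        dzq <- dzc[, q, ki]
        for (i in seq_len(h)) {
          rows <- i:(i + P - 1L)
          dK[[ki]][i, ] <- dK[[ki]][i, ] +
            as.numeric(t(A[rows, cols, drop = FALSE]) %*% dzq)
          dA[rows, cols] <- dA[rows, cols] + outer(dzq, K[i, ])
        }
      }
    }
    gconv[[s]] <- list(kernels = dK, bias = db1, beta = dbeta,
                       pool_bias = dpb)
    dx <- dA
  }
  list(conv = gconv, fc = gfc, dA = dx)
}
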