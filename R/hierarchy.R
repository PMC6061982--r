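# Coarse-to-fine multi-label classification over clustered label embeddings,
# plus the flat per-label binary (member / non-member) baseline.
#
# Coarse stage: labels are k-means-clustered in label-embedding space; a
# document's coarse targets are the clusters containing any of its labels.
# Squared-error losses:
#   coarse  E   = 1/(N C)  sum_C sum_N (f(x, w)   - y)^2
#   fine    J_k = 1/(n_k N) sum      (f(x, w_k) - y)^2   per cluster k
# with f = sigmoid(w x + b); updates to different clusters' weights are
# independent.

#' Cluster label embeddings into coarse classes
#'
#' Seeded k-means with k-means++ initialisation, Euclidean distance and
#' Lloyd iterations (at most `iter_max`). Deterministic given the seed.
#'
#' @param label_embeddings numeric matrix, one row per label (rownames =
#'   label identifiers).
#' @param C number of coarse clusters.
#' @param seed integer seed.
#' @param iter_max maximum Lloyd iterations.
#' @return an `si_partition`: list with `C`, `assignment` (named integer
#'   vector label -> cluster), `centers` (C x dim matrix).
#' @export
cluster_labels <- function(label_embeddings, C, seed = 1L, iter_max = 100L) {
  n <- nrow(label_embeddings)
  if (C < 1L || C > n)
    stop(sprintf("C=%d must be in [1, %d]", C, n))
  X <- as.matrix(label_embeddings)
  centers <- with_seed(derive_seed(seed, 303L), {
    # k-means++ seeding
    idx <- sample.int(n, 1L)
    cent <- X[idx, , drop = FALSE]
    while (nrow(cent) < C) {
      d2 <- apply(X, 1L, function(r)
        min(colSums((t(cent) - r)^2)))
      p <- d2 / sum(d2)
      idx <- sample.int(n, 1L, prob = p)
      cent <- rbind(cent, X[idx, ])
    }
    cent
  })
  fit <- if (C == 1L) {
    list(cluster = rep(1L, n), centers = matrix(colMeans(X), nrow = 1L))
  } else {
    km <- stats::kmeans(X, centers = centers, iter.max = iter_max,
                        algorithm = "Lloyd")
    list(cluster = km$cluster, centers = km$centers)
  }
  assignment <- as.integer(fit$cluster)
  names(assignment) <- rownames(X)
  structure(list(C = as.integer(C), assignment = assignment,
                 centers = fit$centers),
            class = "si_partition")
}

#' Coarse-membership targets for documents
#'
#' A document's coarse target vector has a 1 for every cluster containing at
#' least one of its labels.
#'
#' @param label_sets list of character vectors (gold labels per document).
#' @param partition an `si_partition`.
#' @return binary matrix `N x C`.
#' @export
coarse_targets <- function(label_sets, partition) {
  Y <- matrix(0, nrow = length(label_sets), ncol = partition$C)
  for (i in seq_along(label_sets)) {
    cl <- unique(partition$assignment[label_sets[[i]]])
    Y[i, cl] <- 1
  }
  Y
}

.sigmoid_linear <- function(X, W, b) {
  logistic(X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE))
}

#' Coarse squared-error loss and gradient
#'
#' `E = 1/(N C) sum (sigmoid(X w' + b) - Y)^2` with the gradient obtained by
#' the chain rule. `N` is the number of rows of `X`.
#'
#' @param X feature batch matrix (`N x p`).
#' @param W coarse weights (`C x p`).
#' @param b coarse biases (length `C`).
#' @param Y binary coarse-target matrix (`N x C`).
#' @return list with scalar `E`, gradient `dW` (`C x p`), `db` (length `C`)
#'   and the outputs `F`.
#' @export
coarse_loss <- function(X, W, b, Y) {
  X <- .as_row(X); Y <- .as_row(Y)
  N <- nrow(X)
  if (N == 0L) stop("coarse_loss: N = 0")
  C <- nrow(W)
  F_ <- .sigmoid_linear(X, W, b)
  E <- sum((F_ - Y)^2) / (N * C)
  G <- (2 / (N * C)) * (F_ - Y) * F_ * (1 - F_)   # N x C
  list(E = E, dW = t(G) %*% X, db = colSums(G), dX = G %*% W, F = F_)
}

#' Per-cluster fine squared-error loss and gradient
#'
#' `J_k = 1/(n_k N) sum (sigmoid(X w_k' + b_k) - Y)^2` over the `n_k` labels
#' of cluster `k`. Updates to different clusters are independent.
#'
#' @param X feature batch matrix.
#' @param Wk fine weights for cluster `k` (`n_k x p`).
#' @param bk biases (length `n_k`).
#' @param Yk binary targets restricted to the cluster's labels (`N x n_k`).
#' @return list with scalar `J`, `dW`, `db` and outputs `F`.
#' @export
fine_loss <- function(X, Wk, bk, Yk) {
  X <- .as_row(X); Yk <- .as_row(Yk)
  nk <- nrow(Wk)
  if (nk < 1L) stop("fine_loss: empty cluster")
  N <- nrow(X)
  F_ <- .sigmoid_linear(X, Wk, bk)
  J <- sum((F_ - Yk)^2) / (nk * N)
  G <- (2 / (nk * N)) * (F_ - Yk) * F_ * (1 - F_)
  list(J = J, dW = t(G) %*% X, db = colSums(G), dX = G %*% Wk, F = F_)
}

#' Initialise hierarchy weights
#'
#' @param partition an `si_partition`.
#' @param input_dim feature dimension `p`.
#' @param seed integer seed.
#' @param tau_coarse,tau_fine decision thresholds in `(0, 1)`.
#' @return an `si_hierarchy` with coarse weights `W`, `b`, per-cluster fine
#'   blocks `fine[[k]]$W`, `$b`, `$labels`, and the thresholds.
#' @export
hierarchy_init <- function(partition, input_dim, seed = 1L,
                           tau_coarse = 0.5, tau_fine = 0.5) {
  labs <- names(partition$assignment)
  with_seed(derive_seed(seed, 404L), {
    fine <- lapply(seq_len(partition$C), function(k) {
      lk <- labs[partition$assignment == k]
      list(W = matrix(stats::rnorm(length(lk) * input_dim, sd = 0.1),
                      nrow = length(lk)),
           b = numeric(length(lk)), labels = lk)
    })
    structure(list(W = matrix(stats::rnorm(partition$C * input_dim,
                                           sd = 0.1),
                              nrow = partition$C),
                   b = numeric(partition$C), fine = fine,
                   partition = partition,
                   tau_coarse = tau_coarse, tau_fine = tau_fine),
              class = "si_hierarchy")
  })
}

#' Coarse-to-fine multi-label prediction
#'
#' Clusters whose coarse score reaches `tau_coarse` are selected (the argmax
#' cluster when none passes); within each selected cluster, labels whose fine
#' score reaches `tau_fine` are returned. If the union is empty, the single
#' best fine label within the selected clusters is returned. Labels outside
#' selected clusters are never returned.
#'
#' @param x feature vector for one document.
#' @param hierarchy an `si_hierarchy`.
#' @return character vector of predicted labels, with per-label scores in
#'   attribute `"scores"`.
#' @export
predict_labels <- function(x, hierarchy) {
  x <- matrix(x, nrow = 1L)
  cs <- as.numeric(.sigmoid_linear(x, hierarchy$W, hierarchy$b))
  sel <- which(cs >= hierarchy$tau_coarse)
  if (length(sel) == 0L) sel <- which.max(cs)
  out <- character(0)
  scores <- numeric(0)
  best_lab <- NA_character_
  best_sc <- -Inf
  for (k in sel) {
    blk <- hierarchy$fine[[k]]
    fs <- as.numeric(.sigmoid_linear(x, blk$W, blk$b))
    hit <- fs >= hierarchy$tau_fine
    out <- c(out, blk$labels[hit])
    scores <- c(scores, fs[hit])
    if (max(fs) > best_sc) {
      best_sc <- max(fs)
      best_lab <- blk$labels[which.max(fs)]
    }
  }
  if (length(out) == 0L) {
    out <- best_lab
    scores <- best_sc
  }
  attr(out, "scores") <- scores
  out
}

#' All fine-label scores (for ROC analysis)
#'
#' @param x feature vector.
#' @param hierarchy an `si_hierarchy`.
#' @return named numeric vector of fine scores for every label.
#' @export
label_scores <- function(x, hierarchy) {
  x <- matrix(x, nrow = 1L)
  out <- numeric(0)
  for (blk in hierarchy$fine) {
    fs <- as.numeric(.sigmoid_linear(x, blk$W, blk$b))
    names(fs) <- blk$labels
    out <- c(out, fs)
  }
  out
}

#' Train the hierarchical heads by gradient descent
#'
#' Minimises the coarse loss and every per-cluster fine loss by plain
#' (full-batch) gradient descent on the shared features `X`.
#'
#' @param hierarchy an `si_hierarchy`.
#' @param X feature batch matrix.
#' @param label_sets list of gold label sets.
#' @param epochs iterations.
#' @param learning_rate step size.
#' @return the updated hierarchy, with the loss trace in attribute
#'   `"loss_trace"`.
#' @export
train_hierarchy <- function(hierarchy, X, label_sets, epochs = 200L,
                            learning_rate = 2) {
  Yc <- coarse_targets(label_sets, hierarchy$partition)
  Yf <- lapply(hierarchy$fine, function(blk) {
    Y <- matrix(0, nrow = length(label_sets), ncol = length(blk$labels))
    for (i in seq_along(label_sets))
      Y[i, ] <- as.numeric(blk$labels %in% label_sets[[i]])
    Y
  })
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    cl <- coarse_loss(X, hierarchy$W, hierarchy$b, Yc)
    hierarchy$W <- hierarchy$W - learning_rate * cl$dW
    hierarchy$b <- hierarchy$b - learning_rate * cl$db
    total <- cl$E
    for (k in seq_along(hierarchy$fine)) {
      fl <- fine_loss(X, hierarchy$fine[[k]]$W, hierarchy$fine[[k]]$b,
                      Yf[[k]])
      hierarchy$fine[[k]]$W <- hierarchy$fine[[k]]$W - learning_rate * fl$dW
      hierarchy$fine[[k]]$b <- hierarchy$fine[[k]]$b - learning_rate * fl$db
      total <- total + fl$J
    }
    trace[e] <- total
  }
  attr(hierarchy, "loss_trace") <- trace
  hierarchy
}

# ---- flat per-label binary baseline ----------------------------------------

#' Initialise the flat binary baseline
#'
#' Every label gets an independent two-node (member, non-member) sigmoid
#' output.
#'
#' @param labels character vector of labels.
#' @param input_dim feature dimension.
#' @param seed integer seed.
#' @return an `si_dbc`: per-label list of `W` (`2 x p`) and `b` (length 2).
#' @export
dbc_init <- function(labels, input_dim, seed = 1L) {
  with_seed(derive_seed(seed, 505L), {
    structure(list(labels = labels,
                   heads = lapply(labels, function(l)
                     list(W = matrix(stats::rnorm(2L * input_dim, sd = 0.1),
                                     nrow = 2L),
                          b = numeric(2L)))),
              class = "si_dbc")
  })
}

#' Train the flat binary baseline
#'
#' Squared-error gradient descent on each label's two-node output; the
#' member node targets 1 when the label is present, the non-member node the
#' complement.
#'
#' @param dbc an `si_dbc`.
#' @param X feature batch matrix.
#' @param label_sets list of gold label sets.
#' @param epochs,learning_rate optimiser settings.
#' @return the updated `si_dbc`.
#' @export
train_dbc <- function(dbc, X, label_sets, epochs = 200L,
                      learning_rate = 2) {
  N <- nrow(X)
  for (li in seq_along(dbc$labels)) {
    pos <- vapply(label_sets, function(s) dbc$labels[li] %in% s, logical(1L))
    Y <- cbind(as.numeric(pos), as.numeric(!pos))
    head <- dbc$heads[[li]]
    for (e in seq_len(epochs)) {
      F_ <- .sigmoid_linear(X, head$W, head$b)
      G <- (2 / (2 * N)) * (F_ - Y) * F_ * (1 - F_)
      head$W <- head$W - learning_rate * t(G) %*% X
      head$b <- head$b - learning_rate * colSums(G)
    }
    dbc$heads[[li]] <- head
  }
  dbc
}

#' Flat binary prediction
#'
#' A label is included iff its member node's value strictly exceeds the
#' non-member node's; ties are excluded.
#'
#' @param x feature vector.
#' @param dbc an `si_dbc`.
#' @return character vector of predicted labels, member-node scores in
#'   attribute `"scores"`.
#' @export
dbc_predict <- function(x, dbc) {
  x <- matrix(x, nrow = 1L)
  member <- vapply(dbc$heads, function(h) {
    v <- as.numeric(.sigmoid_linear(x, h$W, h$b))
    v[1L] - v[2L]
  }, numeric(1L))
  scores <- vapply(dbc$heads, function(h)
    as.numeric(.sigmoid_linear(x, h$W, h$b))[1L], numeric(1L))
  out <- dbc$labels[member > 0]
  attr(out, "scores") <- scores[member > 0]
  out
}
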