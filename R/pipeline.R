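# End-to-end orchestration: configuration, data splitting, joint training,
# prediction, evaluation, and a JSON model archive.
#
# Training sequence: preprocess -> meta-features -> DSE matrices -> RBM
# pretraining of the Boltzmann stack -> joint fine-tuning (forward: CNN ->
# fusion -> Boltzmann label scores -> coarse/fine squared-error losses;
# backward: stochastic gradient descent through the hierarchy heads, the
# Boltzmann chain and fusion, and the CNN). Mode "hc" bypasses the Boltzmann
# machine (the hierarchy reads the CNN output directly); mode "dbc" trains
# the flat per-label two-node baseline on the CNN output.

#' Run configuration
#'
#' @param mode `"full"` (full model), `"hc"` (hierarchy on the CNN output,
#'   Boltzmann machine bypassed) or `"dbc"` (flat per-label baseline).
#' @param cnn_stages list of per-stage CNN settings (see [cnn_config()]).
#' @param fc fully-connected layer sizes; the last entry is `|y_c|`.
#' @param dropout_rate drop probability during training.
#' @param n_visible,n_h1,n_h2 Boltzmann layer sizes.
#' @param n_clusters coarse clusters `C` (capped at the label count).
#' @param tau_coarse,tau_fine decision thresholds.
#' @param pretrain_epochs layer-wise RBM pretraining epochs.
#' @param warmup_epochs CNN warm-up epochs for the full model: before the
#'   joint loop, the CNN is trained against a temporary hierarchy head that
#'   reads `y_c` directly, so the convolutional features carry label signal
#'   before the Boltzmann chain (whose stacked sigmoids attenuate gradients)
#'   is placed on top. Ignored outside `"full"` mode.
#' @param finetune_epochs joint fine-tuning epochs.
#' @param cd_weight weight of the contrastive Boltzmann step interleaved
#'   with the discriminative updates (0 disables it).
#' @param lr_cnn,lr_dbm,lr_head learning rates.
#' @param dbm_init_scale sd of the initial Boltzmann weights (larger than
#'   the 0.01 unit-test default so discriminative gradients do not vanish
#'   through the sigmoid chain).
#' @param batch_size minibatch size.
#' @param hierarchy_input `"scores"` (Boltzmann label-score vector, default)
#'   or `"h2"` (top hidden representation).
#' @param use_estimated_categories also give non-anchor words their single
#'   most probable estimated category for enrichment.
#' @param seed integer seed; mandatory for reproducibility.
#' @return an `si_run_config`.
#' @export
run_config <- function(mode = c("full", "hc", "dbc"),
                       cnn_stages = list(list(n_kernels = 4L, h = 2L,
                                              pool_k = 2L)),
                       fc = c(24L, 16L), dropout_rate = 0.5,
                       n_visible = 24L, n_h1 = 20L, n_h2 = 16L,
                       n_clusters = 10L,
                       tau_coarse = 0.5, tau_fine = 0.5,
                       pretrain_epochs = 10L, warmup_epochs = 10L,
                       finetune_epochs = 30L,
                       cd_weight = 0, lr_cnn = 0.1, lr_dbm = 0.5,
                       lr_head = 2, batch_size = 16L,
                       dbm_init_scale = 0.5,
                       hierarchy_input = c("scores", "h2"),
                       use_estimated_categories = TRUE,
                       seed = 1L) {
  structure(list(mode = match.arg(mode), cnn_stages = cnn_stages,
                 fc = as.integer(fc), dropout_rate = dropout_rate,
                 n_visible = as.integer(n_visible),
                 n_h1 = as.integer(n_h1), n_h2 = as.integer(n_h2),
                 n_clusters = as.integer(n_clusters),
                 tau_coarse = tau_coarse, tau_fine = tau_fine,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 cd_weight = cd_weight, lr_cnn = lr_cnn, lr_dbm = lr_dbm,
                 lr_head = lr_head, batch_size = as.integer(batch_size),
                 dbm_init_scale = dbm_init_scale,
                 hierarchy_input = match.arg(hierarchy_input),
                 use_estimated_categories = use_estimated_categories,
                 seed = as.integer(seed)),
            class = "si_run_config")
}

#' Random train/test split with label coverage
#'
#' Seeded split without replacement; the draw is repeated (up to
#' `max_attempts`) until every label of the corpus appears in the training
#' part, otherwise an error lists the orphan labels.
#'
#' @param corpus an `si_corpus`.
#' @param train_fraction in (0, 1); 0.7 reserves 30% for testing.
#' @param seed integer seed.
#' @param max_attempts redraw limit.
#' @return list with `train` and `test` corpora.
#' @export
split_corpus <- function(corpus, train_fraction = 0.7, seed = 1L,
                         max_attempts = 100L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(corpus$documents)
  n_train <- round(train_fraction * n)
  with_seed(derive_seed(seed, 808L), {
    for (a in seq_len(max_attempts)) {
      idx <- sample.int(n, n_train)
      train_labs <- unique(unlist(
        lapply(corpus$documents[idx], `[[`, "labels")))
      missing <- setdiff(corpus$label_vocabulary, train_labs)
      if (length(missing) == 0L) {
        tr <- si_corpus(corpus$documents[idx])
        tr$label_vocabulary <- corpus$label_vocabulary
        te <- si_corpus(corpus$documents[-idx])
        te$label_vocabulary <- corpus$label_vocabulary
        return(list(train = tr, test = te))
      }
    }
    stop("could not cover labels in train after ", max_attempts,
         " attempts; orphan labels: ", paste(missing, collapse = ", "))
  })
}

#' Seeded k-fold partition of a corpus
#'
#' @param corpus an `si_corpus`.
#' @param k number of folds (<= number of documents).
#' @param seed integer seed.
#' @return list of `k` integer vectors of document indices (disjoint,
#'   covering the corpus, near-equal sizes).
#' @export
cross_validation_folds <- function(corpus, k = 10L, seed = 1L) {
  n <- length(corpus$documents)
  if (k > n) stop(sprintf("k=%d exceeds %d documents", k, n))
  with_seed(derive_seed(seed, 909L), {
    ord <- sample.int(n)
    split(ord, rep_len(seq_len(k), n))
  })
}

# Build the enrichment category map: anchors from the input map, non-anchor
# words optionally from the estimated word-category matrix (argmax category
# when clearly above uniform).
.build_enrich_map <- function(category_map, P2, use_estimated) {
  out <- category_map
  if (use_estimated && !is.null(P2) && ncol(P2) > 1L) {
    thr <- 1.5 / ncol(P2)
    non_anchor <- setdiff(rownames(P2), names(category_map))
    for (w in non_anchor) {
      row <- P2[w, ]
      if (max(row) > thr) out[[w]] <- colnames(P2)[which.max(row)]
    }
  }
  out
}

# Forward the feature batch through the classification heads; returns loss,
# head gradients and dX.
.heads_grad <- function(X, model_heads, label_sets, mode) {
  if (mode == "dbc") {
    dbc <- model_heads
    N <- nrow(X)
    dX <- matrix(0, nrow = N, ncol = ncol(X))
    loss <- 0
    grads <- vector("list", length(dbc$heads))
    for (li in seq_along(dbc$labels)) {
      pos <- vapply(label_sets, function(s) dbc$labels[li] %in% s,
                    logical(1L))
      Y <- cbind(as.numeric(pos), as.numeric(!pos))
      h <- dbc$heads[[li]]
      F_ <- .sigmoid_linear(X, h$W, h$b)
      loss <- loss + sum((F_ - Y)^2) / (2 * N)
      G <- (2 / (2 * N)) * (F_ - Y) * F_ * (1 - F_)
      grads[[li]] <- list(W = t(G) %*% X, b = colSums(G))
      dX <- dX + G %*% h$W
    }
    return(list(loss = loss, grads = grads, dX = dX))
  }
  hierarchy <- model_heads
  Yc <- coarse_targets(label_sets, hierarchy$partition)
  cl <- coarse_loss(X, hierarchy$W, hierarchy$b, Yc)
  dX <- cl$dX
  loss <- cl$E
  fine_grads <- vector("list", length(hierarchy$fine))
  for (k in seq_along(hierarchy$fine)) {
    blk <- hierarchy$fine[[k]]
    Yk <- matrix(0, nrow = length(label_sets), ncol = length(blk$labels))
    for (i in seq_along(label_sets))
      Yk[i, ] <- as.numeric(blk$labels %in% label_sets[[i]])
    fl <- fine_loss(X, blk$W, blk$b, Yk)
    loss <- loss + fl$J
    fine_grads[[k]] <- list(W = fl$dW, b = fl$db)
    dX <- dX + fl$dX
  }
  list(loss = loss, grads = list(coarse = list(W = cl$dW, db = cl$db),
                                 fine = fine_grads), dX = dX)
}

.apply_head_grads <- function(model_heads, grads, lr, mode) {
  if (mode == "dbc") {
    for (li in seq_along(model_heads$heads)) {
      model_heads$heads[[li]]$W <- model_heads$heads[[li]]$W -
        lr * grads[[li]]$W
      model_heads$heads[[li]]$b <- model_heads$heads[[li]]$b -
        lr * grads[[li]]$b
    }
    return(model_heads)
  }
  model_heads$W <- model_heads$W - lr * grads$coarse$W
  model_heads$b <- model_heads$b - lr * grads$coarse$db
  for (k in seq_along(model_heads$fine)) {
    model_heads$fine[[k]]$W <- model_heads$fine[[k]]$W - lr * grads$fine[[k]]$W
    model_heads$fine[[k]]$b <- model_heads$fine[[k]]$b - lr * grads$fine[[k]]$b
  }
  model_heads
}

# Accumulate CNN gradient structures (a + s*b).
.axpy_cnn <- function(a, b, s) {
  for (st in seq_along(a$conv)) {
    for (ki in seq_along(a$conv[[st]]$kernels))
      a$conv[[st]]$kernels[[ki]] <- a$conv[[st]]$kernels[[ki]] +
        s * b$conv[[st]]$kernels[[ki]]
    for (nm in c("bias", "beta", "pool_bias"))
      a$conv[[st]][[nm]] <- a$conv[[st]][[nm]] + s * b$conv[[st]][[nm]]
  }
  for (l in seq_along(a$fc)) {
    a$fc[[l]]$W <- a$fc[[l]]$W + s * b$fc[[l]]$W
    a$fc[[l]]$b <- a$fc[[l]]$b + s * b$fc[[l]]$b
  }
  a
}

#' Train the full indexing model
#'
#' @param data list with `corpus` (training `si_corpus`), `embeddings`
#'   (`si_embeddings`), `label_embeddings` (matrix covering every corpus
#'   label; missing labels are an error), `category_map`, `entity_lexicon`
#'   (both optional).
#' @param config an `si_run_config`.
#' @return an `si_model` containing every fitted component plus the
#'   per-epoch loss trace.
#' @export
train_indexer <- function(data, config = run_config()) {
  corpus <- data$corpus
  if (is.null(corpus$documents[[1L]]$tokens))
    corpus <- preprocess_corpus(corpus)
  labels <- corpus$label_vocabulary
  missing <- setdiff(labels, rownames(data$label_embeddings))
  if (length(missing))
    stop("label embeddings missing for: ", paste(missing, collapse = ", "))
  category_map <- data$category_map %||% list()
  lexicon <- data$entity_lexicon %||%
    data.frame(surface = character(0), class = character(0))

  L <- average_length(corpus)
  meta <- NULL
  enrich_map <- category_map
  if (length(category_map)) {
    P1 <- word_class_distribution(corpus)
    P3 <- category_class_distribution(corpus, category_map)
    P2 <- estimate_word_categories(P1, P3, category_map,
                                   max_iter = 2000L, tol = 1e-10)
    enrich_map <- .build_enrich_map(category_map, P2,
                                    config$use_estimated_categories)
    meta <- list(P1 = P1, P2 = P2, P3 = P3)
  }

  annotations <- lapply(corpus$documents, function(d)
    tag_entities(d$tokens, lexicon))
  mats <- lapply(seq_along(corpus$documents), function(i)
    embed_document(corpus$documents[[i]]$tokens, L, data$embeddings,
                   enrich_map, annotations[[i]]))

  cnn_cfg <- cnn_config(L, data$embeddings$dim, stages = config$cnn_stages,
                        fc = config$fc,
                        dropout_rate = config$dropout_rate)
  cnn_par <- cnn_init(cnn_cfg, seed = config$seed)
  n_yc <- utils::tail(config$fc, 1L)
  ent_vocab <- unique(lexicon$class)
  ye <- t(vapply(annotations, function(an)
    entity_feature(an, ent_vocab, n_yc, seed = config$seed),
    numeric(n_yc)))

  label_sets <- lapply(corpus$documents, `[[`, "labels")
  tar <- t(vapply(label_sets, function(s) as.numeric(labels %in% s),
                  numeric(length(labels))))

  C <- min(config$n_clusters, length(labels))
  partition <- cluster_labels(
    data$label_embeddings[labels, , drop = FALSE], C, seed = config$seed)

  n_docs <- length(mats)
  set.seed(derive_seed(config$seed, 1212L))

  if (config$mode == "full" && config$warmup_epochs > 0L) {
    # stage the CNN: a throwaway hierarchy head on y_c shapes the
    # convolutional features before the Boltzmann chain goes on top
    warm_heads <- hierarchy_init(partition, n_yc,
                                 seed = derive_seed(config$seed, 77L))
    for (epoch in seq_len(config$warmup_epochs)) {
      ord <- sample.int(n_docs)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (b in batches) {
        fwd <- lapply(mats[b], function(A)
          cnn_forward(A, cnn_par, cnn_cfg,
                      mode = if (config$dropout_rate > 0) "train"
                             else "inference"))
        X <- t(vapply(fwd, `[[`, numeric(n_yc), "y"))
        hg <- .heads_grad(X, warm_heads, label_sets[b], "hc")
        warm_heads <- .apply_head_grads(warm_heads, hg$grads,
                                        config$lr_head, "hc")
        gacc <- NULL
        for (i in seq_along(b)) {
          g <- cnn_backward(hg$dX[i, ], fwd[[i]]$cache, cnn_par, cnn_cfg)
          gacc <- if (is.null(gacc)) g else .axpy_cnn(gacc, g, 1)
        }
        cnn_par <- .axpy_cnn(cnn_par, gacc, -config$lr_cnn)
      }
    }
  }

  yc0 <- t(vapply(mats, function(A)
    cnn_forward(A, cnn_par, cnn_cfg, mode = "inference")$y, numeric(n_yc)))

  dbm_par <- NULL
  if (config$mode == "full") {
    dbm_par <- dbm_params(config$n_visible, n_yc, n_yc, config$n_h1,
                          config$n_h2, length(labels), seed = config$seed,
                          init_scale = config$dbm_init_scale)
    V0 <- fuse_inputs(yc0, ye, dbm_par)
    dbm_par <- dbm_pretrain(dbm_par, V0, config$pretrain_epochs,
                            learning_rate = config$lr_dbm)$params
  }

  input_dim <- switch(config$mode,
                      full = switch(config$hierarchy_input,
                                    scores = length(labels),
                                    h2 = config$n_h2),
                      hc = n_yc, dbc = n_yc)
  heads <- if (config$mode == "dbc")
    dbc_init(labels, input_dim, seed = config$seed)
  else hierarchy_init(partition, input_dim, seed = config$seed,
                      tau_coarse = config$tau_coarse,
                      tau_fine = config$tau_fine)

  # Frozen feature standardisation in front of the heads. The Boltzmann
  # chain contracts activation variance (stacked sigmoids), leaving the
  # label-relevant signal intact but tiny; z-scoring the head inputs (with
  # statistics frozen after pretraining) both conditions the head problem
  # and rescales the gradient flowing back into the chain by 1/sd.
  X0 <- if (config$mode == "full") {
    f0 <- dbm_forward(yc0, ye, dbm_par)
    if (config$hierarchy_input == "scores") f0$scores else f0$cache$h2p
  } else yc0
  feat_mu <- colMeans(X0)
  feat_sd <- pmax(apply(X0, 2L, stats::sd), 1e-3)
  std <- function(X) sweep(sweep(X, 2L, feat_mu), 2L, feat_sd, "/")

  loss_trace <- numeric(config$finetune_epochs)
  for (epoch in seq_len(config$finetune_epochs)) {
    ord <- sample.int(n_docs)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      fwd <- lapply(mats[b], function(A)
        cnn_forward(A, cnn_par, cnn_cfg,
                    mode = if (config$dropout_rate > 0) "train"
                           else "inference"))
      Yc_batch <- t(vapply(fwd, `[[`, numeric(n_yc), "y"))
      Ye_batch <- ye[b, , drop = FALSE]
      if (config$mode == "full") {
        dbmf <- dbm_forward(Yc_batch, Ye_batch, dbm_par)
        X <- if (config$hierarchy_input == "scores") dbmf$scores
             else dbmf$cache$h2p
        hg <- .heads_grad(std(X), heads, label_sets[b], config$mode)
        dX_raw <- sweep(hg$dX, 2L, feat_sd, "/")
        bk <- dbm_backward(dX_raw, dbmf$cache, dbm_par,
                           wrt = config$hierarchy_input)
        for (nm in c("C", "E", "W1", "W2", "Wlab",
                     "bias1", "bias2", "bias3"))
          dbm_par[[nm]] <- dbm_par[[nm]] - config$lr_dbm * bk[[nm]]
        if (config$cd_weight > 0) {
          st <- dbm_train_step(list(V = fuse_inputs(Yc_batch, Ye_batch,
                                                    dbm_par),
                                    tar = tar[b, , drop = FALSE]),
                               dbm_par,
                               config$cd_weight * config$lr_dbm)
          dbm_par <- st$params
        }
        dyc <- bk$dyc
      } else {
        X <- Yc_batch
        hg <- .heads_grad(std(X), heads, label_sets[b], config$mode)
        dyc <- sweep(hg$dX, 2L, feat_sd, "/")
      }
      heads <- .apply_head_grads(heads, hg$grads, config$lr_head,
                                 config$mode)
      gacc <- NULL
      for (i in seq_along(b)) {
        g <- cnn_backward(dyc[i, ], fwd[[i]]$cache, cnn_par, cnn_cfg)
        gacc <- if (is.null(gacc)) g else .axpy_cnn(gacc, g, 1)
      }
      cnn_par <- .axpy_cnn(cnn_par, gacc, -config$lr_cnn)
      ep_loss <- ep_loss + hg$loss
    }
    loss_trace[epoch] <- ep_loss / length(batches)
  }

  structure(list(config = config, L = L, labels = labels,
                 embeddings = data$embeddings,
                 label_embeddings = data$label_embeddings[labels, ,
                                                          drop = FALSE],
                 enrich_map = enrich_map, lexicon = lexicon,
                 entity_vocab = ent_vocab, meta = meta,
                 cnn_config = cnn_cfg, cnn_params = cnn_par,
                 dbm_params = dbm_par, partition = partition,
                 feat_mu = feat_mu, feat_sd = feat_sd,
                 heads = heads, loss_trace = loss_trace),
            class = "si_model")
}

#' @export
print.si_model <- function(x, ...) {
  cat(sprintf("<si_model mode=%s: %d labels, L=%d, d=%d>\n",
              x$config$mode, length(x$labels), x$L, x$embeddings$dim))
  invisible(x)
}

# Features for one document (inference path).
.doc_features <- function(model, tokens) {
  an <- tag_entities(tokens, model$lexicon)
  A <- embed_document(tokens, model$L, model$embeddings, model$enrich_map,
                      an)
  yc <- cnn_forward(A, model$cnn_params, model$cnn_config,
                    mode = "inference")$y
  n_yc <- length(yc)
  yev <- entity_feature(an, model$entity_vocab, n_yc,
                        seed = model$config$seed)
  x <- if (model$config$mode == "full") {
    out <- dbm_forward(matrix(yc, 1L), matrix(yev, 1L), model$dbm_params)
    if (model$config$hierarchy_input == "scores") as.numeric(out$scores)
    else as.numeric(out$cache$h2p)
  } else yc
  (x - model$feat_mu) / model$feat_sd
}

#' Predict label sets for a corpus
#'
#' @param model an `si_model`.
#' @param corpus an `si_corpus` (preprocessed on the fly if needed).
#' @return list with `predicted` (list of label sets) and `scores`
#'   (documents x labels matrix of per-label scores).
#' @export
predict_corpus <- function(model, corpus) {
  if (is.null(corpus$documents[[1L]]$tokens))
    corpus <- preprocess_corpus(corpus)
  K <- length(model$labels)
  preds <- vector("list", length(corpus$documents))
  scores <- matrix(NA_real_, nrow = length(corpus$documents), ncol = K,
                   dimnames = list(NULL, model$labels))
  for (i in seq_along(corpus$documents)) {
    x <- .doc_features(model, corpus$documents[[i]]$tokens)
    if (model$config$mode == "dbc") {
      p <- dbc_predict(x, model$heads)
      sc <- vapply(model$heads$heads, function(h)
        as.numeric(.sigmoid_linear(matrix(x, 1L), h$W, h$b))[1L],
        numeric(1L))
      names(sc) <- model$heads$labels
    } else {
      p <- predict_labels(x, model$heads)
      sc <- label_scores(x, model$heads)
    }
    preds[[i]] <- as.character(p)
    scores[i, names(sc)] <- sc
  }
  list(predicted = preds, scores = scores)
}

#' Evaluate a model on a corpus
#'
#' Runs prediction on every document and computes the full macro/micro
#' metric set plus a micro-averaged ROC over all (document, label) score
#' pairs.
#'
#' @param model an `si_model`.
#' @param corpus an `si_corpus` whose labels are all known to the model
#'   (unknown labels are an error).
#' @return an `si_metrics` report.
#' @export
evaluate_model <- function(model, corpus) {
  if (is.null(corpus$documents[[1L]]$tokens))
    corpus <- preprocess_corpus(corpus)
  unknown <- setdiff(corpus$label_vocabulary, model$labels)
  if (length(unknown))
    stop("corpus labels unknown to the model: ",
         paste(unknown, collapse = ", "))
  pr <- predict_corpus(model, corpus)
  gold <- lapply(corpus$documents, `[[`, "labels")
  truth <- t(vapply(gold, function(s) model$labels %in% s,
                    logical(length(model$labels))))
  pairs <- data.frame(score = as.numeric(pr$scores),
                      truth = as.logical(truth))
  pairs <- pairs[is.finite(pairs$score), ]
  metrics_report(pr$predicted, gold, model$labels, score_pairs = pairs)
}

# ---- model archive ---------------------------------------------------------

.enc <- function(x) {
  if (is.matrix(x)) list(.mat = TRUE, dim = dim(x),
                         dimnames = dimnames(x), values = as.numeric(x))
  else if (is.list(x) && !is.data.frame(x)) lapply(x, .enc)
  else x
}

.dec <- function(x) {
  if (is.list(x) && isTRUE(x$.mat)) {
    m <- matrix(unlist(x$values), nrow = x$dim[[1L]])
    if (!is.null(x$dimnames))
      dimnames(m) <- lapply(x$dimnames, function(d)
        if (length(d)) unlist(d) else NULL)
    m
  } else if (is.list(x)) lapply(x, .dec)
  else x
}

#' Save a model as a JSON archive
#'
#' Single structured text file: a manifest (package version, mode, seed,
#' shapes) plus every parameter, matrices stored column-major with their
#' dimensions.
#'
#' @param model an `si_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  lex <- model$lexicon
  payload <- list(
    manifest = list(format = "semindex-model", version = 1L,
                    mode = model$config$mode, seed = model$config$seed,
                    L = model$L, d = model$embeddings$dim,
                    n_labels = length(model$labels)),
    config = unclass(model$config),
    L = model$L, labels = model$labels,
    embeddings = list(dim = model$embeddings$dim,
                      words = rownames(model$embeddings$vectors),
                      vectors = .enc(model$embeddings$vectors),
                      unknown = model$embeddings$unknown),
    label_embeddings = .enc(model$label_embeddings),
    enrich_map = model$enrich_map,
    lexicon = list(surface = lex$surface, class = lex$class),
    entity_vocab = model$entity_vocab,
    cnn_config = unclass(model$cnn_config),
    cnn_params = .enc(unclass(model$cnn_params)),
    dbm_params = if (!is.null(model$dbm_params))
      .enc(unclass(model$dbm_params)),
    partition = list(C = model$partition$C,
                     assignment = as.list(model$partition$assignment),
                     centers = .enc(model$partition$centers)),
    feat_mu = model$feat_mu, feat_sd = model$feat_sd,
    heads = .enc(unclass(model$heads)),
    heads_class = class(model$heads)[1L],
    loss_trace = model$loss_trace)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model archive
#'
#' @param path file written by [save_model()].
#' @return an `si_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- p$config
  cfg$cnn_stages <- lapply(cfg$cnn_stages, function(s) lapply(s, unlist))
  cfg$fc <- as.integer(unlist(cfg$fc))
  config <- structure(lapply(cfg, function(x)
    if (is.list(x)) x else x), class = "si_run_config")
  emb_mat <- .dec(p$embeddings$vectors)
  rownames(emb_mat) <- unlist(p$embeddings$words)
  embeddings <- structure(list(dim = as.integer(p$embeddings$dim),
                               vectors = emb_mat,
                               unknown = as.numeric(unlist(
                                 p$embeddings$unknown))),
                          class = "si_embeddings")
  cnn_cfg <- p$cnn_config
  cnn_cfg$stages <- lapply(cnn_cfg$stages, function(s) lapply(s, unlist))
  cnn_cfg <- structure(lapply(cnn_cfg, function(x)
    if (is.list(x)) x else x), class = "si_cnn_config")
  cnn_cfg$fc <- as.integer(unlist(p$cnn_config$fc))
  cnn_cfg$flat_size <- as.integer(p$cnn_config$flat_size)
  cnn_cfg$L <- as.integer(p$cnn_config$L)
  cnn_cfg$d <- as.integer(p$cnn_config$d)
  cnn_params <- .dec(p$cnn_params)
  cnn_params$fc <- lapply(cnn_params$fc, function(l)
    list(W = l$W, b = as.numeric(unlist(l$b))))
  cnn_params$conv <- lapply(cnn_params$conv, function(st)
    list(kernels = st$kernels,
         bias = as.numeric(unlist(st$bias)),
         beta = as.numeric(unlist(st$beta)),
         pool_bias = as.numeric(unlist(st$pool_bias))))
  class(cnn_params) <- "si_cnn_params"
  dbm_params <- if (!is.null(p$dbm_params)) {
    dp <- .dec(p$dbm_params)
    dp <- lapply(dp, function(x)
      if (is.matrix(x)) x else as.numeric(unlist(x)))
    class(dp) <- "si_dbm_params"
    dp
  }
  assignment <- vapply(p$partition$assignment, function(x)
    as.integer(x), integer(1L))
  partition <- structure(list(C = as.integer(p$partition$C),
                              assignment = assignment,
                              centers = .dec(p$partition$centers)),
                         class = "si_partition")
  heads <- .dec(p$heads)
  if (identical(p$heads_class, "si_dbc")) {
    heads$labels <- as.character(unlist(heads$labels))
    heads$heads <- lapply(heads$heads, function(h)
      list(W = h$W, b = as.numeric(unlist(h$b))))
    class(heads) <- "si_dbc"
  } else {
    heads$b <- as.numeric(unlist(heads$b))
    heads$fine <- lapply(heads$fine, function(blk)
      list(W = blk$W, b = as.numeric(unlist(blk$b)),
           labels = as.character(unlist(blk$labels))))
    heads$partition <- partition
    heads$tau_coarse <- as.numeric(heads$tau_coarse)
    heads$tau_fine <- as.numeric(heads$tau_fine)
    class(heads) <- "si_hierarchy"
  }
  structure(list(config = config, L = as.integer(p$L),
                 labels = as.character(unlist(p$labels)),
                 embeddings = embeddings,
                 label_embeddings = .dec(p$label_embeddings),
                 enrich_map = lapply(p$enrich_map, function(x)
                   as.character(unlist(x))),
                 lexicon = data.frame(
                   surface = as.character(unlist(p$lexicon$surface)),
                   class = as.character(unlist(p$lexicon$class)),
                   stringsAsFactors = FALSE),
                 entity_vocab = as.character(unlist(p$entity_vocab)),
                 meta = NULL,
                 cnn_config = cnn_cfg, cnn_params = cnn_params,
                 dbm_params = dbm_params, partition = partition,
                 feat_mu = as.numeric(unlist(p$feat_mu)),
                 feat_sd = as.numeric(unlist(p$feat_sd)),
                 heads = heads,
                 loss_trace = as.numeric(unlist(p$loss_trace))),
            class = "si_model")
}
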