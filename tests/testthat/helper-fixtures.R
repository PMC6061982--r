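# Shared fixtures and independent oracles for the test suite.

# Tiny embedding table built in code.
make_embeddings <- function(words, d, seed = 1, with_unknown = FALSE) {
  set.seed(seed)
  mat <- matrix(round(stats::rnorm(length(words) * d), 6),
                nrow = length(words))
  rownames(mat) <- words
  if (with_unknown) {
    mat <- rbind(mat, UNKNOWN = rep(0, d))
  }
  structure(list(dim = d, vectors = mat, unknown = rep(0, d)),
            class = "si_embeddings")
}

# Tiny labelled corpus built in code (tokens pre-set, no preprocessing).
make_corpus <- function(token_sets, label_sets) {
  docs <- lapply(seq_along(token_sets), function(i)
    si_document(id = paste0("d", i),
                labels = label_sets[[i]], tokens = token_sets[[i]]))
  si_corpus(docs)
}

# Central finite-difference gradient of scalar fn at x (vector).
numeric_grad <- function(fn, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (fn(x1) - fn(x2)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
}

# Adjusted Rand index between two partitions (integer vectors).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# Brute-force per-document multi-label metrics oracle: builds the full
# document x label incidence matrices and counts set intersections directly.
oracle_metrics <- function(predicted, gold, labels) {
  K <- length(labels)
  TP <- FP <- FN <- TN <- numeric(K)
  for (k in seq_len(K)) {
    for (i in seq_along(predicted)) {
      p <- labels[k] %in% predicted[[i]]
      g <- labels[k] %in% gold[[i]]
      if (p && g) TP[k] <- TP[k] + 1
      else if (p) FP[k] <- FP[k] + 1
      else if (g) FN[k] <- FN[k] + 1
      else TN[k] <- TN[k] + 1
    }
  }
  div <- function(n, d) if (d == 0) 0 else n / d
  Pk <- mapply(div, TP, TP + FP); Rk <- mapply(div, TP, TP + FN)
  F1k <- mapply(div, 2 * Pk * Rk, Pk + Rk)
  Sk <- mapply(div, TP, TP + FP + FN)
  MiP <- div(sum(TP), sum(TP) + sum(FP))
  MiR <- div(sum(TP), sum(TP) + sum(FN))
  list(MaP = mean(Pk), MaR = mean(Rk), MaF1 = mean(F1k), MaS = mean(Sk),
       MiP = MiP, MiR = MiR, MiF1 = div(2 * MiP * MiR, MiP + MiR),
       MiS = div(sum(TP), sum(TP) + sum(FP) + sum(FN)),
       TP = TP, FP = FP, FN = FN, TN = TN)
}
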