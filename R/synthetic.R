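# Seeded synthetic-corpus generator.
#
# The generator emulates the statistical structure the indexing method
# assumes: label embeddings arranged in separable clusters; multi-label
# documents whose word distributions depend on their labels (Zipf over a
# per-label sub-vocabulary plus shared background words); unbalanced label
# frequencies; anchor words carrying cluster-tied category terms; multi-token
# entity mentions with a lexicon containing 10% ambiguous single-token
# prefixes to exercise longest-match tagging; word embeddings equal to a
# label-signature vector plus noise. Everything is a pure function of the
# spec and its seed. Token strings are chosen to be invariant under the
# Porter stemmer (consonant/digit strings), so the generated text survives
# preprocessing unchanged.

#' Synthetic dataset specification
#'
#' Defaults describe a small, clearly separable two-cluster world: 2 coarse
#' clusters x 4 labels, label embeddings at separation 10 with unit noise
#' (recoverable by clustering), ~40-token documents, mild class imbalance
#' (most:least frequent = 2), 30% multi-label documents.
#'
#' @param n_clusters coarse clusters.
#' @param labels_per_cluster labels per cluster.
#' @param label_dim label-embedding dimension.
#' @param separation radius of the sphere the cluster centers sit on.
#' @param label_noise sd of label-embedding noise around its center.
#' @param vocab_per_label distinct content words owned by each label.
#' @param background_vocab shared background words.
#' @param background_rate probability a token is background rather than
#'   label-specific.
#' @param docs_per_label expected documents per label.
#' @param imbalance ratio of most to least frequent label (>= 1).
#' @param mean_length mean document token count (Poisson).
#' @param multilabel_rate probability a document carries 2-3 labels.
#' @param n_entities entity surface forms per cluster.
#' @param entity_rate probability a document receives an entity mention.
#' @param anchor_fraction fraction of each label's vocabulary that are
#'   anchor words carrying categories.
#' @param word_dim word-embedding dimension `d`.
#' @param word_noise sd of word-embedding noise around the label signature.
#' @param seed integer seed; fixed seed implies fully deterministic output.
#' @return an `si_synth_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 2L, labels_per_cluster = 4L,
                           label_dim = 10L, separation = 10, label_noise = 1,
                           vocab_per_label = 25L, background_vocab = 30L,
                           background_rate = 0.15,
                           docs_per_label = 75L, imbalance = 2,
                           mean_length = 40, multilabel_rate = 0.3,
                           n_entities = 4L, entity_rate = 0.2,
                           anchor_fraction = 0.2,
                           word_dim = 10L, word_noise = 0.3, seed = 1L) {
  spec <- list(n_clusters = as.integer(n_clusters),
               labels_per_cluster = as.integer(labels_per_cluster),
               label_dim = as.integer(label_dim),
               separation = separation, label_noise = label_noise,
               vocab_per_label = as.integer(vocab_per_label),
               background_vocab = as.integer(background_vocab),
               background_rate = background_rate,
               docs_per_label = as.integer(docs_per_label),
               imbalance = imbalance, mean_length = mean_length,
               multilabel_rate = multilabel_rate,
               n_entities = as.integer(n_entities),
               entity_rate = entity_rate,
               anchor_fraction = anchor_fraction,
               word_dim = as.integer(word_dim), word_noise = word_noise,
               seed = as.integer(seed))
  stopifnot(spec$n_clusters >= 1L, spec$labels_per_cluster >= 1L,
            spec$separation > 0, spec$vocab_per_label >= 1L,
            spec$docs_per_label >= 1L, spec$imbalance >= 1)
  structure(spec, class = "si_synth_spec")
}

#' Generate the label space
#'
#' Cluster centers are random directions scaled to radius `separation`;
#' each label embedding is its center plus `label_noise`-scaled unit
#' Gaussian noise. The planted partition is returned for recovery tests.
#'
#' @param spec an `si_synth_spec`.
#' @return list with `labels` (character), `embeddings` (matrix with label
#'   rownames), `partition` (integer vector, planted cluster per label).
#' @export
generate_label_space <- function(spec) {
  with_seed(derive_seed(spec$seed, 606L), {
    K <- spec$n_clusters * spec$labels_per_cluster
    labels <- sprintf("L%02d", seq_len(K))
    centers <- matrix(stats::rnorm(spec$n_clusters * spec$label_dim),
                      nrow = spec$n_clusters)
    centers <- spec$separation * centers / sqrt(rowSums(centers^2))
    partition <- rep(seq_len(spec$n_clusters),
                     each = spec$labels_per_cluster)
    emb <- centers[partition, , drop = FALSE] +
      matrix(stats::rnorm(K * spec$label_dim, sd = spec$label_noise),
             nrow = K)
    rownames(emb) <- labels
    list(labels = labels, embeddings = emb, partition = partition)
  })
}

#' Generate a corpus and all auxiliary tables
#'
#' @param spec an `si_synth_spec`.
#' @param label_space result of [generate_label_space()] (generated from the
#'   spec when omitted).
#' @return list with `corpus` (si_corpus), `embeddings` (si_embeddings),
#'   `label_embeddings` (matrix), `category_map`, `entity_lexicon`,
#'   `partition` and `word_labels` (named integer vector, owning label per
#'   content word).
#' @export
generate_corpus <- function(spec, label_space = generate_label_space(spec)) {
  with_seed(derive_seed(spec$seed, 707L), {
    K <- length(label_space$labels)
    d <- spec$word_dim
    part <- label_space$partition

    # per-label vocabulary and Zipf weights
    vocab <- lapply(seq_len(K), function(l)
      sprintf("w%02dq%03d", l, seq_len(spec$vocab_per_label)))
    zipf <- (1 / seq_len(spec$vocab_per_label))
    zipf <- zipf / sum(zipf)
    bg <- sprintf("bgq%03d", seq_len(spec$background_vocab))

    # entity surfaces per cluster; 10% of the lexicon are ambiguous
    # single-token prefixes of the multi-token entries
    ent_surf <- list(); ent_class <- character(0)
    for (cl in seq_len(spec$n_clusters)) {
      for (i in seq_len(spec$n_entities)) {
        ent_surf[[length(ent_surf) + 1L]] <-
          c(sprintf("entxq%dj%d", cl, i), sprintf("entyq%dj%d", cl, i))
        ent_class <- c(ent_class, sprintf("CLS%d", cl))
      }
    }
    n_amb <- max(1L, floor(0.1 * length(ent_surf)))
    for (i in seq_len(n_amb)) {
      ent_surf[[length(ent_surf) + 1L]] <- ent_surf[[i]][1L]
      ent_class <- c(ent_class, ent_class[i])
    }
    entity_lexicon <- data.frame(
      surface = vapply(ent_surf, paste, "", collapse = " "),
      class = ent_class, stringsAsFactors = FALSE)

    # anchor words carry 1-3 cluster-tied categories
    cat_terms <- lapply(seq_len(spec$n_clusters), function(cl)
      sprintf("catq%dk%d", cl, 1:3))
    category_map <- list()
    n_anchor <- ceiling(spec$anchor_fraction * spec$vocab_per_label)
    for (l in seq_len(K)) {
      for (w in vocab[[l]][seq_len(n_anchor)]) {
        k <- sample(1:3, 1L)
        category_map[[w]] <- sample(cat_terms[[part[l]]], k)
      }
    }

    # word embeddings: label signature + noise
    sig <- matrix(stats::rnorm(K * d), nrow = K)
    sig <- 3 * sig / sqrt(rowSums(sig^2))
    csig <- matrix(stats::rnorm(spec$n_clusters * d), nrow = spec$n_clusters)
    csig <- 3 * csig / sqrt(rowSums(csig^2))
    all_words <- character(0); all_vecs <- NULL
    for (l in seq_len(K)) {
      V <- matrix(rep(sig[l, ], each = spec$vocab_per_label),
                  nrow = spec$vocab_per_label) +
        matrix(stats::rnorm(spec$vocab_per_label * d, sd = spec$word_noise),
               nrow = spec$vocab_per_label)
      all_words <- c(all_words, vocab[[l]]); all_vecs <- rbind(all_vecs, V)
    }
    bgV <- matrix(stats::rnorm(spec$background_vocab * d,
                               sd = spec$word_noise),
                  nrow = spec$background_vocab)
    all_words <- c(all_words, bg); all_vecs <- rbind(all_vecs, bgV)
    ent_tokens <- unique(unlist(ent_surf))
    ecl <- as.integer(sub("^ent[xy]q(\\d+)j.*$", "\\1", ent_tokens))
    entV <- csig[ecl, , drop = FALSE] +
      matrix(stats::rnorm(length(ent_tokens) * d, sd = spec$word_noise),
             nrow = length(ent_tokens))
    all_words <- c(all_words, ent_tokens); all_vecs <- rbind(all_vecs, entV)
    cat_tokens <- unlist(cat_terms)
    ccl <- rep(seq_len(spec$n_clusters), each = 3L)
    catV <- csig[ccl, , drop = FALSE] +
      matrix(stats::rnorm(length(cat_tokens) * d, sd = spec$word_noise),
             nrow = length(cat_tokens))
    all_words <- c(all_words, cat_tokens, "UNKNOWN")
    all_vecs <- rbind(all_vecs, catV, rep(0, d))
    rownames(all_vecs) <- all_words
    embeddings <- structure(list(dim = d, vectors = all_vecs,
                                 unknown = rep(0, d)),
                            class = "si_embeddings")

    # label sampling weights: most:least frequency ratio = imbalance
    wts <- if (K == 1L) 1 else
      spec$imbalance^(-(seq_len(K) - 1) / (K - 1))
    wts <- wts / sum(wts)
    n_docs <- spec$docs_per_label * K

    docs <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      nl <- if (stats::runif(1) < spec$multilabel_rate)
        sample(2:3, 1L) else 1L
      labs_i <- sort(sample(seq_len(K), nl, prob = wts))
      len <- max(8L, stats::rpois(1L, spec$mean_length))
      words <- character(len)
      for (p in seq_len(len)) {
        if (stats::runif(1) < spec$background_rate) {
          words[p] <- sample(bg, 1L)
        } else {
          l <- labs_i[sample.int(nl, 1L)]
          words[p] <- sample(vocab[[l]], 1L, prob = zipf)
        }
      }
      if (stats::runif(1) < spec$entity_rate) {
        cl <- part[labs_i[1L]]
        cand <- which(ent_class == sprintf("CLS%d", cl) &
                        lengths(ent_surf) > 1L)
        surf <- ent_surf[[sample(cand, 1L)]]
        at <- sample.int(len, 1L)
        words <- append(words, surf, after = at)
      }
      nt <- min(6L, length(words))
      docs[[i]] <- si_document(
        id = sprintf("doc%05d", i),
        title = paste(words[seq_len(nt)], collapse = " "),
        abstract = paste(words[-seq_len(nt)], collapse = " "),
        labels = label_space$labels[labs_i])
    }
    word_labels <- rep(seq_len(K), each = spec$vocab_per_label)
    names(word_labels) <- unlist(vocab)
    list(corpus = si_corpus(docs), embeddings = embeddings,
         label_embeddings = label_space$embeddings,
         category_map = category_map, entity_lexicon = entity_lexicon,
         partition = label_space$partition, word_labels = word_labels)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the file formats the readers consume: `corpus.jsonl`,
#' `embeddings.txt`, `label_embeddings.txt` (word2vec text),
#' `categories.tsv`, `entities.tsv`.
#'
#' @param spec an `si_synth_spec`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data <- generate_corpus(spec)
  write_corpus(data$corpus, file.path(dir, "corpus.jsonl"))
  write_embeddings(data$embeddings, file.path(dir, "embeddings.txt"))
  write_embeddings(data$label_embeddings,
                   file.path(dir, "label_embeddings.txt"))
  write_category_map(data$category_map, file.path(dir, "categories.tsv"))
  write_entity_lexicon(data$entity_lexicon, file.path(dir, "entities.tsv"))
  invisible(dir)
}
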