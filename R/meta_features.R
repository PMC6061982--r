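# Meta-features: word/category/class probability matrices, lexicon entity
# tagging, and the global entity feature vector.
#
# Notation (n words, m document classes, t categories):
#   P1  n x m  row i = probability that word i appears in each class
#   P2  n x t  row i = probability that word i belongs to each category
#   P3  t x m  row k = probability that category k appears in each class
# All rows are probability vectors (non-negative, sum 1).

#' Word-by-class probability matrix (P1)
#'
#' Counts occurrences of each token in documents bearing each class and
#' row-normalises. Multi-label documents contribute their token counts to
#' every class they bear.
#'
#' @param corpus a preprocessed `si_corpus` (tokens filled).
#' @return matrix `n x m` with word rownames and class colnames; every row
#'   sums to 1.
#' @export
word_class_distribution <- function(corpus) {
  classes <- corpus$label_vocabulary
  words <- unique(unlist(lapply(corpus$documents, `[[`, "tokens")))
  P1 <- matrix(0, nrow = length(words), ncol = length(classes),
               dimnames = list(words, classes))
  for (d in corpus$documents) {
    if (length(d$tokens) == 0L) next
    tab <- table(d$tokens)
    wi <- match(names(tab), words)
    for (cl in d$labels) P1[wi, cl] <- P1[wi, cl] + as.numeric(tab)
  }
  sweep(P1, 1L, pmax(rowSums(P1), .Machine$double.eps), "/")
}

#' Category-by-class probability matrix (P3)
#'
#' For every occurrence of an anchor word (a word present in `category_map`)
#' in a document, each of the word's categories is credited to every class of
#' that document; rows are then normalised. A category with zero occurrences
#' gets a uniform row and is flagged in the `"empty_categories"` attribute.
#'
#' @param corpus a preprocessed `si_corpus`.
#' @param category_map named list word -> character vector of categories.
#' @return matrix `t x m` with category rownames and class colnames.
#' @export
category_class_distribution <- function(corpus, category_map) {
  classes <- corpus$label_vocabulary
  cats <- unique(unlist(category_map))
  P3 <- matrix(0, nrow = length(cats), ncol = length(classes),
               dimnames = list(cats, classes))
  anchors <- names(category_map)
  for (d in corpus$documents) {
    hit <- d$tokens[d$tokens %in% anchors]
    if (length(hit) == 0L) next
    for (w in hit) {
      ci <- match(category_map[[w]], cats)
      for (cl in d$labels) P3[ci, cl] <- P3[ci, cl] + 1
    }
  }
  empty <- rowSums(P3) == 0
  if (any(empty)) P3[empty, ] <- 1 / length(classes)
  P3 <- sweep(P3, 1L, rowSums(P3), "/")
  attr(P3, "empty_categories") <- cats[empty]
  P3
}

# Euclidean projection of the rows of X onto the probability simplex
# (sort-based algorithm of Held/Duchi).
.project_rows_simplex <- function(X) {
  t(apply(X, 1L, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(v - theta, 0)
  }))
}

#' Estimate the word-by-category matrix (P2)
#'
#' Recovers row-stochastic `P2` from `P1 ~ P2 %*% P3`. Anchor words (those in
#' `category_map`) are set directly to the uniform distribution over their
#' listed categories; every other row is the simplex-constrained least-squares
#' solution of `min ||P1[i,] - p %*% P3||^2`, computed by accelerated
#' projected gradient (FISTA). When `P3` has full row rank the quadratic is
#' strictly convex and a planted `P2` is recovered to machine-level accuracy.
#'
#' @param P1 word-by-class matrix (rows sum to 1).
#' @param P3 category-by-class matrix (rows sum to 1).
#' @param category_map optional named list of anchor words; rows for anchor
#'   words are fixed, not estimated.
#' @param max_iter,tol optimiser controls.
#' @return matrix `n x t`, rows on the probability simplex.
#' @export
estimate_word_categories <- function(P1, P3, category_map = NULL,
                                     max_iter = 50000L, tol = 1e-14) {
  t_cat <- nrow(P3)
  m <- ncol(P3)
  if (t_cat > m)
    warning("more categories than classes (t > m): system underdetermined, ",
            "simplex projection regularises the returned solution")
  G <- P3 %*% t(P3)                      # t x t
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  B <- P1 %*% t(P3)                      # n x t
  n <- nrow(P1)
  X <- matrix(1 / t_cat, nrow = n, ncol = t_cat,
              dimnames = list(rownames(P1), rownames(P3)))
  Y <- X
  tk <- 1
  for (it in seq_len(max_iter)) {
    grad <- Y %*% G - B
    Xn <- .project_rows_simplex(Y - grad / L)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- Xn + ((tk - 1) / tn) * (Xn - X)
    delta <- max(abs(Xn - X))
    X <- Xn
    tk <- tn
    if (delta < tol) break
  }
  if (!is.null(category_map)) {
    anchors <- intersect(names(category_map), rownames(P1))
    for (w in anchors) {
      row <- numeric(t_cat)
      ci <- match(category_map[[w]], rownames(P3))
      ci <- ci[!is.na(ci)]
      if (length(ci)) {
        row[ci] <- 1 / length(ci)
        X[w, ] <- row
      }
    }
  }
  X
}

#' Tag entities by greedy longest match
#'
#' Scans tokens left to right; at each position the longest lexicon surface
#' sequence starting there wins, and matching resumes after it, so spans never
#' overlap.
#'
#' @param tokens character vector of document tokens.
#' @param lexicon data.frame with columns `surface` (space-joined token
#'   sequences) and `class`.
#' @return an `si_entity_annotation`: data.frame with columns `start`, `end`
#'   (half-open, 1-based) and `class`.
#' @export
tag_entities <- function(tokens, lexicon) {
  surfaces <- strsplit(lexicon$surface, " ", fixed = TRUE)
  lens <- lengths(surfaces)
  keys <- vapply(surfaces, paste, "", collapse = " ")
  lut <- split(seq_along(keys), keys)
  maxlen <- if (length(lens)) max(lens) else 0L
  res <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n && maxlen > 0L) {
    matched <- FALSE
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      hit <- lut[[key]]
      if (!is.null(hit)) {
        res[[length(res) + 1L]] <-
          data.frame(start = i, end = i + len, class = lexicon$class[hit[1L]],
                     stringsAsFactors = FALSE)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(start = integer(0), end = integer(0),
                         class = character(0), stringsAsFactors = FALSE)
  class(out) <- c("si_entity_annotation", class(out))
  out
}

#' Global entity feature vector
#'
#' Counts tagged entity classes and maps the count vector to `target_dim`
#' (the CNN output length) by a fixed, seeded random projection whose columns
#' have unit norm, then rescales to unit maximum absolute value. Documents
#' with no entities yield a zero vector. The construction is a pure function
#' of (annotation counts, vocabulary, dim, seed).
#'
#' @param annotation an `si_entity_annotation`.
#' @param class_vocabulary character vector of all entity classes.
#' @param target_dim length of the output vector (must equal `|y_c|`).
#' @param seed integer seed for the projection matrix.
#' @return numeric vector of length `target_dim`.
#' @export
entity_feature <- function(annotation, class_vocabulary, target_dim,
                           seed = 1L) {
  counts <- as.numeric(table(factor(annotation$class,
                                    levels = class_vocabulary)))
  if (sum(counts) == 0) return(numeric(target_dim))
  proj <- with_seed(derive_seed(seed, 17L), {
    M <- matrix(stats::rnorm(target_dim * length(class_vocabulary)),
                nrow = target_dim)
    sweep(M, 2L, sqrt(colSums(M^2)), "/")
  })
  y <- as.numeric(proj %*% counts)
  y / max(abs(y))
}
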