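# Document word-sequence embedding (DSE): fix every document to the corpus
# average length L, enrich each surviving token with three extension words
# (entity class, then category terms, then the token itself), and embed the
# 4-word tuple per position, giving an L x (4 d) matrix.

UNKNOWN_TOKEN <- "UNKNOWN"

#' Corpus average document length
#'
#' @param corpus a preprocessed `si_corpus`.
#' @return `L = max(1, floor(mean(token counts)))`.
#' @export
average_length <- function(corpus) {
  if (length(corpus$documents) == 0L) stop("empty corpus")
  lens <- vapply(corpus$documents, function(d) length(d$tokens), integer(1L))
  max(1L, as.integer(floor(mean(lens))))
}

#' Fit a token sequence to length L
#'
#' Shorter documents are padded with the reserved `UNKNOWN` token. Longer
#' documents keep high-frequency words: distinct words are ranked by
#' in-document frequency (descending, ties broken by earliest first
#' occurrence); whole words are included in rank order until adding the next
#' word's occurrences would exceed `L`, then that boundary word contributes
#' its earliest occurrences only, up to `L`. Surviving tokens keep their
#' original relative order, so the output is a subsequence of the input.
#'
#' @param tokens character vector.
#' @param L target length (>= 1).
#' @return character vector of length exactly `L`, with attribute `"indices"`
#'   giving the original position of each kept token (`NA` for padding).
#' @export
fit_to_length <- function(tokens, L) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  n <- length(tokens)
  if (n <= L) {
    out <- c(tokens, rep(UNKNOWN_TOKEN, L - n))
    attr(out, "indices") <- c(seq_len(n), rep(NA_integer_, L - n))
    return(out)
  }
  first_pos <- match(unique(tokens), tokens)
  words <- unique(tokens)
  freq <- as.integer(table(factor(tokens, levels = words)))
  ord <- order(-freq, first_pos)          # rank: frequency desc, earliest first
  keep <- integer(0)
  budget <- L
  for (w in words[ord]) {
    pos <- which(tokens == w)
    if (length(pos) <= budget) {
      keep <- c(keep, pos)
      budget <- budget - length(pos)
      if (budget == 0L) break
    } else {
      keep <- c(keep, pos[seq_len(budget)])  # earliest occurrences survive
      budget <- 0L
      break
    }
  }
  keep <- sort(keep)
  out <- tokens[keep]
  attr(out, "indices") <- keep
  out
}

#' Build the 4-word enrichment tuple for one token
#'
#' The three extension slots are filled, in priority order, from the token's
#' entity class (if tagged), then its category terms in map order; remaining
#' slots repeat the token itself.
#'
#' @param token the base word.
#' @param categories character vector of category terms for this token (may
#'   be empty).
#' @param entity_class optional entity class string (`NA` or `NULL` if
#'   untagged).
#' @return character vector of length 4: `c(token, x1, x2, x3)`.
#' @export
enrich_token <- function(token, categories = character(0),
                         entity_class = NULL) {
  ext <- character(0)
  if (!is.null(entity_class) && length(entity_class) == 1L &&
      !is.na(entity_class))
    ext <- entity_class
  ext <- c(ext, categories)
  ext <- ext[seq_len(min(3L, length(ext)))]
  c(token, ext, rep(token, 3L - length(ext)))
}

#' Embed a document as an L x (4 d) matrix
#'
#' Applies [fit_to_length()], enriches every position with
#' [enrich_token()] (padding `UNKNOWN` positions carry no categories or
#' entities), and replaces each of the 4 words by its embedding vector
#' (the table's unknown vector when absent). Row `p` is the concatenation of
#' the 4 sub-vectors of position `p`.
#'
#' @param tokens preprocessed token vector.
#' @param L target length.
#' @param embeddings an `si_embeddings` of dimension `d`.
#' @param category_map named list word -> categories (anchors).
#' @param annotation optional `si_entity_annotation` over `tokens`.
#' @return numeric matrix `L x (4 d)`.
#' @export
embed_document <- function(tokens, L, embeddings, category_map = list(),
                           annotation = NULL) {
  fitted <- fit_to_length(tokens, L)
  idx <- attr(fitted, "indices")
  ent_class <- rep(NA_character_, length(tokens))
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    for (r in seq_len(nrow(annotation)))
      ent_class[annotation$start[r]:(annotation$end[r] - 1L)] <-
        annotation$class[r]
  }
  d <- embeddings$dim
  words4 <- matrix("", nrow = L, ncol = 4L)
  for (p in seq_len(L)) {
    tok <- fitted[p]
    orig <- idx[p]
    ec <- if (!is.na(orig)) ent_class[orig] else NA_character_
    cats <- if (tok %in% names(category_map)) category_map[[tok]]
            else character(0)
    words4[p, ] <- enrich_token(tok, categories = cats, entity_class = ec)
  }
  out <- matrix(0, nrow = L, ncol = 4L * d)
  for (s in 1:4)
    out[, ((s - 1L) * d + 1L):(s * d)] <- embedding_lookup(embeddings,
                                                           words4[, s])
  out
}
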