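# Corpus, embedding-table and mapping-table IO plus text preprocessing.
#
# A corpus is a plain list with class "si_corpus":
#   documents        list of si_document
#   label_vocabulary character vector (ordered union of document labels)
# A document is a list with class "si_document":
#   id, title, abstract  strings
#   labels               character vector (set of heading identifiers)
#   tokens               character vector, filled by preprocess_corpus()

#' Bundled English stopword list
#'
#' @return character vector of lowercase stopwords (versioned text fixture
#'   shipped with the package).
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "semindex")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Tokenize and normalise free text
#'
#' Lowercases, splits on non-alphanumeric characters (pure-numeric tokens are
#' kept: abstracts contain rate constants), removes stopwords, then stems each
#' surviving token. Token order is preserved. Empty input yields an empty
#' token vector.
#'
#' @param text character scalar (arbitrary unicode; titles and abstracts are
#'   concatenated by the caller, title first).
#' @param stopwords character vector of lowercase stopwords.
#' @param stemmer `"porter"` (default) or `"none"`.
#' @return character vector of normalised tokens.
#' @examples
#' preprocess_text("Kinetics of bacterial bioluminescence.")
#' @export
preprocess_text <- function(text, stopwords = default_stopwords(),
                            stemmer = c("porter", "none")) {
  stemmer <- match.arg(stemmer)
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!(toks %in% stopwords)]
  if (stemmer == "porter") toks <- porter_stem(toks)
  toks
}

#' Construct a document
#'
#' @param id unique document identifier.
#' @param title,abstract text fields.
#' @param labels character vector of label identifiers.
#' @param tokens optional pre-computed token vector.
#' @return an `si_document`.
#' @export
si_document <- function(id, title = "", abstract = "", labels = character(0),
                        tokens = NULL) {
  structure(list(id = as.character(id), title = title, abstract = abstract,
                 labels = as.character(labels), tokens = tokens),
            class = "si_document")
}

#' Construct a corpus from documents
#'
#' @param documents list of [si_document()] objects.
#' @return an `si_corpus`; `label_vocabulary` is the ordered union of document
#'   labels (first-appearance order).
#' @export
si_corpus <- function(documents) {
  ids <- vapply(documents, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate document ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labs <- unique(unlist(lapply(documents, `[[`, "labels")))
  structure(list(documents = documents,
                 label_vocabulary = as.character(labs %||% character(0))),
            class = "si_corpus")
}

#' @export
print.si_corpus <- function(x, ...) {
  cat(sprintf("<si_corpus: %d documents, %d labels>\n",
              length(x$documents), length(x$label_vocabulary)))
  invisible(x)
}

#' Tokenize every document of a corpus in place
#'
#' Title and abstract are concatenated (title first) before tokenization; the
#' downstream model never distinguishes them.
#'
#' @param corpus an `si_corpus`.
#' @inheritParams preprocess_text
#' @return the corpus with `tokens` filled on every document.
#' @export
preprocess_corpus <- function(corpus, stopwords = default_stopwords(),
                              stemmer = "porter") {
  corpus$documents <- lapply(corpus$documents, function(d) {
    d$tokens <- preprocess_text(paste(d$title, d$abstract),
                                stopwords = stopwords, stemmer = stemmer)
    d
  })
  corpus
}

#' Read a corpus from a JSON-lines file
#'
#' One JSON object per line with keys `id` (string), `title` (string),
#' `abstract` (string) and `labels` (array of strings). Malformed lines and
#' missing `id`/`labels` fields are reported with their line numbers.
#'
#' @param path file path.
#' @return an `si_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("line %d: malformed JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    if (is.null(obj$id))
      stop(sprintf("line %d: missing 'id' field", i), call. = FALSE)
    if (is.null(obj$labels))
      stop(sprintf("line %d: missing 'labels' field", i), call. = FALSE)
    docs[[i]] <- si_document(id = obj$id, title = obj$title %||% "",
                             abstract = obj$abstract %||% "",
                             labels = unlist(obj$labels))
  }
  si_corpus(docs)
}

#' Write a corpus as JSON-lines
#'
#' @param corpus an `si_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$documents, function(d) {
    jsonlite::toJSON(list(id = jsonlite::unbox(d$id),
                          title = jsonlite::unbox(d$title),
                          abstract = jsonlite::unbox(d$abstract),
                          labels = d$labels))
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- embedding tables -------------------------------------------------------

#' Read a word2vec-style text embedding table
#'
#' First line `"count dim"`, then one row per word: `word v1 ... vdim`.
#' A row for the reserved word `UNKNOWN` becomes the table's unknown vector;
#' when absent the unknown vector defaults to the zero vector.
#'
#' @param path file path.
#' @return an `si_embeddings` list with fields `dim`, `vectors` (named matrix,
#'   one row per word) and `unknown` (length-`dim` vector).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(header) != 2L)
    stop("line 1: expected header 'count dim'", call. = FALSE)
  d <- as.integer(header[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  words <- character(length(body))
  mat <- matrix(0, nrow = length(body), ncol = d)
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(parts) != d + 1L)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, d + 1L, length(parts)), call. = FALSE)
    words[i] <- parts[1L]
    mat[i, ] <- as.numeric(parts[-1L])
  }
  rownames(mat) <- words
  unknown <- if ("UNKNOWN" %in% words) mat["UNKNOWN", ] else rep(0, d)
  structure(list(dim = d, vectors = mat, unknown = unknown),
            class = "si_embeddings")
}

#' Write an embedding table in word2vec text format
#'
#' Values are printed with 6 decimal digits, the round-trip precision the
#' format guarantees.
#'
#' @param embeddings an `si_embeddings` object or a named numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  mat <- if (inherits(embeddings, "si_embeddings")) embeddings$vectors
         else embeddings
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(rownames(mat)[i],
                     paste(sprintf("%.6f", mat[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Look up word vectors, falling back to the unknown vector
#'
#' @param embeddings an `si_embeddings`.
#' @param words character vector.
#' @return matrix `length(words) x dim`.
#' @export
embedding_lookup <- function(embeddings, words) {
  idx <- match(words, rownames(embeddings$vectors))
  out <- matrix(rep(embeddings$unknown, each = length(words)),
                nrow = length(words))
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- embeddings$vectors[idx[hit], , drop = FALSE]
  out
}

# ---- auxiliary mapping tables ----------------------------------------------

#' Read a word-to-category mapping table
#'
#' TSV; column 1 is a word, columns 2..k its category terms.
#'
#' @param path file path.
#' @return named list mapping word to character vector of categories.
#' @export
read_category_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    out[[parts[1L]]] <- parts[-1L]
  }
  out
}

#' @rdname read_category_map
#' @param category_map named list as returned by `read_category_map()`.
#' @export
write_category_map <- function(category_map, path) {
  lines <- vapply(names(category_map), function(w)
    paste(c(w, category_map[[w]]), collapse = "\t"), character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an entity lexicon
#'
#' TSV; column 1 is a space-joined surface token sequence, column 2 the entity
#' class.
#'
#' @param path file path.
#' @return data.frame with columns `surface` (character) and `class`
#'   (character).
#' @export
read_entity_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(surface = vapply(parts, `[[`, "", 1L),
             class = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' @rdname read_entity_lexicon
#' @param lexicon data.frame with columns `surface` and `class`.
#' @export
write_entity_lexicon <- function(lexicon, path) {
  writeLines(paste(lexicon$surface, lexicon$class, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}
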