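# Porter stemming algorithm (the classic 1980 suffix-stripping procedure),
# implemented in base R so the package has no external NLP dependency.
#
# Conventions follow the original description: a word is scanned as
# [C](VC){m}[V]; 'y' counts as a consonant at the start of a word or after a
# vowel, and as a vowel after a consonant. Digits are treated as consonants
# (abstracts contain rate constants; such tokens are left untouched because
# they contain no vowels). Words of length <= 2 are returned unchanged.

.porter_cons <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cons <- logical(n)
  for (i in seq_len(n)) {
    c1 <- ch[i]
    cons[i] <- if (c1 %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (c1 == "y") {
      if (i == 1L) TRUE else !cons[i - 1L]
    } else TRUE
  }
  cons
}

.porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cc <- .porter_cons(stem)
  n <- length(cc)
  if (n < 2L) return(0L)
  sum(cc[-1L] & !cc[-n])
}

.porter_has_vowel <- function(stem) {
  nzchar(stem) && any(!.porter_cons(stem))
}

.porter_ends_double_cons <- function(stem) {
  n <- nchar(stem)
  n >= 2L &&
    substr(stem, n, n) == substr(stem, n - 1L, n - 1L) &&
    .porter_cons(stem)[n]
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y.
.porter_ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  cc <- .porter_cons(stem)
  last <- substr(stem, n, n)
  cc[n - 2L] && !cc[n - 1L] && cc[n] && !(last %in% c("w", "x", "y"))
}

# Apply the longest matching suffix rule of a step; if the longest match's
# condition fails no shorter suffix is tried (this is what keeps e.g.
# "rational" from becoming "rate").
.porter_rule <- function(word, suffixes, replacements, cond) {
  ord <- order(nchar(suffixes), decreasing = TRUE)
  for (i in ord) {
    suf <- suffixes[i]
    ns <- nchar(suf)
    nw <- nchar(word)
    if (nw > ns && substr(word, nw - ns + 1L, nw) == suf) {
      stem <- substr(word, 1L, nw - ns)
      if (cond(stem)) return(paste0(stem, replacements[i]))
      return(word)
    }
  }
  word
}

.porter_step1 <- function(word) {
  n <- nchar(word)
  # 1a
  if (endsWith(word, "sses")) {
    word <- substr(word, 1L, n - 2L)
  } else if (endsWith(word, "ies")) {
    word <- paste0(substr(word, 1L, n - 3L), "i")
  } else if (!endsWith(word, "ss") && endsWith(word, "s")) {
    word <- substr(word, 1L, n - 1L)
  }
  # 1b
  n <- nchar(word)
  cleanup <- FALSE
  if (endsWith(word, "eed")) {
    stem <- substr(word, 1L, n - 3L)
    if (.porter_m(stem) > 0L) word <- substr(word, 1L, n - 1L)
  } else if (endsWith(word, "ed")) {
    stem <- substr(word, 1L, n - 2L)
    if (.porter_has_vowel(stem)) { word <- stem; cleanup <- TRUE }
  } else if (endsWith(word, "ing")) {
    stem <- substr(word, 1L, n - 3L)
    if (.porter_has_vowel(stem)) { word <- stem; cleanup <- TRUE }
  }
  if (cleanup) {
    if (endsWith(word, "at") || endsWith(word, "bl") || endsWith(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_ends_double_cons(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- substr(word, 1L, nchar(word) - 1L)
    } else if (.porter_m(word) == 1L && .porter_ends_cvc(word)) {
      word <- paste0(word, "e")
    }
  }
  # 1c
  n <- nchar(word)
  if (endsWith(word, "y") && .porter_has_vowel(substr(word, 1L, n - 1L)))
    word <- paste0(substr(word, 1L, n - 1L), "i")
  word
}

.porter_step2 <- function(word) {
  .porter_rule(
    word,
    c("ational", "tional", "enci", "anci", "izer", "abli", "alli", "entli",
      "eli", "ousli", "ization", "ation", "ator", "alism", "iveness",
      "fulness", "ousness", "aliti", "iviti", "biliti"),
    c("ate", "tion", "ence", "ance", "ize", "able", "al", "ent",
      "e", "ous", "ize", "ate", "ate", "al", "ive",
      "ful", "ous", "al", "ive", "ble"),
    function(stem) .porter_m(stem) > 0L
  )
}

.porter_step3 <- function(word) {
  .porter_rule(
    word,
    c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    c("ic", "", "al", "ic", "ic", "", ""),
    function(stem) .porter_m(stem) > 0L
  )
}

.porter_step4 <- function(word) {
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")
  ord <- order(nchar(sufs), decreasing = TRUE)
  for (i in ord) {
    suf <- sufs[i]
    ns <- nchar(suf); nw <- nchar(word)
    if (nw > ns && substr(word, nw - ns + 1L, nw) == suf) {
      stem <- substr(word, 1L, nw - ns)
      ok <- .porter_m(stem) > 1L
      if (suf == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) return(stem)
      return(word)
    }
  }
  word
}

.porter_step5 <- function(word) {
  n <- nchar(word)
  if (endsWith(word, "e")) {
    stem <- substr(word, 1L, n - 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_ends_cvc(stem))) word <- stem
  }
  n <- nchar(word)
  if (.porter_m(word) > 1L && .porter_ends_double_cons(word) &&
      endsWith(word, "l"))
    word <- substr(word, 1L, n - 1L)
  word
}

#' Porter stemmer
#'
#' Reduces English words to their Porter (1980) stems. Vectorised over words;
#' words of one or two characters are returned unchanged, as is conventional.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("kinetics", "bacterial", "bioluminescence"))
#' @export
porter_stem <- function(words) {
  vapply(words, function(w) {
    if (nchar(w) <= 2L) return(w)
    w <- .porter_step1(w)
    w <- .porter_step2(w)
    w <- .porter_step3(w)
    w <- .porter_step4(w)
    .porter_step5(w)
  }, character(1L), USE.NAMES = FALSE)
}
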