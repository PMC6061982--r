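# Multi-label evaluation: per-class contingency counts, macro/micro
# precision/recall/F1, Jaccard-style similarity, and ROC curves.
#
# Conventions: a 0/0 ratio (class never predicted and never gold) contributes
# 0. Macro metrics average per-class values; micro metrics pool the counts
# over classes first. Similarity S = TP/(TP+FP+FN) is reported both macro
# (per-class mean) and micro (pooled).

#' Per-class contingency counts
#'
#' For every class: TP = documents carrying the label in both prediction and
#' gold; FP = predicted only; FN = gold only; TN = neither. Row sums always
#' equal the number of documents.
#'
#' @param predicted list of character vectors (predicted label sets).
#' @param gold list of character vectors (gold label sets), same length.
#' @param labels character vector, the label vocabulary.
#' @return data.frame with columns `label`, `TP`, `FP`, `FN`, `TN`.
#' @export
class_counts <- function(predicted, gold, labels) {
  if (length(predicted) != length(gold))
    stop("predicted and gold must have equal length")
  seen <- unique(c(unlist(predicted), unlist(gold)))
  bad <- setdiff(seen, labels)
  if (length(bad))
    stop("labels outside vocabulary: ", paste(bad, collapse = ", "))
  n <- length(predicted)
  P <- vapply(labels, function(l)
    vapply(predicted, function(s) l %in% s, logical(1L)), logical(n))
  G <- vapply(labels, function(l)
    vapply(gold, function(s) l %in% s, logical(1L)), logical(n))
  P <- matrix(P, nrow = n); G <- matrix(G, nrow = n)
  data.frame(label = labels,
             TP = colSums(P & G), FP = colSums(P & !G),
             FN = colSums(!P & G), TN = colSums(!P & !G),
             row.names = NULL, stringsAsFactors = FALSE)
}

.safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Macro-averaged precision, recall, F1 and similarity
#'
#' Per class: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`,
#' `S = TP/(TP+FP+FN)`; macro values are unweighted means over classes
#' (0/0 -> 0).
#'
#' @param counts data.frame from [class_counts()].
#' @return named list `MaP`, `MaR`, `MaF1`, `MaS`.
#' @export
macro_metrics <- function(counts) {
  P <- .safe_div(counts$TP, counts$TP + counts$FP)
  R <- .safe_div(counts$TP, counts$TP + counts$FN)
  F1 <- .safe_div(2 * P * R, P + R)
  S <- .safe_div(counts$TP, counts$TP + counts$FP + counts$FN)
  list(MaP = mean(P), MaR = mean(R), MaF1 = mean(F1), MaS = mean(S))
}

#' Micro-averaged precision, recall, F1 and similarity
#'
#' Counts are pooled over classes before the formulas are applied once, so
#' `MiF1` is exactly the harmonic mean of `MiP` and `MiR`.
#'
#' @param counts data.frame from [class_counts()].
#' @return named list `MiP`, `MiR`, `MiF1`, `MiS`.
#' @export
micro_metrics <- function(counts) {
  tp <- sum(counts$TP); fp <- sum(counts$FP); fn <- sum(counts$FN)
  MiP <- .safe_div(tp, tp + fp)
  MiR <- .safe_div(tp, tp + fn)
  list(MiP = MiP, MiR = MiR,
       MiF1 = .safe_div(2 * MiP * MiR, MiP + MiR),
       MiS = .safe_div(tp, tp + fp + fn))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the distinct scores in descending order (equal
#' scores are grouped into one step), predicting positive at
#' `score >= threshold`. The curve starts at (0, 0) and ends at (1, 1); the
#' AUC is the trapezoid-rule area.
#'
#' @param scores numeric vector.
#' @param truth logical or 0/1 vector; must contain at least one positive
#'   and one negative.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   scalar `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L)
    stop("roc_curve needs at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / npos,
                numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / nneg,
                numeric(1L))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Full multi-label metrics report
#'
#' @param predicted,gold lists of label sets.
#' @param labels label vocabulary.
#' @param score_pairs optional data.frame with columns `score` and `truth`
#'   over all (document, label) pairs; when supplied a micro-averaged ROC is
#'   included.
#' @return an `si_metrics` list with `counts`, `macro`, `micro` and
#'   optionally `roc`.
#' @export
metrics_report <- function(predicted, gold, labels, score_pairs = NULL) {
  counts <- class_counts(predicted, gold, labels)
  rep <- list(counts = counts,
              macro = macro_metrics(counts),
              micro = micro_metrics(counts))
  if (!is.null(score_pairs) &&
      length(unique(score_pairs$truth)) == 2L)
    rep$roc <- roc_curve(score_pairs$score, score_pairs$truth)
  structure(rep, class = "si_metrics")
}

#' @export
print.si_metrics <- function(x, ...) {
  cat(sprintf("micro: P=%.4f R=%.4f F1=%.4f S=%.4f\n",
              x$micro$MiP, x$micro$MiR, x$micro$MiF1, x$micro$MiS))
  cat(sprintf("macro: P=%.4f R=%.4f F1=%.4f S=%.4f\n",
              x$macro$MaP, x$macro$MaR, x$macro$MaF1, x$macro$MaS))
  if (!is.null(x$roc)) cat(sprintf("micro ROC AUC: %.4f\n", x$roc$auc))
  invisible(x)
}

#' Write a metrics report as JSON and TSV
#'
#' @param report an `si_metrics`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(macro = report$macro, micro = report$micro),
                       file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(report$counts, file.path(dir, "class_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$roc))
    utils::write.table(report$roc$points, file.path(dir, "roc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
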