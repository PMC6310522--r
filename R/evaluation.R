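# Internal evaluation protocol: an 11x11 confusion matrix (rows = true
# labels, columns = predicted, canonical order) built from the candidate
# pairs with generated negatives, multi-label gold pairs duplicated with
# the same predicted label, and cross-sentence gold annotations counted as
# false negatives. Percentages are reported to 2 decimals (round
# half-even); the exact counts stay available for rational comparisons.

#' Wrap an 11x11 count matrix as a confusion matrix
#'
#' @param counts 11x11 non-negative integer matrix, rows = true labels,
#'   columns = predicted labels, in canonical label order. Dimnames are
#'   imposed.
#' @return A \code{cprex_confusion}.
#' @export
confusion_matrix_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 11, ncol(counts) == 11, all(counts >= 0))
  dimnames(counts) <- list(true = cpr_labels(), predicted = cpr_labels())
  structure(counts, class = c("cprex_confusion", class(counts)))
}

#' Read a confusion matrix from a TSV file
#'
#' Expects 11 data rows and a header of the 11 predicted classes, rows in
#' canonical true-label order.
#'
#' @param path TSV file.
#' @return A \code{cprex_confusion}.
#' @export
read_confusion_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  confusion_matrix_from_counts(as.matrix(df))
}

#' Build the confusion matrix for a gold standard and a prediction set
#'
#' Every candidate pair contributes one count at (gold, predicted); pairs
#' without a prediction default to predicted \code{negative}. Multi-label
#' gold pairs contribute one count per gold label, each with the same
#' predicted label. Cross-sentence gold annotations contribute
#' (gold, negative) counts. Predictions for unknown pair keys are ignored
#' with a warning.
#'
#' @param gold_pairs Candidate pairs (\code{cprex_pairs}) with their gold
#'   labels (negatives included).
#' @param predset A \code{cprex_predictions}.
#' @param cross_sentence Optional data frame from
#'   \code{\link{cross_sentence_relations}}.
#' @return A \code{cprex_confusion}.
#' @export
build_confusion_matrix <- function(gold_pairs, predset,
                                   cross_sentence = NULL) {
  m <- matrix(0L, 11, 11)
  gk <- paste(gold_pairs$pmid, gold_pairs$chem_id, gold_pairs$gene_id,
              sep = "\r")
  pk <- paste(predset$pmid, predset$arg1, predset$arg2, sep = "\r")
  unknown <- !(pk %in% gk)
  if (any(unknown)) {
    warning(sum(unknown), " prediction(s) for unknown pair keys ignored")
  }
  pred_of <- stats::setNames(predset$label, pk)
  neg <- label_index("negative")
  for (i in seq_len(nrow(gold_pairs))) {
    p <- pred_of[gk[i]]
    pid <- if (is.na(p)) neg else label_index(p)
    for (lab in gold_pairs$gold[[i]]) {
      gid <- label_index(lab)
      m[gid, pid] <- m[gid, pid] + 1L
    }
  }
  if (!is.null(cross_sentence) && nrow(cross_sentence) > 0) {
    for (lab in cross_sentence$label) {
      gid <- label_index(lab)
      m[gid, neg] <- m[gid, neg] + 1L
    }
  }
  confusion_matrix_from_counts(m)
}

metric_percent <- function(x) round(100 * x, 2)

#' Micro-averaged precision, recall and F-score over a class subset
#'
#' TP = sum of the subset diagonal; predicted = sum of the subset columns;
#' gold = sum of the subset row totals. P = TP/predicted, R = TP/gold,
#' F = 2PR/(P+R), with the 0 convention when a denominator is 0. Over all
#' 11 classes of a single-label task the micro F equals overall accuracy.
#'
#' @param cm A \code{cprex_confusion}.
#' @param classes Non-empty character vector of class labels.
#' @return List with percentages (\code{precision}, \code{recall},
#'   \code{f}, 2 decimals) and exact counts (\code{tp}, \code{predicted},
#'   \code{gold}).
#' @export
micro_metrics <- function(cm, classes = cpr_eval_classes()) {
  stopifnot(length(classes) >= 1)
  idx <- label_index(classes)
  tp <- sum(diag(cm)[idx])
  predicted <- sum(cm[, idx])
  gold <- sum(cm[idx, ])
  p <- if (predicted > 0) tp / predicted else 0
  r <- if (gold > 0) tp / gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = metric_percent(p), recall = metric_percent(r),
       f = metric_percent(f), tp = tp, predicted = predicted, gold = gold)
}

#' Per-class precision, recall and F-score
#'
#' @param cm A \code{cprex_confusion}.
#' @return Data frame with one row per class: precision, recall, f
#'   (percent, 2 decimals) and the underlying counts.
#' @export
per_class_metrics <- function(cm) {
  tp <- diag(cm)
  predicted <- colSums(cm)
  gold <- rowSums(cm)
  p <- ifelse(predicted > 0, tp / predicted, 0)
  r <- ifelse(gold > 0, tp / gold, 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  data.frame(class = cpr_labels(), precision = metric_percent(p),
             recall = metric_percent(r), f = metric_percent(f),
             tp = as.integer(tp), predicted = as.integer(predicted),
             gold = as.integer(gold), row.names = NULL,
             stringsAsFactors = FALSE)
}
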