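#' Canonical relation label set
#'
#' The task is formulated as 11-class classification: ten grouped
#' chemical-protein relation (CPR) classes plus an explicit \code{negative}
#' class for candidate pairs with no annotated relation. The canonical
#' ordering (CPR:1 .. CPR:10, negative) fixes class indices 1..11 everywhere
#' in the package (confusion matrices, network output layers, tie-breaking).
#'
#' @return Character vector of the 11 labels in canonical order.
#' @export
#' @examples
#' cpr_labels()
cpr_labels <- function() {
  c(paste0("CPR:", 1:10), "negative")
}

#' Officially evaluated relation classes
#'
#' Only five of the ten CPR classes count towards the official task metric:
#' CPR:3 (upregulator), CPR:4 (downregulator), CPR:5 (agonist),
#' CPR:6 (antagonist) and CPR:9 (substrate/product).
#'
#' @return Character vector of the five evaluated class labels.
#' @export
cpr_eval_classes <- function() {
  paste0("CPR:", c(3, 4, 5, 6, 9))
}

#' Map labels to canonical class indices
#'
#' @param labels Character vector of labels from \code{\link{cpr_labels}}.
#' @return Integer indices in 1..11.
#' @export
label_index <- function(labels) {
  idx <- match(labels, cpr_labels())
  if (anyNA(idx)) {
    stop("unknown label(s): ", paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}
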