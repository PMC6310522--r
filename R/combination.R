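# System combination: merging two systems' prediction sets as a union (OR)
# or intersection (AND) with per-system min-max confidence normalization
# and class filtering. Both systems score in their own confidence ranges,
# so scores are normalized into [0, 1] before being compared.

#' Min-max normalize the confidences of a prediction set
#'
#' (c - min) / (max - min) over all raw confidences in the set; a
#' degenerate range (max = min) maps every entry to 0.5. An empty set is a
#' no-op.
#'
#' @param predset A \code{cprex_predictions}.
#' @return The set with the \code{normalized} column filled in.
#' @export
normalize_confidences <- function(predset) {
  if (nrow(predset) == 0) return(predset)
  lo <- min(predset$confidence)
  hi <- max(predset$confidence)
  predset$normalized <- if (hi > lo) (predset$confidence - lo) / (hi - lo)
                        else rep(0.5, nrow(predset))
  predset
}

#' Filter a prediction set by class group
#'
#' \code{all}: unchanged (11 classes); \code{positive}: drop
#' \code{negative} entries (10 classes); \code{eval}: keep only the five
#' officially evaluated classes.
#'
#' @param predset A \code{cprex_predictions}.
#' @param mode One of "all", "positive", "eval".
#' @return Filtered prediction set.
#' @export
filter_classes <- function(predset, mode = c("all", "positive", "eval")) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    all = rep(TRUE, nrow(predset)),
    positive = predset$label != "negative",
    eval = predset$label %in% cpr_eval_classes()
  )
  out <- predset[keep, , drop = FALSE]
  class(out) <- class(predset)
  rownames(out) <- NULL
  out
}

#' Combine two systems' prediction sets
#'
#' OR keeps every pair key present in either set; AND only keys present in
#' both. When both systems predict for a key, the entry with the higher
#' normalized confidence wins (ties go to the first set). Both inputs must
#' already be normalized (and filtered with the same class mode).
#'
#' @param a,b Normalized \code{cprex_predictions}.
#' @param op "OR" (union) or "AND" (intersection).
#' @return Combined prediction set, ordered by key.
#' @export
combine_predictions <- function(a, b, op = c("OR", "AND")) {
  op <- match.arg(op)
  if ((nrow(a) > 0 && anyNA(a$normalized)) ||
      (nrow(b) > 0 && anyNA(b$normalized))) {
    stop("combine_predictions requires normalized inputs; ",
         "call normalize_confidences() first")
  }
  ka <- paste(a$pmid, a$arg1, a$arg2, sep = "\r")
  kb <- paste(b$pmid, b$arg1, b$arg2, sep = "\r")
  both <- intersect(ka, kb)
  pick <- function(df, sel) { out <- df[sel, , drop = FALSE]; out }
  resolved <- NULL
  if (length(both) > 0) {
    ia <- match(both, ka)
    ib <- match(both, kb)
    from_a <- a$normalized[ia] >= b$normalized[ib]
    resolved <- rbind(pick(a, ia[from_a]), pick(b, ib[!from_a]))
  }
  out <- if (op == "OR") {
    rbind(resolved, pick(a, !(ka %in% both)), pick(b, !(kb %in% both)))
  } else {
    resolved
  }
  if (is.null(out) || nrow(out) == 0) {
    out <- prediction_set(character(), character(), character(),
                          character(), numeric())
  }
  out <- out[order(out$pmid, out$arg1, out$arg2, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cprex_predictions", "data.frame")
  out
}
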