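# High-level plumbing: encoding a corpus split, persisting models, and the
# evaluate convenience wrapper used by the command-line interface.

#' Encode a corpus split end-to-end
#'
#' Generates candidate pairs, builds (or reuses) the POS/DT vocabularies
#' and encodes every pair. Build vocabularies on the training split and
#' pass them in for dev/test splits.
#'
#' @param corpus A parsed corpus.
#' @param vectors Word vectors.
#' @param config A \code{\link{model_config}}.
#' @param vocabs Vocabularies from the training split, or NULL to build
#'   them from this corpus.
#' @return List with \code{pairs}, \code{examples}, \code{vocabs},
#'   \code{cross_sentence}.
#' @export
encode_split <- function(corpus, vectors, config, vocabs = NULL) {
  pairs <- generate_candidate_pairs(corpus)
  if (is.null(vocabs)) vocabs <- corpus_vocabularies(pairs, corpus, config)
  list(pairs = pairs,
       examples = encode_corpus(pairs, corpus, vectors, vocabs$pos_vocab,
                                vocabs$dt_vocab, config),
       vocabs = vocabs,
       cross_sentence = cross_sentence_relations(corpus))
}

#' Score a prediction set against a gold corpus
#'
#' Builds the confusion matrix under the internal protocol (generated
#' negatives, multi-label duplication, cross-sentence false negatives) and
#' returns micro metrics over the requested class subset together with the
#' per-class table.
#'
#' @param gold_pairs Candidate pairs with gold labels.
#' @param predset A \code{cprex_predictions}.
#' @param cross_sentence Optional cross-sentence gold relations.
#' @param classes "target" (the five evaluated classes) or "all".
#' @return List with \code{confusion}, \code{micro}, \code{per_class}.
#' @export
evaluate_predictions <- function(gold_pairs, predset, cross_sentence = NULL,
                                 classes = c("target", "all")) {
  classes <- match.arg(classes)
  cm <- build_confusion_matrix(gold_pairs, predset, cross_sentence)
  subset <- if (classes == "target") cpr_eval_classes() else cpr_labels()
  list(confusion = cm, micro = micro_metrics(cm, subset),
       per_class = per_class_metrics(cm))
}

#' Persist a trained model or ensemble
#'
#' Saves the parameters together with the configuration, vocabularies and
#' seed into one self-describing file.
#'
#' @param object A \code{cprex_model} or \code{cprex_ensemble}.
#' @param path Output file.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, c("cprex_model", "cprex_ensemble")))
  saveRDS(object, path)
  invisible(path)
}

#' Load a model saved by \code{\link{save_model}}
#'
#' @param path File written by \code{\link{save_model}}.
#' @return The model or ensemble object.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, c("cprex_model", "cprex_ensemble")))
  obj
}
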