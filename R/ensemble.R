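# Ensembles of architecture-identical networks differing only in their
# random initialization. Per-class confidences are summed across members
# and the overall argmax class is selected; the summed confidence of the
# selected class is exported as the raw confidence consumed by system
# combination.

#' Train an ensemble of networks
#'
#' Member i is trained by an independent \code{\link{train_network}} run
#' seeded \code{base_seed + i - 1}; all members share one configuration.
#'
#' @param examples Encoded training examples.
#' @param config A \code{\link{model_config}}.
#' @param vectors Word vectors.
#' @param vocabs Feature vocabularies.
#' @param n Ensemble size (default 4).
#' @param base_seed Seed of the first member.
#' @param dev_examples Optional dev examples for early stopping.
#' @param score_classes Dev-metric class subset.
#' @param verbose Print progress.
#' @return A \code{cprex_ensemble}.
#' @export
train_ensemble <- function(examples, config, vectors, vocabs, n = 4,
                           base_seed = 0, dev_examples = NULL,
                           score_classes = cpr_eval_classes(),
                           verbose = FALSE) {
  stopifnot(n >= 1)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    members[[i]] <- tryCatch(
      train_network(examples, config, vectors, vocabs,
                    seed = base_seed + i - 1L,
                    dev_examples = dev_examples,
                    score_classes = score_classes, verbose = verbose),
      error = function(e) stop("ensemble member ", i, " failed: ",
                               conditionMessage(e))
    )
  }
  structure(list(members = members, config = config, base_seed = base_seed),
            class = "cprex_ensemble")
}

#' Aggregate member confidences
#'
#' Elementwise sum of the members' confidence matrices; per example the
#' argmax class wins, ties broken by the lowest class index (canonical
#' label order).
#'
#' @param mats List of n x 11 confidence matrices, one per member.
#' @return List with \code{label_id} (argmax indices), \code{label}
#'   (labels), \code{summed} (n x 11 summed matrix) and \code{confidence}
#'   (summed confidence of the selected class).
#' @export
aggregate_confidences <- function(mats) {
  stopifnot(length(mats) >= 1)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 11)) {
    stop("confidence matrices must all be n x 11 with equal n")
  }
  summed <- Reduce(`+`, mats)
  ids <- max.col(summed, ties.method = "first")
  list(label_id = ids, label = cpr_labels()[ids], summed = summed,
       confidence = summed[cbind(seq_len(nrow(summed)), ids)])
}

#' Predict with an ensemble
#'
#' @param ensemble A \code{cprex_ensemble}.
#' @param examples Encoded examples.
#' @return A \code{cprex_predictions} set keyed by the examples' (pmid,
#'   chemical, gene) keys, with the summed confidence of the selected class
#'   as the raw confidence.
#' @export
predict_ensemble <- function(ensemble, examples) {
  mats <- lapply(ensemble$members, predict_confidences, examples = examples)
  agg <- aggregate_confidences(mats)
  keys <- t(vapply(examples, function(e) e$key, character(3)))
  prediction_set(keys[, 1], keys[, 2], keys[, 3], agg$label, agg$confidence)
}

#' @export
print.cprex_ensemble <- function(x, ...) {
  cat(sprintf("<cprex_ensemble> %d members (arch %s), base seed %d\n",
              length(x$members), x$config$arch, x$base_seed))
  invisible(x)
}
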