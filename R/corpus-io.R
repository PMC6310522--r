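# Corpus model and readers for CHEMPROT-style TSV triplets plus CoNLL-U
# parses. Character offsets are 0-based, half-open, into the reconstructed
# document text "title<sep>abstract" (the convention of the public CHEMPROT
# distribution); the separator is configurable for other corpora.

split_n <- function(line, n, path, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < n) {
    stop(sprintf("%s:%d: expected %d tab-separated fields, got %d",
                 path, lineno, n, length(parts)))
  }
  parts
}

#' Read a CHEMPROT-style corpus from its three TSV files
#'
#' Reconstructs each abstract as \code{title} + \code{separator} +
#' \code{body}, attaches entity annotations (collapsing the GENE-Y/GENE-N
#' subtypes to a single GENE type) and gold relations. Sentences and token
#' spans are filled in later by \code{\link{attach_parses}}.
#'
#' @param abstracts_path TSV with columns pmid, title, abstract.
#' @param entities_path TSV with columns pmid, id, type, start, end, text
#'   (offsets 0-based half-open into the reconstructed text).
#' @param relations_path Optional TSV with columns pmid, CPR group, eval
#'   flag, relation type, \code{Arg1:<id>}, \code{Arg2:<id>}.
#' @param separator String inserted between title and abstract when
#'   reconstructing the document text. Default a tab, matching the public
#'   CHEMPROT offset convention.
#' @return A \code{cprex_corpus}: a list of documents, each holding the
#'   text, an entity table and a relation table.
#' @export
read_chemprot_tsv <- function(abstracts_path, entities_path,
                              relations_path = NULL, separator = "\t") {
  for (p in c(abstracts_path, entities_path, relations_path)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  docs <- list()
  lines <- readLines(abstracts_path, encoding = "UTF-8")
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- split_n(lines[i], 3, abstracts_path, i)
    pmid <- f[1]
    docs[[pmid]] <- list(
      pmid = pmid,
      text = paste0(f[2], separator, paste(f[-(1:2)], collapse = "\t")),
      sentences = list(),
      entities = empty_entity_table(),
      relations = empty_relation_table()
    )
  }

  lines <- readLines(entities_path, encoding = "UTF-8")
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- split_n(lines[i], 6, entities_path, i)
    pmid <- f[1]
    if (is.null(docs[[pmid]])) {
      stop(sprintf("%s:%d: entity for unknown document %s", entities_path, i, pmid))
    }
    type <- f[3]
    if (type %in% c("GENE-Y", "GENE-N")) type <- "GENE"
    if (!type %in% c("CHEMICAL", "GENE")) {
      stop(sprintf("%s:%d: unknown entity type '%s'", entities_path, i, f[3]))
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      stop(sprintf("%s:%d: malformed offsets", entities_path, i))
    }
    text <- docs[[pmid]]$text
    if (end > nchar(text)) {
      stop(sprintf("%s:%d: entity span [%d,%d) outside document text (%d chars)",
                   entities_path, i, start, end, nchar(text)))
    }
    slice <- substr(text, start + 1L, end)
    if (slice != f[6]) {
      stop(sprintf("%s:%d: entity text '%s' does not match document slice '%s'",
                   entities_path, i, f[6], slice))
    }
    docs[[pmid]]$entities <- rbind(
      docs[[pmid]]$entities,
      data.frame(id = f[2], type = type, start = start, end = end,
                 text = f[6], sentence = NA_integer_,
                 tok_first = NA_integer_, tok_last = NA_integer_,
                 stringsAsFactors = FALSE)
    )
  }

  if (!is.null(relations_path)) {
    lines <- readLines(relations_path, encoding = "UTF-8")
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i])) next
      f <- split_n(lines[i], 6, relations_path, i)
      pmid <- f[1]
      if (is.null(docs[[pmid]])) {
        stop(sprintf("%s:%d: relation for unknown document %s", relations_path, i, pmid))
      }
      arg1 <- sub("^Arg1:", "", f[5])
      arg2 <- sub("^Arg2:", "", f[6])
      known <- docs[[pmid]]$entities$id
      for (a in c(arg1, arg2)) {
        if (!a %in% known) {
          stop(sprintf("%s:%d: relation references unknown entity id %s",
                       relations_path, i, a))
        }
      }
      if (!f[2] %in% cpr_labels()) {
        stop(sprintf("%s:%d: unknown relation group '%s'", relations_path, i, f[2]))
      }
      docs[[pmid]]$relations <- rbind(
        docs[[pmid]]$relations,
        data.frame(cpr = f[2], eval_flag = f[3], type = f[4],
                   arg1 = arg1, arg2 = arg2, stringsAsFactors = FALSE)
      )
    }
  }
  structure(list(documents = docs), class = "cprex_corpus")
}

empty_entity_table <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), text = character(), sentence = integer(),
             tok_first = integer(), tok_last = integer(),
             stringsAsFactors = FALSE)
}

empty_relation_table <- function() {
  data.frame(cpr = character(), eval_flag = character(), type = character(),
             arg1 = character(), arg2 = character(), stringsAsFactors = FALSE)
}

#' @export
print.cprex_corpus <- function(x, ...) {
  nent <- sum(vapply(x$documents, function(d) nrow(d$entities), 0L))
  nrel <- sum(vapply(x$documents, function(d) nrow(d$relations), 0L))
  nsent <- sum(vapply(x$documents, function(d) length(d$sentences), 0L))
  cat(sprintf("<cprex_corpus> %d documents, %d sentences, %d entities, %d relations\n",
              length(x$documents), nsent, nent, nrel))
  invisible(x)
}

#' Read dependency parses from a CoNLL-U file
#'
#' One sentence per block, in document order. Multi-word-token ranges and
#' empty nodes (decimal ids) are skipped. Each block must carry a
#' \code{# sent_id = <pmid>.<k>} comment so parses can be assigned to
#' documents by \code{\link{attach_parses}}.
#'
#' @param path CoNLL-U file.
#' @return List of parsed sentences: each has \code{sent_id}, \code{forms},
#'   \code{upos}, \code{heads} (0 = root) and \code{deplabels}.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- list()
  cur <- NULL
  sent_id <- NA_character_
  flush <- function() {
    if (!is.null(cur) && length(cur$forms) > 0) {
      n <- length(cur$forms)
      bad <- cur$heads < 0 | cur$heads > n
      if (any(bad)) {
        stop(sprintf("CoNLL-U sentence %s: head index out of range", sent_id))
      }
      cur$sent_id <- sent_id
      sentences[[length(sentences) + 1L]] <<- cur
    }
    cur <<- NULL
    sent_id <<- NA_character_
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2) sent_id <- m[2]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop(sprintf("%s:%d: malformed CoNLL-U line", path, i))
    if (grepl("[-.]", f[1])) next  # multiword range or empty node
    if (is.null(cur)) cur <- list(forms = character(), upos = character(),
                                  heads = integer(), deplabels = character())
    cur$forms <- c(cur$forms, f[2])
    cur$upos <- c(cur$upos, f[4])
    cur$heads <- c(cur$heads, as.integer(f[7]))
    cur$deplabels <- c(cur$deplabels, f[8])
  }
  flush()
  sentences
}

# Greedy left-to-right alignment of token surfaces to document text.
# Returns 0-based half-open char spans. cursor0 is a 0-based start offset.
align_tokens <- function(text, forms, cursor0, pmid, sent_no) {
  starts <- integer(length(forms))
  ends <- integer(length(forms))
  cur <- cursor0
  for (i in seq_along(forms)) {
    rest <- substr(text, cur + 1L, nchar(text))
    p <- regexpr(forms[i], rest, fixed = TRUE)
    if (p < 0) {
      stop(sprintf("document %s sentence %d: token '%s' not found in text after offset %d",
                   pmid, sent_no, forms[i], cur))
    }
    starts[i] <- cur + as.integer(p) - 1L
    ends[i] <- starts[i] + nchar(forms[i])
    cur <- ends[i]
  }
  list(starts = starts, ends = ends)
}

#' Attach CoNLL-U parses to a corpus and map entities to tokens
#'
#' Parses are assigned to documents via their \code{sent_id}
#' (\code{<pmid>.<k>}), ordered by \code{k}. Token surfaces are aligned to
#' the document text left-to-right to obtain character spans; each entity is
#' then mapped to the contiguous range of tokens overlapping its span, which
#' must lie within a single sentence.
#'
#' @param corpus A \code{cprex_corpus} from \code{\link{read_chemprot_tsv}}.
#' @param parses Output of \code{\link{read_conllu}}.
#' @return The corpus with sentences populated and entities mapped.
#' @export
attach_parses <- function(corpus, parses) {
  ids <- vapply(parses, function(s) s$sent_id, character(1))
  if (anyNA(ids)) stop("every CoNLL-U sentence needs a '# sent_id = <pmid>.<k>' comment")
  pm <- sub("\\.[0-9]+$", "", ids)
  k <- as.integer(sub("^.*\\.", "", ids))
  for (pmid in names(corpus$documents)) {
    doc <- corpus$documents[[pmid]]
    sel <- which(pm == pmid)
    sel <- sel[order(k[sel])]
    cursor <- 0L
    sents <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      p <- parses[[sel[j]]]
      al <- align_tokens(doc$text, p$forms, cursor, pmid, j)
      cursor <- al$ends[length(al$ends)]
      sents[[j]] <- list(
        index = j,
        tokens = data.frame(index = seq_along(p$forms), surface = p$forms,
                            pos = p$upos, start = al$starts, end = al$ends,
                            stringsAsFactors = FALSE),
        heads = p$heads,
        deplabels = p$deplabels
      )
    }
    doc$sentences <- sents
    # map entities to sentences / token spans
    if (nrow(doc$entities) > 0) {
      for (e in seq_len(nrow(doc$entities))) {
        es <- doc$entities$start[e]; ee <- doc$entities$end[e]
        hit_sent <- NA_integer_; hit_first <- NA_integer_; hit_last <- NA_integer_
        for (s in seq_along(sents)) {
          tok <- sents[[s]]$tokens
          ov <- which(tok$start < ee & tok$end > es)
          if (length(ov) > 0) {
            if (!is.na(hit_sent)) {
              stop(sprintf("document %s: entity %s spans multiple sentences",
                           pmid, doc$entities$id[e]))
            }
            hit_sent <- s
            hit_first <- min(ov); hit_last <- max(ov)
          }
        }
        if (is.na(hit_sent)) {
          stop(sprintf("document %s: entity %s [%d,%d) overlaps no token",
                       pmid, doc$entities$id[e], es, ee))
        }
        doc$entities$sentence[e] <- hit_sent
        doc$entities$tok_first[e] <- hit_first
        doc$entities$tok_last[e] <- hit_last
      }
    }
    corpus$documents[[pmid]] <- doc
  }
  corpus
}

#' Generate same-sentence CHEMICAL-GENE candidate pairs
#'
#' Emits one candidate per same-sentence (CHEMICAL, GENE) combination. Pairs
#' with no gold annotation are labeled \code{negative}. Cross-sentence gold
#' relations are not emitted as candidates; retrieve them with
#' \code{\link{cross_sentence_relations}} (they are counted as false
#' negatives in evaluation). Multi-label gold pairs carry all their labels in
#' file order.
#'
#' @param corpus A parsed corpus (after \code{\link{attach_parses}}).
#' @return A data frame of class \code{cprex_pairs} with columns pmid,
#'   chem_id, gene_id, sentence and list-column \code{gold}.
#' @export
generate_candidate_pairs <- function(corpus) {
  rows <- list()
  for (doc in corpus$documents) {
    ent <- doc$entities
    if (nrow(ent) == 0) next
    rel <- doc$relations
    # orient each relation as (chemical, gene) by entity type
    rel_chem <- rel_gene <- character(nrow(rel))
    if (nrow(rel) > 0) {
      ty <- stats::setNames(ent$type, ent$id)
      for (r in seq_len(nrow(rel))) {
        a1 <- rel$arg1[r]; a2 <- rel$arg2[r]
        if (ty[[a1]] == "CHEMICAL" && ty[[a2]] == "GENE") {
          rel_chem[r] <- a1; rel_gene[r] <- a2
        } else if (ty[[a2]] == "CHEMICAL" && ty[[a1]] == "GENE") {
          rel_chem[r] <- a2; rel_gene[r] <- a1
        } else {
          stop(sprintf("document %s: relation %d does not link a CHEMICAL to a GENE",
                       doc$pmid, r))
        }
      }
    }
    for (s in unique(ent$sentence)) {
      chems <- ent$id[ent$type == "CHEMICAL" & ent$sentence == s]
      genes <- ent$id[ent$type == "GENE" & ent$sentence == s]
      for (ch in chems) {
        for (g in genes) {
          hit <- which(rel_chem == ch & rel_gene == g)
          gold <- if (length(hit) > 0) rel$cpr[hit] else "negative"
          rows[[length(rows) + 1L]] <- list(pmid = doc$pmid, chem_id = ch,
                                            gene_id = g, sentence = s,
                                            gold = gold)
        }
      }
    }
  }
  out <- data.frame(
    pmid = vapply(rows, `[[`, character(1), "pmid"),
    chem_id = vapply(rows, `[[`, character(1), "chem_id"),
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    sentence = vapply(rows, `[[`, integer(1), "sentence"),
    stringsAsFactors = FALSE
  )
  out$gold <- lapply(rows, `[[`, "gold")
  class(out) <- c("cprex_pairs", "data.frame")
  out
}

#' Gold relations whose two entities lie in different sentences
#'
#' These are never candidates for the same-sentence classifiers but must be
#' scored as false negatives.
#'
#' @param corpus A parsed corpus.
#' @return Data frame with columns pmid, chem_id, gene_id, label.
#' @export
cross_sentence_relations <- function(corpus) {
  rows <- list()
  for (doc in corpus$documents) {
    rel <- doc$relations
    if (nrow(rel) == 0) next
    ent <- doc$entities
    ty <- stats::setNames(ent$type, ent$id)
    sent_of <- stats::setNames(ent$sentence, ent$id)
    for (r in seq_len(nrow(rel))) {
      if (sent_of[[rel$arg1[r]]] != sent_of[[rel$arg2[r]]]) {
        chem <- if (ty[[rel$arg1[r]]] == "CHEMICAL") rel$arg1[r] else rel$arg2[r]
        gene <- if (ty[[rel$arg1[r]]] == "CHEMICAL") rel$arg2[r] else rel$arg1[r]
        rows[[length(rows) + 1L]] <- data.frame(
          pmid = doc$pmid, chem_id = chem, gene_id = gene, label = rel$cpr[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pmid = character(), chem_id = character(),
                      gene_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Construct a prediction set
#'
#' A prediction set maps each (pmid, chemical id, gene id) key to a predicted
#' label and a raw confidence score; \code{\link{normalize_confidences}}
#' fills in min-max normalized scores before system combination.
#'
#' @param pmid,arg1,arg2 Key columns (arg1 = chemical id, arg2 = gene id).
#' @param label Predicted labels (must be in \code{\link{cpr_labels}}).
#' @param confidence Raw confidence scores.
#' @param normalized Optional normalized confidences in [0, 1].
#' @return Data frame of class \code{cprex_predictions}.
#' @export
prediction_set <- function(pmid, arg1, arg2, label, confidence,
                           normalized = NA_real_) {
  stopifnot(length(pmid) == length(arg1), length(arg1) == length(arg2),
            length(arg2) == length(label), length(label) == length(confidence))
  label_index(label)  # validate
  key <- paste(pmid, arg1, arg2, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate pair keys in prediction set")
  out <- data.frame(pmid = pmid, arg1 = arg1, arg2 = arg2, label = label,
                    confidence = confidence,
                    normalized = rep_len(normalized, length(pmid)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cprex_predictions", "data.frame")
  out
}

#' Write a prediction set as TSV
#'
#' Columns pmid, arg1, arg2, label, confidence, in deterministic row order
#' (pmid, arg1, arg2).
#'
#' @param predset A \code{cprex_predictions} object.
#' @param path Output file.
#' @export
write_predictions <- function(predset, path) {
  ord <- order(predset$pmid, predset$arg1, predset$arg2, method = "radix")
  out <- predset[ord, c("pmid", "arg1", "arg2", "label", "confidence")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a prediction set written by \code{\link{write_predictions}}
#'
#' @param path TSV file.
#' @return A \code{cprex_predictions} data frame.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pmid = "character", arg1 = "character",
                                         arg2 = "character", label = "character",
                                         confidence = "numeric"))
  prediction_set(df$pmid, df$arg1, df$arg2, df$label, df$confidence)
}
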