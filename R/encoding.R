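# Feature encoding: word ids with out-of-vocabulary entity substitution,
# POS / dependency-type vocabularies, signed 10-bit relative-position
# vectors and five-way token types.

#' Load pretrained word vectors (word2vec text or binary format)
#'
#' Word2vec files are frequency-ordered, so capping the vocabulary keeps
#' the most frequent words.
#'
#' @param path File in word2vec format: a header line "<n> <dim>" followed
#'   by one word + vector per record. Text and binary layouts are supported.
#' @param max_vocab Keep at most this many entries, in file order.
#' @param binary Read the binary layout (little-endian float32).
#' @return A \code{cprex_vectors}: \code{vocab} (word -> row index),
#'   \code{mat} (|V| x dim matrix), \code{dim}.
#' @export
load_word_vectors <- function(path, max_vocab = Inf, binary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- character()
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (ch == "\n") break
      header <- c(header, ch)
    }
    hd <- as.integer(strsplit(paste(header, collapse = ""), " ")[[1]])
    n <- min(hd[1], max_vocab); dim <- hd[2]
    words <- character(n)
    mat <- matrix(0, n, dim)
    for (i in seq_len(n)) {
      w <- character()
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (ch == " ") break
        if (ch != "\n") w <- c(w, ch)
      }
      words[i] <- paste(w, collapse = "")
      mat[i, ] <- readBin(con, numeric(), n = dim, size = 4, endian = "little")
    }
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    hd <- as.integer(strsplit(lines[1], " ")[[1]])
    n <- min(hd[1], max_vocab, length(lines) - 1L); dim <- hd[2]
    words <- character(n)
    mat <- matrix(0, n, dim)
    for (i in seq_len(n)) {
      f <- strsplit(trimws(lines[i + 1L]), " +")[[1]]
      if (length(f) != dim + 1L) {
        stop(sprintf("%s: row %d has %d values, expected %d", path, i,
                     length(f) - 1L, dim))
      }
      words[i] <- f[1]
      mat[i, ] <- as.numeric(f[-1])
    }
  }
  if (anyDuplicated(words)) words <- make.unique(words)
  structure(list(vocab = stats::setNames(seq_len(n), words), mat = mat,
                 dim = dim), class = "cprex_vectors")
}

#' Write word vectors in word2vec text format
#'
#' @param vectors A \code{cprex_vectors} object.
#' @param path Output file.
#' @export
write_word_vectors <- function(vectors, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(vectors$mat), vectors$dim), con)
  words <- names(vectors$vocab)[order(vectors$vocab)]
  for (i in seq_len(nrow(vectors$mat))) {
    writeLines(paste(words[i],
                     paste(formatC(vectors$mat[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}

# case-sensitive lookup with lowercase fallback; 0 if out of vocabulary
word_row <- function(vectors, word) {
  i <- vectors$vocab[word]
  if (!is.na(i)) return(unname(i))
  i <- vectors$vocab[tolower(word)]
  if (!is.na(i)) return(unname(i))
  0L
}

#' Substitute out-of-vocabulary entity tokens by reserved words
#'
#' Every token inside a GENE (resp. CHEMICAL) entity span whose surface form
#' is absent from the embedding vocabulary is replaced by \code{"protein"}
#' (resp. \code{"chemical"}); in-vocabulary entity tokens and all non-entity
#' tokens are left unchanged (generic OOV handling happens later, at
#' lookup). Entity names in biomedical text often contain characters absent
#' from pretrained embeddings, and this substitution keeps at least a
#' generic type signal.
#'
#' @param words Sentence token surfaces.
#' @param chem,gene Entity rows (with tok_first/tok_last) or NULL.
#' @param vectors Word vectors; must contain \code{"protein"} and
#'   \code{"chemical"}.
#' @return Modified word vector.
#' @export
substitute_entity_oov <- function(words, chem, gene, vectors) {
  if (word_row(vectors, "protein") == 0L || word_row(vectors, "chemical") == 0L) {
    stop("word vectors must contain the reserved words 'protein' and 'chemical'")
  }
  sub_span <- function(words, first, last, replacement) {
    for (t in first:last) {
      if (word_row(vectors, words[t]) == 0L) words[t] <- replacement
    }
    words
  }
  if (!is.null(chem)) words <- sub_span(words, chem$tok_first, chem$tok_last, "chemical")
  if (!is.null(gene)) words <- sub_span(words, gene$tok_first, gene$tok_last, "protein")
  words
}

#' Encode a signed token distance as a 10-bit vector
#'
#' Bit 1 is the sign (1 iff d < 0); bits 2..10 are the binary encoding of
#' min(|d|, 511), most-significant bit first. The encoding is injective on
#' d in [-511, 511].
#'
#' @param d Signed integer distance (in tokens).
#' @return Numeric vector of 10 bits.
#' @export
encode_relative_position <- function(d) {
  mag <- min(abs(d), 511L)
  bits <- as.integer(intToBits(mag))[9:1]  # 9 bits, MSB first
  c(as.integer(d < 0), bits)
}

#' Assign the five-way token type for a candidate pair
#'
#' 1 = inside the CHEMICAL span; 2 = inside the GENE span; 3 = before the
#' first occurring entity; 4 = between the two entities; 5 = after the
#' second occurring entity. Span membership takes precedence over position;
#' for (pathological) overlapping annotations the chemical wins.
#'
#' @param t Token index.
#' @param chem,gene Entity rows with tok_first/tok_last.
#' @return Integer in 1..5.
#' @export
assign_token_type <- function(t, chem, gene) {
  if (t >= chem$tok_first && t <= chem$tok_last) return(1L)
  if (t >= gene$tok_first && t <= gene$tok_last) return(2L)
  first <- if (chem$tok_first <= gene$tok_first) chem else gene
  second <- if (chem$tok_first <= gene$tok_first) gene else chem
  if (t < first$tok_first) return(3L)
  if (t > second$tok_last) return(5L)
  4L
}

#' Build a categorical feature vocabulary
#'
#' Maps the distinct values (training split only) to integer ids; the last
#' id is the reserved UNK for unseen values at prediction time.
#'
#' @param values Character vector of observed values.
#' @return Named integer vector with an \code{"<UNK>"} entry.
#' @export
build_feature_vocab <- function(values) {
  u <- sort(unique(values))
  stats::setNames(seq_len(length(u) + 1L), c(u, "<UNK>"))
}

feature_id <- function(vocab, values) {
  i <- unname(vocab[values])
  i[is.na(i)] <- unname(vocab["<UNK>"])
  i
}

#' Encode one candidate pair into the feature sequences the networks consume
#'
#' Builds the chemical-to-gene shortest dependency path, applies
#' out-of-vocabulary entity substitution, and produces integer id sequences
#' for SDP words/POS/DTs plus per-token sentence features (word id, POS id,
#' two 10-bit relative-position vectors measured to the entity head tokens,
#' and the five-way token type). Word id 0 is the generic OOV/UNK row.
#' Sequences are truncated at the configured maxima: the SDP keeps its
#' start; the sentence keeps a window covering both entities.
#'
#' @param sentence A sentence from a parsed document.
#' @param chem,gene Entity rows.
#' @param vectors Word vectors.
#' @param pos_vocab,dt_vocab Feature vocabularies from the training split.
#' @param config A \code{\link{model_config}} (adjacency weight, maxima,
#'   direction markers).
#' @param label Gold label (default "negative").
#' @param key Character vector (pmid, chem id, gene id).
#' @return A \code{cprex_example} list.
#' @export
encode_example <- function(sentence, chem, gene, vectors, pos_vocab, dt_vocab,
                           config, label = "negative",
                           key = c(NA, NA, NA)) {
  sdp <- pair_sdp(sentence, chem, gene,
                  adjacency_weight = config$adjacency_weight,
                  directed = config$directed_dt)
  words <- substitute_entity_oov(sentence$tokens$surface, chem, gene, vectors)
  lookup <- vapply(words, function(w) word_row(vectors, w), integer(1),
                   USE.NAMES = FALSE)

  sdp_word <- lookup[sdp$token_path]
  sdp_pos <- feature_id(pos_vocab, sdp$pos_tags)
  sdp_dt <- feature_id(dt_vocab, sdp$dt_labels)
  keep <- seq_len(min(length(sdp_word), config$max_sdp_len))
  sdp_word <- sdp_word[keep]
  sdp_pos <- sdp_pos[keep]
  sdp_dt <- sdp_dt[keep[-length(keep)]]

  n <- nrow(sentence$tokens)
  ch_head <- select_entity_head(chem$tok_first, chem$tok_last, sentence$heads)
  gn_head <- select_entity_head(gene$tok_first, gene$tok_last, sentence$heads)
  first_head <- min(ch_head, gn_head)
  second_head <- max(ch_head, gn_head)

  win <- seq_len(n)
  if (n > config$max_sent_len) {
    lo <- max(1L, min(chem$tok_first, gene$tok_first))
    lo <- min(lo, n - config$max_sent_len + 1L)
    win <- lo:(lo + config$max_sent_len - 1L)
  }
  pos1 <- t(vapply(win, function(t) encode_relative_position(t - first_head),
                   numeric(10)))
  pos2 <- t(vapply(win, function(t) encode_relative_position(t - second_head),
                   numeric(10)))
  ttype <- vapply(win, assign_token_type, integer(1), chem = chem, gene = gene)

  structure(list(
    key = key,
    label_id = label_index(label),
    sdp_word = sdp_word, sdp_pos = sdp_pos, sdp_dt = sdp_dt,
    sent_word = lookup[win],
    sent_pos = feature_id(pos_vocab, sentence$tokens$pos[win]),
    sent_type = ttype, sent_pos1 = pos1, sent_pos2 = pos2
  ), class = "cprex_example")
}

#' Encode all candidate pairs of a corpus
#'
#' Multi-label gold pairs use their first gold label (file order) as the
#' single training target.
#'
#' @param pairs Candidate pairs from \code{\link{generate_candidate_pairs}}.
#' @param corpus The parsed corpus.
#' @param vectors Word vectors.
#' @param pos_vocab,dt_vocab Feature vocabularies; build them from the
#'   training split with \code{\link{corpus_vocabularies}}.
#' @param config A \code{\link{model_config}}.
#' @return List of \code{cprex_example}.
#' @export
encode_corpus <- function(pairs, corpus, vectors, pos_vocab, dt_vocab, config) {
  lapply(seq_len(nrow(pairs)), function(i) {
    doc <- corpus$documents[[pairs$pmid[i]]]
    sent <- doc$sentences[[pairs$sentence[i]]]
    chem <- doc$entities[doc$entities$id == pairs$chem_id[i], ]
    gene <- doc$entities[doc$entities$id == pairs$gene_id[i], ]
    encode_example(sent, chem, gene, vectors, pos_vocab, dt_vocab, config,
                   label = pairs$gold[[i]][1],
                   key = c(pairs$pmid[i], pairs$chem_id[i], pairs$gene_id[i]))
  })
}

#' Build POS and dependency-type vocabularies from a training corpus
#'
#' The DT vocabulary is collected from the actual SDPs of the training
#' pairs (so it contains direction-marked labels and ADJ exactly as they
#' will be consumed).
#'
#' @param pairs Training candidate pairs.
#' @param corpus The parsed corpus.
#' @param config A \code{\link{model_config}}.
#' @return List with \code{pos_vocab} and \code{dt_vocab}.
#' @export
corpus_vocabularies <- function(pairs, corpus, config) {
  pos <- character(); dts <- character()
  for (doc in corpus$documents) {
    for (s in doc$sentences) pos <- c(pos, s$tokens$pos)
  }
  for (i in seq_len(nrow(pairs))) {
    doc <- corpus$documents[[pairs$pmid[i]]]
    sent <- doc$sentences[[pairs$sentence[i]]]
    chem <- doc$entities[doc$entities$id == pairs$chem_id[i], ]
    gene <- doc$entities[doc$entities$id == pairs$gene_id[i], ]
    sdp <- pair_sdp(sent, chem, gene,
                    adjacency_weight = config$adjacency_weight,
                    directed = config$directed_dt)
    dts <- c(dts, sdp$dt_labels)
  }
  list(pos_vocab = build_feature_vocab(pos),
       dt_vocab = build_feature_vocab(if (length(dts)) dts else "ADJ"))
}
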