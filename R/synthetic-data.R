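# Seeded synthetic corpora with a planted trigger-word rule.
#
# Each sentence contains one CHEMICAL entity, 1-3 GENE entities and, for a
# positive pair, a class-specific trigger token. In the default
# ("on-SDP") variant the dependency tree is built so the trigger lies on
# the dependency path between the chemical and the annotated gene, making
# the task solvable from the SDP alone; the off-SDP variant connects the
# chemical and gene by a direct dependency edge so the trigger is visible
# only to models that read the whole sentence. A rule-based oracle
# (trigger lookup on the gold SDP) classifies the on-SDP corpus with 100%
# accuracy, upper-bounding the learning task.

#' Specification of a synthetic corpus
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param vocab_size Number of distinct filler words.
#' @param triggers Named character vector mapping planted CPR classes to
#'   distinct trigger words (defaults: CPR:3 "activates", CPR:4 "inhibits",
#'   CPR:9 "metabolizes", chosen from the evaluated classes so the official
#'   metric doubles as the planted-class metric).
#' @param negative_fraction Probability that a sentence carries no planted
#'   relation.
#' @param max_extra_genes Up to this many additional (negative) GENE
#'   entities per sentence, placed before the chemical.
#' @param tree Dependency-tree shape: "chain" or "random" (random
#'   attachment outside the chemical-gene backbone).
#' @param trigger_on_sdp Place triggers on the dependency path (TRUE) or
#'   off it (FALSE, direct chemical-gene edge).
#' @param oov_entity_fraction Fraction of entity mentions whose surface is
#'   absent from the generated word vectors (exercises the reserved-word
#'   substitution).
#' @param cross_sentence_per_doc Number of additional cross-sentence gold
#'   relations per document (requires >= 2 sentences).
#' @param seed Generator seed; output files are byte-identical given the
#'   same spec.
#' @return A \code{cprex_synth_spec}.
#' @export
synthetic_spec <- function(n_documents = 50, sentences_per_doc = 2,
                           vocab_size = 30,
                           triggers = c("CPR:3" = "activates",
                                        "CPR:4" = "inhibits",
                                        "CPR:9" = "metabolizes"),
                           negative_fraction = 0.4,
                           max_extra_genes = 2,
                           tree = c("chain", "random"),
                           trigger_on_sdp = TRUE,
                           oov_entity_fraction = 0.3,
                           cross_sentence_per_doc = 0,
                           seed = 0) {
  tree <- match.arg(tree)
  stopifnot(n_documents >= 1, sentences_per_doc >= 1,
            length(triggers) >= 1, length(triggers) <= 10,
            !anyDuplicated(triggers),
            all(names(triggers) %in% paste0("CPR:", 1:10)),
            negative_fraction >= 0, negative_fraction <= 1)
  if (vocab_size < 5) stop("vocab_size too small for a usable filler lexicon")
  if (cross_sentence_per_doc > 0 && sentences_per_doc < 2) {
    stop("cross-sentence relations require at least 2 sentences per document")
  }
  structure(list(n_documents = n_documents,
                 sentences_per_doc = sentences_per_doc,
                 vocab_size = vocab_size, triggers = triggers,
                 negative_fraction = negative_fraction,
                 max_extra_genes = max_extra_genes, tree = tree,
                 trigger_on_sdp = trigger_on_sdp,
                 oov_entity_fraction = oov_entity_fraction,
                 cross_sentence_per_doc = cross_sentence_per_doc,
                 seed = seed),
            class = "cprex_synth_spec")
}

synth_lexicon <- function(spec) {
  list(fillers = sprintf("w%03d", seq_len(spec$vocab_size)),
       chems = sprintf("chem%02d", 1:12),
       genes = sprintf("gene%02d", 1:12),
       chems_oov = sprintf("chemx%02d", 1:12),
       genes_oov = sprintf("genex%02d", 1:12),
       pos_fillers = c("NN", "JJ", "DT", "IN", "RB"),
       dep_fillers = c("nsubj", "dobj", "prep", "amod", "conj"))
}

#' In-vocabulary word list of a synthetic corpus
#'
#' The words whose vectors \code{\link{generate_word_vectors}} writes:
#' fillers, triggers, in-vocabulary entity surfaces and the reserved words
#' "protein" and "chemical" (deliberately excluding the *x* entity
#' surfaces, which stay out of vocabulary).
#'
#' @param spec A \code{cprex_synth_spec}.
#' @return Character vector.
#' @export
synth_vocabulary <- function(spec) {
  lex <- synth_lexicon(spec)
  c(lex$fillers, unname(spec$triggers), lex$chems, lex$genes,
    "protein", "chemical")
}

# one sentence: token table + heads/labels + entity descriptors + relation
synth_sentence <- function(spec, lex) {
  pick <- function(x, n = 1) x[sample.int(length(x), n, replace = TRUE)]
  positive <- stats::runif(1) >= spec$negative_fraction
  cls <- if (positive) pick(names(spec$triggers)) else NA_character_
  oov <- function() stats::runif(1) < spec$oov_entity_fraction
  chem_word <- if (oov()) pick(lex$chems_oov) else pick(lex$chems)
  gene_word <- if (oov()) pick(lex$genes_oov) else pick(lex$genes)
  n_extra <- sample.int(spec$max_extra_genes + 1L, 1) - 1L
  extra_words <- if (n_extra > 0) {
    vapply(seq_len(n_extra),
           function(i) if (oov()) pick(lex$genes_oov) else pick(lex$genes),
           character(1))
  } else character()
  fill <- function(n) pick(lex$fillers, n)

  if (spec$trigger_on_sdp) {
    toks <- c(extra_words, fill(sample(1:2, 1)), chem_word)
    chem_pos <- length(toks)
    toks <- c(toks, fill(sample(0:1, 1)))
    trig_pos <- NA_integer_
    if (positive) {
      toks <- c(toks, spec$triggers[[cls]])
      trig_pos <- length(toks)
    }
    toks <- c(toks, fill(sample(0:1, 1)), gene_word)
    gene_pos <- length(toks)
    toks <- c(toks, fill(sample(1:2, 1)))
  } else {
    toks <- c(extra_words, fill(sample(1:2, 1)), chem_word)
    chem_pos <- length(toks)
    toks <- c(toks, gene_word)
    gene_pos <- length(toks)
    toks <- c(toks, fill(sample(1:2, 1)))
    trig_pos <- NA_integer_
    if (positive) {
      toks <- c(toks, spec$triggers[[cls]])
      trig_pos <- length(toks)
    }
    toks <- c(toks, fill(sample(0:1, 1)))
  }
  n <- length(toks)
  extra_pos <- seq_len(n_extra)

  heads <- integer(n)
  labels <- character(n)
  if (spec$trigger_on_sdp) {
    if (spec$tree == "chain") {
      heads <- c(0L, seq_len(n - 1L))
      labels <- c("root", pick(lex$dep_fillers, n - 1L))
    } else {
      # backbone chem..gene chained, rooted at the chemical; pre-chemical
      # tokens attach to the chemical, post-gene tokens to a random
      # backbone node (keeps the planted rule exact: no chemical-gene path
      # strays outside the backbone)
      backbone <- chem_pos:gene_pos
      heads[chem_pos] <- 0L
      labels[chem_pos] <- "root"
      for (t in setdiff(backbone, chem_pos)) {
        heads[t] <- t - 1L
        labels[t] <- pick(lex$dep_fillers)
      }
      for (t in seq_len(chem_pos - 1L)) {
        heads[t] <- chem_pos
        labels[t] <- pick(lex$dep_fillers)
      }
      for (t in setdiff(seq_len(n), c(backbone, seq_len(chem_pos - 1L)))) {
        heads[t] <- pick(backbone)
        labels[t] <- pick(lex$dep_fillers)
      }
    }
  } else {
    heads <- rep(chem_pos, n)
    labels <- rep("dep", n)
    heads[chem_pos] <- 0L
    labels[chem_pos] <- "root"
    labels[gene_pos] <- "dobj"
  }

  pos <- pick(lex$pos_fillers, n)
  pos[c(chem_pos, gene_pos, extra_pos)] <- "NN"
  if (!is.na(trig_pos)) pos[trig_pos] <- "VB"

  list(tokens = toks, pos = pos, heads = heads, labels = labels,
       chem_pos = chem_pos, gene_pos = gene_pos, extra_pos = extra_pos,
       class = cls)
}

#' Generate a synthetic corpus on disk
#'
#' Writes abstracts.tsv, entities.tsv, relations.tsv and parses.conllu into
#' \code{dir}. Deterministic and byte-identical given the spec (including
#' its seed).
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the four file paths.
#' @export
generate_corpus <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)
  lex <- synth_lexicon(spec)
  abs_lines <- character()
  ent_lines <- character()
  rel_lines <- character()
  conllu <- character()
  for (d in seq_len(spec$n_documents)) {
    pmid <- sprintf("%d", 10000L + d)
    title <- paste("Doc", pmid)
    sents <- lapply(seq_len(spec$sentences_per_doc),
                    function(k) synth_sentence(spec, lex))
    abstract <- paste(vapply(sents, function(s) paste(s$tokens, collapse = " "),
                             character(1)), collapse = " ")
    abs_lines <- c(abs_lines, paste(pmid, title, abstract, sep = "\t"))
    text <- paste0(title, "\t", abstract)
    offset <- nchar(title) + 1L  # 0-based start of the abstract
    eid <- 0L
    chem_ids <- character(length(sents))
    gene_ids <- character(length(sents))
    for (k in seq_along(sents)) {
      s <- sents[[k]]
      starts <- offset + cumsum(c(0L, nchar(s$tokens[-length(s$tokens)]) + 1L))
      ends <- starts + nchar(s$tokens)
      add_ent <- function(t, type) {
        eid <<- eid + 1L
        id <- paste0("T", eid)
        ent_lines <<- c(ent_lines,
                        paste(pmid, id, type, starts[t], ends[t], s$tokens[t],
                              sep = "\t"))
        id
      }
      chem_ids[k] <- add_ent(s$chem_pos, "CHEMICAL")
      gtype <- if (stats::runif(1) < 0.5) "GENE-Y" else "GENE-N"
      gene_ids[k] <- add_ent(s$gene_pos, gtype)
      for (t in s$extra_pos) add_ent(t, "GENE-Y")
      if (!is.na(s$class)) {
        rel_lines <- c(rel_lines,
                       paste(pmid, s$class, "Y ", "PLANTED",
                             paste0("Arg1:", chem_ids[k]),
                             paste0("Arg2:", gene_ids[k]), sep = "\t"))
      }
      conllu <- c(conllu, sprintf("# sent_id = %s.%d", pmid, k),
                  sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                          seq_along(s$tokens), s$tokens, s$pos, s$heads,
                          s$labels),
                  "")
      offset <- ends[length(ends)] + 1L
    }
    if (spec$cross_sentence_per_doc > 0) {
      for (j in seq_len(spec$cross_sentence_per_doc)) {
        rel_lines <- c(rel_lines,
                       paste(pmid, sample(names(spec$triggers), 1), "Y ",
                             "PLANTED-X",
                             paste0("Arg1:", chem_ids[1]),
                             paste0("Arg2:", gene_ids[2]), sep = "\t"))
      }
    }
  }
  paths <- list(abstracts = file.path(dir, "abstracts.tsv"),
                entities = file.path(dir, "entities.tsv"),
                relations = file.path(dir, "relations.tsv"),
                parses = file.path(dir, "parses.conllu"))
  writeLines(abs_lines, paths$abstracts, useBytes = TRUE)
  writeLines(ent_lines, paths$entities, useBytes = TRUE)
  writeLines(rel_lines, paths$relations, useBytes = TRUE)
  writeLines(conllu, paths$parses, useBytes = TRUE)
  invisible(paths)
}

#' Read a synthetic corpus directory back into a parsed corpus
#'
#' @param dir Directory written by \code{\link{generate_corpus}}.
#' @return A parsed \code{cprex_corpus}.
#' @export
read_synthetic_corpus <- function(dir) {
  corpus <- read_chemprot_tsv(file.path(dir, "abstracts.tsv"),
                              file.path(dir, "entities.tsv"),
                              file.path(dir, "relations.tsv"))
  attach_parses(corpus, read_conllu(file.path(dir, "parses.conllu")))
}

#' Generate random word vectors for a synthetic corpus
#'
#' Standard-normal entries, deterministic given the seed; always includes
#' the reserved words "protein" and "chemical". Written in word2vec text
#' format.
#'
#' @param words Vocabulary (reserved words appended if missing).
#' @param dim Vector dimensionality.
#' @param seed RNG seed.
#' @param path Optional output file; when NULL nothing is written.
#' @return A \code{cprex_vectors} (invisibly when \code{path} is given).
#' @export
generate_word_vectors <- function(words, dim = 16, seed = 0, path = NULL) {
  words <- union(words, c("protein", "chemical"))
  set.seed(seed)
  mat <- matrix(stats::rnorm(length(words) * dim), length(words), dim)
  vec <- structure(list(vocab = stats::setNames(seq_along(words), words),
                        mat = mat, dim = dim), class = "cprex_vectors")
  if (!is.null(path)) {
    write_word_vectors(vec, path)
    return(invisible(vec))
  }
  vec
}

#' Rule-based oracle classifier for planted-trigger corpora
#'
#' Labels each candidate pair by looking up the planted trigger words on
#' its gold shortest dependency path; pairs whose path carries no trigger
#' are negative. On an on-SDP synthetic corpus this classifies with 100%
#' accuracy, providing the sanity upper bound for the learning task.
#'
#' @param corpus A parsed corpus.
#' @param pairs Candidate pairs.
#' @param triggers Named class -> trigger-word map.
#' @param adjacency_weight Word-adjacency edge weight.
#' @return A \code{cprex_predictions} (confidence 1 everywhere).
#' @export
sdp_trigger_oracle <- function(corpus, pairs, triggers,
                               adjacency_weight = 5) {
  lab <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    doc <- corpus$documents[[pairs$pmid[i]]]
    sent <- doc$sentences[[pairs$sentence[i]]]
    chem <- doc$entities[doc$entities$id == pairs$chem_id[i], ]
    gene <- doc$entities[doc$entities$id == pairs$gene_id[i], ]
    sdp <- pair_sdp(sent, chem, gene, adjacency_weight = adjacency_weight)
    hit <- match(sdp$words, triggers)
    hit <- hit[!is.na(hit)]
    lab[i] <- if (length(hit) > 0) names(triggers)[hit[1]] else "negative"
  }
  prediction_set(pairs$pmid, pairs$chem_id, pairs$gene_id, lab,
                 rep(1, nrow(pairs)))
}
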