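# Shared fixture builders. Everything is generated in code at test time.

# Write a small corpus from parallel sentence descriptions and read it back.
# sentences: list of lists with fields tokens, pos, heads, labels,
# entities (data.frame: tok (index), type), relations (data.frame: chem
# entity number, gene entity number, cpr) -- entity numbers are per
# document in order of creation.
write_hand_corpus <- function(sentences, pmid = "9001", dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  title <- paste("Doc", pmid)
  abstract <- paste(vapply(sentences, function(s) paste(s$tokens, collapse = " "),
                           character(1)), collapse = " ")
  writeLines(paste(pmid, title, abstract, sep = "\t"),
             file.path(dir, "abstracts.tsv"))
  offset <- nchar(title) + 1L
  ent_lines <- character(); rel_lines <- character(); conllu <- character()
  eid <- 0L
  ids <- list()
  for (k in seq_along(sentences)) {
    s <- sentences[[k]]
    starts <- offset + cumsum(c(0L, nchar(s$tokens[-length(s$tokens)]) + 1L))
    ends <- starts + nchar(s$tokens)
    if (!is.null(s$entities)) {
      for (e in seq_len(nrow(s$entities))) {
        eid <- eid + 1L
        ids[[eid]] <- paste0("T", eid)
        t <- s$entities$tok[e]
        ent_lines <- c(ent_lines,
                       paste(pmid, paste0("T", eid), s$entities$type[e],
                             starts[t], ends[t], s$tokens[t], sep = "\t"))
      }
    }
    conllu <- c(conllu, sprintf("# sent_id = %s.%d", pmid, k),
                sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                        seq_along(s$tokens), s$tokens, s$pos, s$heads,
                        s$labels), "")
    offset <- ends[length(ends)] + 1L
  }
  writeLines(ent_lines, file.path(dir, "entities.tsv"))
  rels <- do.call(rbind, lapply(sentences, function(s) s$relations))
  if (!is.null(rels) && nrow(rels) > 0) {
    for (r in seq_len(nrow(rels))) {
      rel_lines <- c(rel_lines,
                     paste(pmid, rels$cpr[r], "Y", "HAND",
                           paste0("Arg1:T", rels$chem[r]),
                           paste0("Arg2:T", rels$gene[r]), sep = "\t"))
    }
  }
  writeLines(rel_lines, file.path(dir, "relations.tsv"))
  writeLines(conllu, file.path(dir, "parses.conllu"))
  dir
}

# The worked example sentence: "Rapamycin allosterically inhibits the
# proteasome", chemical Rapamycin, gene proteasome, gold CPR:4.
fig_sentence <- function() {
  list(tokens = c("Rapamycin", "allosterically", "inhibits", "the", "proteasome"),
       pos = c("NN", "RB", "VBZ", "DT", "NN"),
       heads = c(3L, 3L, 0L, 5L, 3L),
       labels = c("nsubj", "advmod", "root", "det", "dobj"),
       entities = data.frame(tok = c(1L, 5L), type = c("CHEMICAL", "GENE")),
       relations = data.frame(chem = 1L, gene = 2L, cpr = "CPR:4"))
}

fig_corpus <- function() {
  dir <- write_hand_corpus(list(fig_sentence()))
  read_synthetic_corpus(dir)
}

# small parsed synthetic corpus + matching word vectors
small_synth <- function(n_documents = 10, seed = 7, ...) {
  spec <- synthetic_spec(n_documents = n_documents, seed = seed, ...)
  dir <- tempfile()
  generate_corpus(spec, dir)
  list(spec = spec, dir = dir, corpus = read_synthetic_corpus(dir),
       vectors = generate_word_vectors(synth_vocabulary(spec), dim = 8,
                                       seed = seed))
}

# random parse graph on n tokens: random dependency tree + the implicit
# adjacency edges from build_parse_graph
random_graph <- function(n, adjacency_weight = 5) {
  heads <- integer(n)
  if (n > 1) for (i in 2:n) heads[i] <- sample.int(i - 1L, 1)
  build_parse_graph(n, heads, rep("dep", n), adjacency_weight)
}

# exhaustive simple-path enumeration under the same ordering (weight, edge
# count, lexicographic token sequence); independent oracle for sdp_search
enum_best_path <- function(graph, from, to) {
  n <- graph$n
  W <- matrix(Inf, n, n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    w <- e$weight[r]
    if (w < W[e$u[r], e$v[r]]) W[e$u[r], e$v[r]] <- W[e$v[r], e$u[r]] <- w
  }
  best <- NULL
  better <- function(a, b) {
    if (a$w != b$w) return(a$w < b$w)
    if (a$n != b$n) return(a$n < b$n)
    l <- min(length(a$p), length(b$p))
    for (i in seq_len(l)) if (a$p[i] != b$p[i]) return(a$p[i] < b$p[i])
    length(a$p) < length(b$p)
  }
  rec <- function(path, w) {
    u <- path[length(path)]
    if (u == to) {
      cand <- list(w = w, n = length(path) - 1L, p = path)
      if (is.null(best) || better(cand, best)) best <<- cand
      return()
    }
    for (v in seq_len(n)) {
      if (is.finite(W[u, v]) && !(v %in% path)) rec(c(path, v), w + W[u, v])
    }
  }
  rec(from, 0)
  best
}

random_prediction_set <- function(n, pmids = paste0("p", 1:5)) {
  keys <- unique(data.frame(
    pmid = sample(pmids, n, replace = TRUE),
    arg1 = paste0("T", sample(1:6, n, replace = TRUE)),
    arg2 = paste0("T", sample(7:12, n, replace = TRUE)),
    stringsAsFactors = FALSE))
  prediction_set(keys$pmid, keys$arg1, keys$arg2,
                 sample(cpr_labels(), nrow(keys), replace = TRUE),
                 stats::runif(nrow(keys), -2, 4))
}
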