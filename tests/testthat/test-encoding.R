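test_that("relative position encoding is the documented signed 10-bit layout", {
  expect_equal(encode_relative_position(0), rep(0, 10))
  expect_equal(encode_relative_position(5), c(0, 0, 0, 0, 0, 0, 0, 1, 0, 1))
  expect_equal(encode_relative_position(-5), c(1, 0, 0, 0, 0, 0, 0, 1, 0, 1))
  expect_equal(encode_relative_position(511), c(0, rep(1, 9)))
  # magnitudes clip at 511
  expect_equal(encode_relative_position(600), encode_relative_position(511))
  expect_equal(encode_relative_position(-9999), encode_relative_position(-511))
})

test_that("relative position encoding is injective on [-511, 511]", {
  codes <- vapply(-511:511, function(d)
    paste(encode_relative_position(d), collapse = ""), character(1))
  expect_equal(anyDuplicated(codes), 0)
})

test_that("token types partition the sentence into five regions", {
  chem <- data.frame(tok_first = 3L, tok_last = 4L)
  gene <- data.frame(tok_first = 8L, tok_last = 8L)
  types <- vapply(1:10, assign_token_type, integer(1), chem = chem, gene = gene)
  expect_equal(types, c(3L, 3L, 1L, 1L, 4L, 4L, 4L, 2L, 5L, 5L))
  # order-independent: gene before chemical
  types2 <- vapply(1:10, assign_token_type, integer(1),
                   chem = data.frame(tok_first = 8L, tok_last = 8L),
                   gene = data.frame(tok_first = 3L, tok_last = 4L))
  expect_equal(types2, c(3L, 3L, 2L, 2L, 4L, 4L, 4L, 1L, 5L, 5L))
  # every token gets exactly one type in 1..5
  expect_true(all(types %in% 1:5))
})

test_that("word vectors round-trip through the word2vec text format", {
  v <- generate_word_vectors(c("alpha", "beta", "gamma"), dim = 4, seed = 3)
  p <- tempfile()
  write_word_vectors(v, p)
  back <- load_word_vectors(p)
  expect_equal(names(back$vocab), names(v$vocab))
  expect_equal(back$mat, v$mat, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$dim, 4)
  # vocabulary capping keeps file order
  capped <- load_word_vectors(p, max_vocab = 2)
  expect_equal(names(capped$vocab), names(v$vocab)[1:2])
  # malformed row is reported
  lines <- readLines(p)
  lines[2] <- sub(" [^ ]+$", "", lines[2])
  writeLines(lines, p)
  expect_error(load_word_vectors(p), "row 1 has 3 values, expected 4")
})

test_that("binary word2vec files load identically to text", {
  v <- generate_word_vectors(c("alpha", "beta"), dim = 3, seed = 9)
  p <- tempfile()
  con <- file(p, "wb")
  writeChar(sprintf("%d %d\n", nrow(v$mat), v$dim), con, eos = NULL)
  for (i in seq_len(nrow(v$mat))) {
    writeChar(paste0(names(v$vocab)[i], " "), con, eos = NULL)
    writeBin(as.numeric(v$mat[i, ]), con, size = 4, endian = "little")
    writeChar("\n", con, eos = NULL)
  }
  close(con)
  back <- load_word_vectors(p, binary = TRUE)
  expect_equal(names(back$vocab), names(v$vocab))
  expect_equal(back$mat, v$mat, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("word lookup is case-sensitive with lowercase fallback", {
  v <- generate_word_vectors(c("Insulin", "kinase"), dim = 2, seed = 0)
  expect_equal(cprex:::word_row(v, "Insulin"), 1L)
  expect_equal(cprex:::word_row(v, "Kinase"), 2L)   # lowercase fallback
  expect_equal(cprex:::word_row(v, "KINASE"), 2L)   # fallback lowercases fully
  # the fallback only lowercases the query, it never uppercases the vocab
  expect_equal(cprex:::word_row(v, "INSULIN"), 0L)
  expect_equal(cprex:::word_row(v, "absent"), 0L)
})

test_that("out-of-vocabulary entity tokens get the reserved substitutes", {
  v <- generate_word_vectors(c("aspirin", "filler"), dim = 2, seed = 1)
  words <- c("XQ-231", "filler", "aspirin", "filler", "p53delta")
  chem <- data.frame(tok_first = 1L, tok_last = 1L)
  gene <- data.frame(tok_first = 5L, tok_last = 5L)
  out <- substitute_entity_oov(words, chem, gene, v)
  expect_equal(out, c("chemical", "filler", "aspirin", "filler", "protein"))
  # in-vocabulary entity surfaces stay; non-entity OOV tokens stay
  chem2 <- data.frame(tok_first = 3L, tok_last = 3L)
  out2 <- substitute_entity_oov(words, chem2, gene, v)
  expect_equal(out2[1], "XQ-231")
  expect_equal(out2[3], "aspirin")
  # missing reserved words is an error
  v2 <- structure(list(vocab = c(aspirin = 1L), mat = matrix(0, 1, 2), dim = 2),
                  class = "cprex_vectors")
  expect_error(substitute_entity_oov(words, chem, gene, v2),
               "reserved words")
})

test_that("feature vocabularies reserve the last id for UNK", {
  vv <- build_feature_vocab(c("NN", "VB", "NN", "DT"))
  expect_equal(names(vv), c("DT", "NN", "VB", "<UNK>"))
  expect_equal(unname(vv["<UNK>"]), 4L)
  expect_equal(cprex:::feature_id(vv, c("NN", "nope", "VB")), c(2L, 4L, 3L))
})

test_that("encode_example produces consistent SDP and sentence features", {
  corpus <- fig_corpus()
  doc <- corpus$documents[["9001"]]
  sent <- doc$sentences[[1]]
  v <- generate_word_vectors(c("Rapamycin", "allosterically", "inhibits",
                               "the"), dim = 4, seed = 5)
  cfg <- model_config_tiny("i")
  pairs <- generate_candidate_pairs(corpus)
  vocabs <- corpus_vocabularies(pairs, corpus, cfg)
  ex <- encode_example(sent, doc$entities[1, ], doc$entities[2, ], v,
                       vocabs$pos_vocab, vocabs$dt_vocab, cfg,
                       label = "CPR:4", key = c("9001", "T1", "T2"))
  expect_equal(ex$label_id, label_index("CPR:4"))
  expect_length(ex$sdp_word, 3)           # Rapamycin inhibits proteasome
  expect_length(ex$sdp_pos, 3)
  expect_length(ex$sdp_dt, 2)
  # proteasome is OOV inside the gene span -> substituted by "protein"
  expect_equal(ex$sdp_word[3], cprex:::word_row(v, "protein"))
  expect_equal(ex$sent_word[5], cprex:::word_row(v, "protein"))
  expect_equal(ex$sent_type, c(1L, 4L, 4L, 4L, 2L))
  # positions are measured to the entity head tokens (1 and 5)
  expect_equal(ex$sent_pos1[1, ], encode_relative_position(0))
  expect_equal(ex$sent_pos2[5, ], encode_relative_position(0))
  expect_equal(ex$sent_pos1[3, ], encode_relative_position(2))
  expect_equal(ex$sent_pos2[1, ], encode_relative_position(-4))
  # dt vocabulary was built from actual directed SDP labels
  expect_true(all(c("nsubj↑", "dobj↓") %in% names(vocabs$dt_vocab)))
})

test_that("gene OOV substitution reaches the SDP words", {
  # 'protein' is in every generated vector set, so an OOV gene on the path
  # maps to the 'protein' row rather than the generic UNK
  corpus <- fig_corpus()
  doc <- corpus$documents[["9001"]]
  v <- generate_word_vectors("inhibits", dim = 4, seed = 5)
  cfg <- model_config_tiny("st")
  pairs <- generate_candidate_pairs(corpus)
  vocabs <- corpus_vocabularies(pairs, corpus, cfg)
  ex <- encode_example(doc$sentences[[1]], doc$entities[1, ],
                       doc$entities[2, ], v, vocabs$pos_vocab,
                       vocabs$dt_vocab, cfg)
  expect_equal(ex$sdp_word, c(cprex:::word_row(v, "chemical"),
                              cprex:::word_row(v, "inhibits"),
                              cprex:::word_row(v, "protein")))
})

test_that("truncation keeps the SDP start and a sentence window covering both entities", {
  # long chain sentence: 30 tokens, chemical at 1, gene at 30
  n <- 30L
  s <- list(tokens = sprintf("tk%02d", 1:n), pos = rep("NN", n),
            heads = c(0L, seq_len(n - 1L)), labels = c("root", rep("dep", n - 1L)),
            entities = data.frame(tok = c(10L, 20L), type = c("CHEMICAL", "GENE")),
            relations = NULL)
  corpus <- read_synthetic_corpus(write_hand_corpus(list(s)))
  doc <- corpus$documents[["9001"]]
  v <- generate_word_vectors(s$tokens, dim = 4, seed = 2)
  cfg <- model_config_tiny("i", max_sdp_len = 5, max_sent_len = 15)
  pairs <- generate_candidate_pairs(corpus)
  vocabs <- corpus_vocabularies(pairs, corpus, cfg)
  ex <- encode_example(doc$sentences[[1]], doc$entities[1, ], doc$entities[2, ],
                       v, vocabs$pos_vocab, vocabs$dt_vocab, cfg)
  expect_length(ex$sdp_word, 5)
  expect_length(ex$sdp_dt, 4)
  # SDP keeps its start: first word is the chemical head's word id
  expect_equal(ex$sdp_word[1], cprex:::word_row(v, "tk10"))
  # sentence window is max_sent_len long and covers both entity spans
  expect_length(ex$sent_word, 15)
  expect_equal(ex$sent_word[1], cprex:::word_row(v, "tk10"))
  expect_true(any(ex$sent_type == 1L) && any(ex$sent_type == 2L))
})
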