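# Shared tiny encoded dataset for the network tests.
net_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      syn <- small_synth(n_documents = 12, seed = 21)
      cfg_i <- model_config_tiny("i")
      cfg_st <- model_config_tiny("st")
      split <- encode_split(syn$corpus, syn$vectors, cfg_i)
      cache <<- list(syn = syn, cfg_i = cfg_i, cfg_st = cfg_st,
                     split = split,
                     n_pos = length(split$vocabs$pos_vocab),
                     n_dt = length(split$vocabs$dt_vocab))
    }
    cache
  }
})

test_that("configuration defaults differ by architecture and reject unknown fields", {
  ci <- model_config("i")
  cs <- model_config("st")
  expect_equal(ci$batch_size, 16); expect_equal(cs$batch_size, 32)
  expect_equal(ci$learning_rate, 0.0005); expect_equal(cs$learning_rate, 0.002)
  expect_equal(ci$epochs, 4); expect_equal(cs$epochs, 3)
  expect_equal(ci$hidden_dim, 1024)
  expect_equal(ci$lstm_sdp_words, 300)
  expect_error(model_config("i", nonsense = 1))
  expect_error(model_config("i", dropout = 1))
})

test_that("forward confidences are valid distributions for both architectures", {
  fx <- net_fixture()
  v <- fx$syn$vectors
  for (cfg in list(fx$cfg_st, fx$cfg_i)) {
    set.seed(1)
    params <- init_network(cfg, v, fx$n_pos, fx$n_dt)
    batch <- make_batch(fx$split$examples[1:7], cfg, nrow(params$E_word),
                        fx$n_pos, fx$n_dt)
    fwd <- if (cfg$arch == "st") st_ann_forward(params, batch, cfg)
           else i_ann_forward(params, batch, cfg)
    expect_equal(dim(fwd), c(7, 11))
    expect_true(all(fwd > 0))
    expect_equal(rowSums(fwd), rep(1, 7), tolerance = 1e-12)
    # architecture mismatch is an error
    wrong <- if (cfg$arch == "st") i_ann_forward else st_ann_forward
    expect_error(wrong(params, batch, cfg))
  }
})

test_that("inference is deterministic and dropout only fires in training mode", {
  fx <- net_fixture()
  cfg <- fx$cfg_i
  set.seed(2)
  params <- init_network(cfg, fx$syn$vectors, fx$n_pos, fx$n_dt)
  batch <- make_batch(fx$split$examples[1:5], cfg, nrow(params$E_word),
                      fx$n_pos, fx$n_dt)
  a <- i_ann_forward(params, batch, cfg)
  b <- i_ann_forward(params, batch, cfg)
  expect_identical(a, b)
  # training mode draws a dropout mask from the RNG: two calls differ
  set.seed(3); tr1 <- i_ann_forward(params, batch, cfg, training = TRUE)
  set.seed(4); tr2 <- i_ann_forward(params, batch, cfg, training = TRUE)
  expect_false(identical(tr1, tr2))
  # but are reproducible under the same RNG state
  set.seed(3); tr1b <- i_ann_forward(params, batch, cfg, training = TRUE)
  expect_identical(tr1, tr1b)
})

test_that("padding cannot change an example's confidences", {
  fx <- net_fixture()
  ex <- fx$split$examples
  # pick a short and a long example so batching pads the short one
  lens <- vapply(ex, function(e) length(e$sent_word), 0L)
  short <- ex[[which.min(lens)]]
  long <- ex[[which.max(lens)]]
  expect_true(length(short$sent_word) < length(long$sent_word))
  for (cfg in list(fx$cfg_st, fx$cfg_i)) {
    set.seed(5)
    params <- init_network(cfg, fx$syn$vectors, fx$n_pos, fx$n_dt)
    alone <- cprex:::network_forward(
      params, make_batch(list(short), cfg, nrow(params$E_word), fx$n_pos,
                         fx$n_dt), cfg)$probs
    padded <- cprex:::network_forward(
      params, make_batch(list(short, long), cfg, nrow(params$E_word),
                         fx$n_pos, fx$n_dt), cfg)$probs
    expect_equal(padded[1, ], alone[1, ], tolerance = 1e-12)
  }
})

test_that("a single-token sequence pools to its own biLSTM state", {
  fx <- net_fixture()
  cfg <- fx$cfg_i
  set.seed(6)
  params <- init_network(cfg, fx$syn$vectors, fx$n_pos, fx$n_dt)
  ex <- fx$split$examples[[1]]
  ex$sent_word <- ex$sent_word[1]; ex$sent_pos <- ex$sent_pos[1]
  ex$sent_type <- ex$sent_type[1]
  ex$sent_pos1 <- ex$sent_pos1[1, , drop = FALSE]
  ex$sent_pos2 <- ex$sent_pos2[1, , drop = FALSE]
  batch <- make_batch(list(ex), cfg, nrow(params$E_word), fx$n_pos, fx$n_dt)
  fwd <- cprex:::network_forward(params, batch, cfg)
  pooled <- fwd$cache$pool$pooled
  hcat <- cbind(fwd$cache$ff$h_all[[1]], fwd$cache$fb$h_all[[1]])
  expect_equal(pooled, hcat, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  fx <- net_fixture()
  for (arch in c("st", "i")) {
    cfg <- model_config_tiny(arch, pos_dim = 3, dt_dim = 3,
                             lstm_sdp_words = 4, lstm_sdp_pos = 3,
                             lstm_sdp_dt = 3, lstm_sentence = 4,
                             hidden_dim = 5, dropout = 0)
    set.seed(7)
    params <- init_network(cfg, fx$syn$vectors, fx$n_pos, fx$n_dt)
    batch <- make_batch(fx$split$examples[1:4], cfg, nrow(params$E_word),
                        fx$n_pos, fx$n_dt)
    res <- cprex:::network_grads(params, batch, cfg, training = FALSE)
    eps <- 1e-5
    set.seed(8)
    for (nm in c("o.W", "h.W", "sdpw.U", "sdpd.W", "E_pos",
                 if (arch == "i") c("sentf.W", "sentb.U", "E_type"))) {
      g <- res$grads[[nm]]
      for (probe in 1:4) {
        i <- sample.int(length(params[[nm]]), 1)
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- cprex:::network_grads(p2, batch, cfg, training = FALSE)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- cprex:::network_grads(p2, batch, cfg, training = FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-3)
      }
    }
  }
})

test_that("position-bit inputs carry no trainable parameters", {
  fx <- net_fixture()
  res_names <- {
    cfg <- fx$cfg_i
    set.seed(9)
    params <- init_network(cfg, fx$syn$vectors, fx$n_pos, fx$n_dt)
    batch <- make_batch(fx$split$examples[1:3], cfg, nrow(params$E_word),
                        fx$n_pos, fx$n_dt)
    names(cprex:::network_grads(params, batch, cfg, training = FALSE)$grads)
  }
  expect_false(any(grepl("pos1|pos2|position", res_names)))
})

test_that("training is seeded, logged, and reduces the loss", {
  fx <- net_fixture()
  cfg <- model_config_tiny("st", epochs = 2, monitor_dev = FALSE)
  m1 <- train_network(fx$split$examples, cfg, fx$syn$vectors,
                      fx$split$vocabs, seed = 42)
  m2 <- train_network(fx$split$examples, cfg, fx$syn$vectors,
                      fx$split$vocabs, seed = 42)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$log$epoch, 1:2)
  expect_lt(m1$log$loss[2], m1$log$loss[1])
  # a different seed gives different parameters
  m3 <- train_network(fx$split$examples, cfg, fx$syn$vectors,
                      fx$split$vocabs, seed = 43)
  expect_false(identical(m1$params$o.W, m3$params$o.W))
  expect_error(train_network(list(), cfg, fx$syn$vectors, fx$split$vocabs),
               "empty training set")
})

test_that("zero-epoch training returns the seeded initialization", {
  fx <- net_fixture()
  cfg <- model_config_tiny("st", epochs = 0, monitor_dev = FALSE)
  m <- train_network(fx$split$examples, cfg, fx$syn$vectors,
                     fx$split$vocabs, seed = 11)
  set.seed(11)
  params <- init_network(cfg, fx$syn$vectors, fx$n_pos, fx$n_dt)
  expect_identical(m$params, params)
  expect_equal(nrow(m$log), 0)
})

test_that("dev monitoring stops early and returns the best epoch", {
  fx <- net_fixture()
  dev_syn <- small_synth(n_documents = 6, seed = 22)
  dev <- encode_split(dev_syn$corpus, fx$syn$vectors, fx$cfg_st,
                      vocabs = fx$split$vocabs)
  cfg <- model_config_tiny("st", epochs = 6, patience = 1)
  m <- train_network(fx$split$examples, cfg, fx$syn$vectors,
                     fx$split$vocabs, seed = 1, dev_examples = dev$examples)
  expect_true(all(!is.na(m$log$dev_f)))
  expect_equal(m$best_epoch, which.max(m$log$dev_f))
  # stopped once dev-F failed to improve for `patience` epochs, so the log
  # is never longer than best_epoch + patience
  expect_lte(nrow(m$log), m$best_epoch + cfg$patience)
})

test_that("Nadam matches a hand-stepped scalar reference", {
  # one scalar parameter, constant gradient 2
  params <- list(w = 1)
  st <- cprex:::nadam_new(params)
  mu <- 0.9; nu <- 0.999; eps <- 1e-8
  w <- 1; m <- 0; v <- 0
  for (t in 1:3) {
    g <- 2
    upd <- cprex:::nadam_step(params, list(w = g), st, lr = 0.1)
    params <- upd$params; st <- upd$state
    m <- mu * m + (1 - mu) * g
    v <- nu * v + (1 - nu) * g^2
    mhat <- mu * m / (1 - mu^(t + 1)) + (1 - mu) * g / (1 - mu^t)
    vhat <- v / (1 - nu^t)
    w <- w - 0.1 * mhat / (sqrt(vhat) + eps)
    expect_equal(params$w, w, tolerance = 1e-12)
  }
})

test_that("models survive a save/load round trip", {
  fx <- net_fixture()
  cfg <- model_config_tiny("st", epochs = 1, monitor_dev = FALSE)
  m <- train_network(fx$split$examples, cfg, fx$syn$vectors,
                     fx$split$vocabs, seed = 2)
  p <- tempfile(fileext = ".rds")
  save_model(m, p)
  back <- load_model(p)
  expect_identical(back$params, m$params)
  expect_identical(predict_confidences(back, fx$split$examples[1:4]),
                   predict_confidences(m, fx$split$examples[1:4]))
  expect_error(save_model(list(), p))
})
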