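# The two classifier architectures and their training loop.
#
# Both networks read the chemical-to-gene shortest dependency path through
# three unidirectional LSTM chains (words, POS tags, dependency types); the
# three final hidden states are concatenated into the SDP representation.
# The sentence-augmented architecture ("i") additionally runs a
# bidirectional LSTM over the full sentence -- each token represented by the
# concatenation of its word and POS embeddings, two 10-bit relative-position
# vectors and a token-type embedding -- and max-over-time pools the
# per-token states into a sentence vector. The concatenated representation
# feeds a tanh dense layer with dropout, then an 11-way softmax decision
# layer. Training uses categorical cross-entropy and the Nadam optimizer,
# reshuffling the training examples before every epoch.

#' Network and training configuration
#'
#' Defaults are the grid-search optima of the reference configuration: POS
#' and DT embeddings 25-d, token-type 10-d, positions fixed 10-bit, SDP
#' LSTMs 300/200/200, sentence LSTMs 300 per direction, word-adjacency
#' weight 5, dense layer 1024 with tanh, dropout 0.2. The
#' sentence-augmented architecture trains with batch 16 / learning rate
#' 0.0005 / 4 epochs; the SDP-only architecture with batch 32 / 0.002 / 3
#' epochs.
#'
#' @param arch "i" (SDP + bidirectional sentence chains) or "st" (SDP only).
#' @param ... Overrides for any field.
#' @return A \code{cprex_config} list.
#' @export
model_config <- function(arch = c("i", "st"), ...) {
  arch <- match.arg(arch)
  cfg <- list(
    arch = arch,
    pos_dim = 25, dt_dim = 25, position_dim = 10, token_type_dim = 10,
    lstm_sdp_words = 300, lstm_sdp_pos = 200, lstm_sdp_dt = 200,
    lstm_sentence = 300,
    adjacency_weight = 5, hidden_dim = 1024, dropout = 0.2,
    batch_size = if (arch == "st") 32 else 16,
    learning_rate = if (arch == "st") 0.002 else 0.0005,
    epochs = if (arch == "st") 3 else 4,
    patience = 1, monitor_dev = TRUE,
    max_sdp_len = 20, max_sent_len = 100,
    directed_dt = TRUE
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$dropout >= 0, cfg$dropout < 1, cfg$batch_size >= 1,
            cfg$adjacency_weight > 0)
  class(cfg) <- "cprex_config"
  cfg
}

#' Reduced-dimension configuration for desk-scale experiments
#'
#' Word vectors 16-d (supplied separately), all LSTMs 16 units, dense layer
#' 32, POS/DT embeddings 8-d, learning rate 0.005, up to 10 epochs keeping
#' the best dev epoch. Sized so a full train/evaluate cycle on a synthetic
#' corpus of a few hundred sentences runs in minutes on one CPU.
#'
#' @param arch "i" or "st".
#' @param ... Further overrides.
#' @return A \code{cprex_config}.
#' @export
model_config_tiny <- function(arch = c("i", "st"), ...) {
  model_config(arch = arch, pos_dim = 8, dt_dim = 8,
               lstm_sdp_words = 16, lstm_sdp_pos = 16, lstm_sdp_dt = 16,
               lstm_sentence = 16, hidden_dim = 32,
               batch_size = 16, learning_rate = 0.005,
               epochs = 10, patience = 10, ...)
}

#' Initialize network parameters
#'
#' Word embeddings start from the pretrained matrix (plus a zero UNK row
#' that also serves as padding) and are fine-tuned; all other embeddings
#' and weights are Glorot-initialized from the current RNG state. Word and
#' POS embedding tables are shared between the SDP and sentence chains.
#'
#' @param config A \code{\link{model_config}}.
#' @param vectors Pretrained word vectors (\code{cprex_vectors}).
#' @param n_pos,n_dt Sizes of the POS and DT vocabularies (including UNK).
#' @return Named list of parameter matrices/vectors.
#' @export
init_network <- function(config, vectors, n_pos, n_dt) {
  V <- nrow(vectors$mat)
  Dw <- vectors$dim
  p <- list()
  p[["E_word"]] <- rbind(vectors$mat, matrix(0, 1, Dw))  # last row = UNK/pad
  p[["E_pos"]] <- glorot(n_pos, config$pos_dim)
  p[["E_dt"]] <- glorot(n_dt, config$dt_dim)
  add_lstm <- function(p, name, din, dh) {
    l <- lstm_init(din, dh)
    p[[paste0(name, ".W")]] <- l$W
    p[[paste0(name, ".U")]] <- l$U
    p[[paste0(name, ".b")]] <- l$b
    p
  }
  p <- add_lstm(p, "sdpw", Dw, config$lstm_sdp_words)
  p <- add_lstm(p, "sdpp", config$pos_dim, config$lstm_sdp_pos)
  p <- add_lstm(p, "sdpd", config$dt_dim, config$lstm_sdp_dt)
  zdim <- config$lstm_sdp_words + config$lstm_sdp_pos + config$lstm_sdp_dt
  if (config$arch == "i") {
    p[["E_type"]] <- glorot(5, config$token_type_dim)
    din <- Dw + config$pos_dim + 2 * config$position_dim + config$token_type_dim
    p <- add_lstm(p, "sentf", din, config$lstm_sentence)
    p <- add_lstm(p, "sentb", din, config$lstm_sentence)
    zdim <- zdim + 2 * config$lstm_sentence
  }
  p[["h.W"]] <- glorot(zdim, config$hidden_dim)
  p[["h.b"]] <- numeric(config$hidden_dim)
  p[["o.W"]] <- glorot(config$hidden_dim, 11)
  p[["o.b"]] <- numeric(11)
  p
}

#' Assemble a padded mini-batch from encoded examples
#'
#' Pads id sequences with the UNK/pad id and builds 0/1 masks; padded
#' positions never contribute to any output (mask carry-through in the
#' LSTMs, exclusion from max-pooling).
#'
#' @param examples List of \code{cprex_example}.
#' @param config A \code{\link{model_config}}.
#' @param n_word_rows Number of rows of the word embedding table (|V| + 1);
#'   the last row is the UNK/pad row.
#' @param n_pos,n_dt Vocabulary sizes (UNK = last id).
#' @return A batch list of id matrices, masks and position-bit blocks.
#' @export
make_batch <- function(examples, config, n_word_rows, n_pos, n_dt) {
  B <- length(examples)
  unk_w <- n_word_rows
  widof <- function(ids) ifelse(ids == 0L, unk_w, ids)
  ls <- vapply(examples, function(e) length(e$sdp_word), 0L)
  Ts <- max(ls)
  Td <- max(1L, max(ls - 1L))
  sdpw <- matrix(unk_w, B, Ts); sdpp <- matrix(n_pos, B, Ts)
  sdpd <- matrix(n_dt, B, Td)
  msdp <- matrix(0, Ts, B); mdt <- matrix(0, Td, B)
  for (b in seq_len(B)) {
    e <- examples[[b]]
    l <- ls[b]
    sdpw[b, seq_len(l)] <- widof(e$sdp_word)
    sdpp[b, seq_len(l)] <- e$sdp_pos
    msdp[seq_len(l), b] <- 1
    if (l > 1) {
      sdpd[b, seq_len(l - 1L)] <- e$sdp_dt
      mdt[seq_len(l - 1L), b] <- 1
    }
  }
  batch <- list(B = B, sdpw = sdpw, sdpp = sdpp, sdpd = sdpd,
                msdp = msdp, mdt = mdt,
                labels = vapply(examples, function(e) e$label_id, 0L),
                keys = t(vapply(examples, function(e) e$key, character(3))))
  if (config$arch == "i") {
    ln <- vapply(examples, function(e) length(e$sent_word), 0L)
    Tn <- max(ln)
    sw <- matrix(unk_w, B, Tn); sp <- matrix(n_pos, B, Tn)
    st <- matrix(1L, B, Tn)
    msent <- matrix(0, Tn, B)
    pos1 <- lapply(seq_len(Tn), function(t) matrix(0, B, 10))
    pos2 <- lapply(seq_len(Tn), function(t) matrix(0, B, 10))
    for (b in seq_len(B)) {
      e <- examples[[b]]
      l <- ln[b]
      sw[b, seq_len(l)] <- widof(e$sent_word)
      sp[b, seq_len(l)] <- e$sent_pos
      st[b, seq_len(l)] <- e$sent_type
      msent[seq_len(l), b] <- 1
      for (t in seq_len(l)) {
        pos1[[t]][b, ] <- e$sent_pos1[t, ]
        pos2[[t]][b, ] <- e$sent_pos2[t, ]
      }
    }
    batch <- c(batch, list(sentw = sw, sentp = sp, sentt = st,
                           msent = msent, pos1 = pos1, pos2 = pos2))
  }
  batch
}

embed_seq <- function(E, ids) {
  lapply(seq_len(ncol(ids)), function(t) E[ids[, t], , drop = FALSE])
}

run_chain <- function(p, name, X, mask) {
  lstm_forward(X, mask, p[[paste0(name, ".W")]], p[[paste0(name, ".U")]],
               p[[paste0(name, ".b")]])
}

# Full forward pass. training = TRUE applies (and caches) a dropout mask on
# the dense-layer output, drawn from the ambient RNG stream.
network_forward <- function(params, batch, config, training = FALSE) {
  p <- params
  Xw <- embed_seq(p$E_word, batch$sdpw)
  Xp <- embed_seq(p$E_pos, batch$sdpp)
  Xd <- embed_seq(p$E_dt, batch$sdpd)
  fw <- run_chain(p, "sdpw", Xw, batch$msdp)
  fp <- run_chain(p, "sdpp", Xp, batch$msdp)
  fd <- run_chain(p, "sdpd", Xd, batch$mdt)
  z <- cbind(fw$h_final, fp$h_final, fd$h_final)
  cache <- list(fw = fw, fp = fp, fd = fd)
  if (config$arch == "i") {
    Tn <- ncol(batch$sentw)
    Xs <- lapply(seq_len(Tn), function(t) {
      cbind(p$E_word[batch$sentw[, t], , drop = FALSE],
            p$E_pos[batch$sentp[, t], , drop = FALSE],
            batch$pos1[[t]], batch$pos2[[t]],
            p$E_type[batch$sentt[, t], , drop = FALSE])
    })
    ff <- run_chain(p, "sentf", Xs, batch$msent)
    Xr <- rev(Xs)
    mr <- batch$msent[rev(seq_len(Tn)), , drop = FALSE]
    fb <- run_chain(p, "sentb", Xr, mr)
    Hcat <- lapply(seq_len(Tn), function(t) {
      cbind(ff$h_all[[t]], fb$h_all[[Tn + 1L - t]])
    })
    pool <- max_pool_forward(Hcat, batch$msent)
    z <- cbind(z, pool$pooled)
    cache <- c(cache, list(ff = ff, fb = fb, pool = pool, Tn = Tn))
  }
  h1 <- tanh(sweep(z %*% p[["h.W"]], 2, p[["h.b"]], "+"))
  if (training && config$dropout > 0) {
    dm <- matrix((stats::runif(length(h1)) >= config$dropout) /
                   (1 - config$dropout), nrow(h1), ncol(h1))
    h1d <- h1 * dm
  } else {
    dm <- NULL
    h1d <- h1
  }
  logits <- sweep(h1d %*% p[["o.W"]], 2, p[["o.b"]], "+")
  probs <- softmax_rows(logits)
  cache <- c(cache, list(z = z, h1 = h1, h1d = h1d, dm = dm))
  list(probs = probs, cache = cache)
}

# Cross-entropy loss and gradients for one batch.
network_grads <- function(params, batch, config, training = TRUE) {
  fwd <- network_forward(params, batch, config, training = training)
  probs <- fwd$probs
  cache <- fwd$cache
  B <- batch$B
  Y <- matrix(0, B, 11)
  Y[cbind(seq_len(B), batch$labels)] <- 1
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), batch$labels)], 1e-12)))
  if (!is.finite(loss)) stop("non-finite training loss")
  g <- list()
  dlogits <- (probs - Y) / B
  g[["o.W"]] <- crossprod(cache$h1d, dlogits)
  g[["o.b"]] <- colSums(dlogits)
  dh1d <- dlogits %*% t(params[["o.W"]])
  dh1 <- if (is.null(cache$dm)) dh1d else dh1d * cache$dm
  dpre <- dh1 * (1 - cache$h1^2)
  g[["h.W"]] <- crossprod(cache$z, dpre)
  g[["h.b"]] <- colSums(dpre)
  dz <- dpre %*% t(params[["h.W"]])

  Hw <- config$lstm_sdp_words; Hp <- config$lstm_sdp_pos; Hd <- config$lstm_sdp_dt
  off <- 0L
  take <- function(k) {
    cols <- (off + 1L):(off + k)
    off <<- off + k
    dz[, cols, drop = FALSE]
  }
  dzw <- take(Hw); dzp <- take(Hp); dzd <- take(Hd)

  back_chain <- function(name, fwd_chain, dH) {
    bk <- lstm_backward(fwd_chain, dH)
    g[[paste0(name, ".W")]] <<- bk$dW
    g[[paste0(name, ".U")]] <<- bk$dU
    g[[paste0(name, ".b")]] <<- bk$db
    bk$dX
  }
  final_grad <- function(fwd_chain, dlast) {
    T_ <- length(fwd_chain$h_all)
    dH <- lapply(seq_len(T_), function(t) matrix(0, nrow(dlast), ncol(dlast)))
    dH[[T_]] <- dlast
    dH
  }
  dXw <- back_chain("sdpw", cache$fw, final_grad(cache$fw, dzw))
  dXp <- back_chain("sdpp", cache$fp, final_grad(cache$fp, dzp))
  dXd <- back_chain("sdpd", cache$fd, final_grad(cache$fd, dzd))

  nwr <- nrow(params$E_word)
  dEw <- matrix(0, nwr, ncol(params$E_word))
  dEp <- matrix(0, nrow(params$E_pos), ncol(params$E_pos))
  dEd <- matrix(0, nrow(params$E_dt), ncol(params$E_dt))
  for (t in seq_along(dXw)) dEw <- accumulate_rows(dEw, batch$sdpw[, t], dXw[[t]])
  for (t in seq_along(dXp)) dEp <- accumulate_rows(dEp, batch$sdpp[, t], dXp[[t]])
  for (t in seq_along(dXd)) dEd <- accumulate_rows(dEd, batch$sdpd[, t], dXd[[t]])

  if (config$arch == "i") {
    Hs <- config$lstm_sentence
    dpool <- take(2 * Hs)
    dHcat <- max_pool_backward(cache$pool, dpool)
    Tn <- cache$Tn
    dHf <- lapply(dHcat, function(m) m[, 1:Hs, drop = FALSE])
    dHb_rev <- lapply(rev(seq_len(Tn)), function(t) {
      dHcat[[t]][, (Hs + 1):(2 * Hs), drop = FALSE]
    })
    dXf <- back_chain("sentf", cache$ff, dHf)
    dXb_rev <- back_chain("sentb", cache$fb, dHb_rev)
    Dw <- ncol(params$E_word); Dp <- config$pos_dim
    Dt <- config$token_type_dim
    dEt <- matrix(0, 5, Dt)
    for (t in seq_len(Tn)) {
      dXs <- dXf[[t]] + dXb_rev[[Tn + 1L - t]]
      dEw <- accumulate_rows(dEw, batch$sentw[, t], dXs[, 1:Dw, drop = FALSE])
      dEp <- accumulate_rows(dEp, batch$sentp[, t],
                             dXs[, (Dw + 1):(Dw + Dp), drop = FALSE])
      # position-bit blocks are fixed encodings: no parameters to update
      dEt <- accumulate_rows(dEt, batch$sentt[, t],
                             dXs[, (Dw + Dp + 21):(Dw + Dp + 20 + Dt),
                                 drop = FALSE])
    }
    g[["E_type"]] <- dEt
  }
  g[["E_word"]] <- dEw
  g[["E_pos"]] <- dEp
  g[["E_dt"]] <- dEd
  list(loss = loss, grads = g, probs = probs)
}

#' SDP-only network forward pass
#'
#' Softmax confidences for a batch; rows are non-negative and sum to 1.
#' Inference mode (no dropout) unless \code{training}.
#'
#' @param params Parameters from \code{\link{init_network}}.
#' @param batch A batch from \code{\link{make_batch}}.
#' @param config The matching \code{\link{model_config}} (arch "st").
#' @param training Apply dropout (training mode).
#' @return B x 11 confidence matrix.
#' @export
st_ann_forward <- function(params, batch, config, training = FALSE) {
  stopifnot(config$arch == "st")
  network_forward(params, batch, config, training = training)$probs
}

#' Sentence-augmented network forward pass
#'
#' @inheritParams st_ann_forward
#' @return B x 11 confidence matrix.
#' @export
i_ann_forward <- function(params, batch, config, training = FALSE) {
  stopifnot(config$arch == "i")
  network_forward(params, batch, config, training = training)$probs
}

nadam_new <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# Nadam update (Nesterov-accelerated Adam) with the published defaults
# mu = 0.9, nu = 0.999, eps = 1e-8.
nadam_step <- function(params, grads, state, lr, skip = "") {
  mu <- 0.9; nu <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    if (nm %in% skip) next
    gr <- grads[[nm]]
    state$m[[nm]] <- mu * state$m[[nm]] + (1 - mu) * gr
    state$v[[nm]] <- nu * state$v[[nm]] + (1 - nu) * gr^2
    mhat <- mu * state$m[[nm]] / (1 - mu^(t + 1)) + (1 - mu) * gr / (1 - mu^t)
    vhat <- state$v[[nm]] / (1 - nu^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

score_micro_f <- function(pred_ids, gold_ids, classes = cpr_eval_classes()) {
  m <- matrix(0L, 11, 11, dimnames = list(cpr_labels(), cpr_labels()))
  for (i in seq_along(pred_ids)) {
    m[gold_ids[i], pred_ids[i]] <- m[gold_ids[i], pred_ids[i]] + 1L
  }
  micro_metrics(confusion_matrix_from_counts(m), classes)$f
}

#' Train one network
#'
#' Categorical cross-entropy, Nadam, training examples reshuffled with the
#' run's seeded generator before every epoch. When dev examples are
#' supplied and \code{config$monitor_dev} is TRUE, the dev micro-F over
#' \code{score_classes} is logged after each epoch and training stops early
#' once it has failed to improve for \code{config$patience} consecutive
#' epochs; the parameters of the best-scoring epoch are returned. Without
#' dev monitoring the network trains for the fixed \code{config$epochs}.
#'
#' @param examples Encoded training examples.
#' @param config A \code{\link{model_config}}.
#' @param vectors Pretrained word vectors.
#' @param vocabs Output of \code{\link{corpus_vocabularies}}.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param dev_examples Optional encoded dev examples for early stopping.
#' @param score_classes Class subset for the dev metric (default the five
#'   officially evaluated classes).
#' @param verbose Print per-epoch progress.
#' @return A \code{cprex_model}: parameters, config, vocabularies, word
#'   vocabulary and a per-epoch training log.
#' @export
train_network <- function(examples, config, vectors, vocabs, seed = 0,
                          dev_examples = NULL,
                          score_classes = cpr_eval_classes(),
                          verbose = FALSE) {
  if (length(examples) == 0) stop("empty training set")
  set.seed(seed)
  n_pos <- length(vocabs$pos_vocab)
  n_dt <- length(vocabs$dt_vocab)
  params <- init_network(config, vectors, n_pos, n_dt)
  opt <- nadam_new(params)
  n <- length(examples)
  nwr <- nrow(params$E_word)
  log <- data.frame(epoch = integer(), loss = numeric(), dev_f = numeric())
  best <- list(score = -Inf, params = params, epoch = 0L)
  bad <- 0L
  monitor <- !is.null(dev_examples) && isTRUE(config$monitor_dev)
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      tot <- 0
      nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        batch <- make_batch(examples[idx], config, nwr, n_pos, n_dt)
        res <- network_grads(params, batch, config, training = TRUE)
        upd <- nadam_step(params, res$grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        tot <- tot + res$loss
        nb <- nb + 1L
      }
      dev_f <- NA_real_
      if (monitor) {
        probs <- predict_confidences_params(params, config, dev_examples,
                                            n_pos, n_dt)
        pred <- max.col(probs, ties.method = "first")
        gold <- vapply(dev_examples, function(e) e$label_id, 0L)
        dev_f <- score_micro_f(pred, gold, score_classes)
        if (dev_f > best$score) {
          best <- list(score = dev_f, params = params, epoch = ep)
          bad <- 0L
        } else {
          bad <- bad + 1L
        }
      }
      log <- rbind(log, data.frame(epoch = ep, loss = tot / nb, dev_f = dev_f))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f dev_f %s", ep, tot / nb,
                        ifelse(is.na(dev_f), "-", sprintf("%.2f", dev_f))))
      }
      if (monitor && bad >= config$patience) break
    }
  }
  if (monitor && best$epoch > 0L) params <- best$params
  structure(list(params = params, config = config, vocabs = vocabs,
                 word_vocab = vectors$vocab, seed = seed, log = log,
                 best_epoch = if (monitor) best$epoch else config$epochs),
            class = "cprex_model")
}

predict_confidences_params <- function(params, config, examples, n_pos, n_dt,
                                       batch_size = 64L) {
  nwr <- nrow(params$E_word)
  out <- matrix(0, length(examples), 11)
  for (start in seq(1, length(examples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(examples))
    batch <- make_batch(examples[idx], config, nwr, n_pos, n_dt)
    out[idx, ] <- network_forward(params, batch, config, training = FALSE)$probs
  }
  colnames(out) <- cpr_labels()
  out
}

#' Predict class confidences with a trained network
#'
#' Inference mode: dropout disabled, deterministic.
#'
#' @param model A \code{cprex_model} from \code{\link{train_network}}.
#' @param examples Encoded examples.
#' @param batch_size Prediction batch size.
#' @return n x 11 matrix of softmax confidences (columns in canonical
#'   label order).
#' @export
predict_confidences <- function(model, examples, batch_size = 64L) {
  predict_confidences_params(model$params, model$config, examples,
                             length(model$vocabs$pos_vocab),
                             length(model$vocabs$dt_vocab),
                             batch_size = batch_size)
}

#' @export
print.cprex_model <- function(x, ...) {
  cat(sprintf("<cprex_model arch=%s> %d parameter blocks, best epoch %d\n",
              x$config$arch, length(x$params), x$best_epoch))
  invisible(x)
}
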