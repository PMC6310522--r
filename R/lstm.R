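# Batched LSTM forward/backward passes, max-over-time pooling and dense
# layers, in plain matrix code. Gate layout in the 4H-wide parameter blocks
# is (input, forget, output, candidate). Padded positions are handled by a
# carry-through mask: at masked steps the hidden and cell states pass
# through unchanged, so the "final" state is the state at the last unmasked
# position and appending padding cannot change any output.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

# LSTM parameter block; forget-gate bias initialized to 1 (standard remedy
# against early vanishing of the cell state).
lstm_init <- function(input_dim, hidden_dim) {
  b <- numeric(4 * hidden_dim)
  b[(hidden_dim + 1):(2 * hidden_dim)] <- 1
  list(W = glorot(input_dim, 4 * hidden_dim),
       U = glorot(hidden_dim, 4 * hidden_dim),
       b = b)
}

# X: list over time of B x D matrices; mask: T x B matrix of 0/1.
# Returns h_all (list of B x H post-mask states), h_final, and a cache for
# the backward pass.
lstm_forward <- function(X, mask, W, U, b) {
  T_ <- length(X)
  B <- nrow(X[[1]])
  H <- ncol(U)
  Hh <- H / 4
  h <- matrix(0, B, Hh)
  cc <- matrix(0, B, Hh)
  bmat <- matrix(b, B, H, byrow = TRUE)
  ii <- 1:Hh; fi <- Hh + ii; oi <- 2 * Hh + ii; gi <- 3 * Hh + ii
  steps <- vector("list", T_)
  h_all <- vector("list", T_)
  for (t in seq_len(T_)) {
    A <- X[[t]] %*% W + h %*% U + bmat
    i <- sigmoid(A[, ii, drop = FALSE])
    f <- sigmoid(A[, fi, drop = FALSE])
    o <- sigmoid(A[, oi, drop = FALSE])
    g <- tanh(A[, gi, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[t, ]
    h_prev <- h; c_prev <- cc
    h <- h_new * m + h_prev * (1 - m)
    cc <- c_new * m + c_prev * (1 - m)
    steps[[t]] <- list(i = i, f = f, o = o, g = g, tc = tc,
                       c_prev = c_prev, h_prev = h_prev, m = m)
    h_all[[t]] <- h
  }
  list(h_all = h_all, h_final = h,
       cache = list(steps = steps, X = X, W = W, U = U, B = B, Hh = Hh))
}

# dH: list over time of B x H gradients on the post-mask hidden states
# (zeros where a chain's output is unused). Returns parameter gradients and
# dX, the gradients on the inputs.
lstm_backward <- function(fwd, dH) {
  cache <- fwd$cache
  steps <- cache$steps
  X <- cache$X; W <- cache$W; U <- cache$U
  T_ <- length(steps); B <- cache$B; Hh <- cache$Hh
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, nrow(U), ncol(U))
  db <- numeric(4 * Hh)
  dX <- vector("list", T_)
  dh_carry <- matrix(0, B, Hh)
  dc <- matrix(0, B, Hh)
  for (t in rev(seq_len(T_))) {
    st <- steps[[t]]
    m <- st$m
    dh <- dH[[t]] + dh_carry
    dh_new <- dh * m
    dh_prev_direct <- dh * (1 - m)
    dc_new <- dc * m
    dc_prev_direct <- dc * (1 - m)
    do_ <- dh_new * st$tc
    dc_new <- dc_new + dh_new * st$o * (1 - st$tc^2)
    df <- dc_new * st$c_prev
    di <- dc_new * st$g
    dg <- dc_new * st$i
    dc <- dc_new * st$f + dc_prev_direct
    dA <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dW <- dW + crossprod(X[[t]], dA)
    dU <- dU + crossprod(st$h_prev, dA)
    db <- db + colSums(dA)
    dX[[t]] <- dA %*% t(W)
    dh_carry <- dA %*% t(U) + dh_prev_direct
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# Max-over-time pooling over unmasked positions. H: list over time of
# B x K; mask T x B with at least one unmasked position per example.
max_pool_forward <- function(H, mask) {
  T_ <- length(H); B <- nrow(H[[1]]); K <- ncol(H[[1]])
  pooled <- matrix(-Inf, B, K)
  argt <- matrix(0L, B, K)
  for (t in seq_len(T_)) {
    Ht <- H[[t]]
    Ht[mask[t, ] == 0, ] <- -Inf
    upd <- Ht > pooled
    pooled[upd] <- Ht[upd]
    argt[upd] <- t
  }
  list(pooled = pooled, argt = argt, T_ = T_, B = B, K = K)
}

max_pool_backward <- function(pool, dP) {
  dH <- lapply(seq_len(pool$T_), function(t) matrix(0, pool$B, pool$K))
  for (t in seq_len(pool$T_)) {
    sel <- pool$argt == t
    if (any(sel)) {
      M <- dH[[t]]
      M[sel] <- dP[sel]
      dH[[t]] <- M
    }
  }
  dH
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# accumulate row-indexed gradients into an embedding gradient matrix
accumulate_rows <- function(dE, ids, grads) {
  agg <- rowsum(grads, ids)
  ridx <- as.integer(rownames(agg))
  dE[ridx, ] <- dE[ridx, , drop = FALSE] + agg
  dE
}
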