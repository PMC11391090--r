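# Layer builders on top of the autodiff tape, shared by the hierarchical
# transformer and the flat baseline encoders, plus parameter initialisers
# and the Adam update rule.

# sinusoidal positional encodings; row p is position p-1, so position 0 is
# (0, 1, 0, 1, ...)
pe_matrix <- function(n_pos, d) {
  stopifnot(d %% 2 == 0)
  pos <- matrix(0:(n_pos - 1), n_pos, d / 2)
  i <- matrix(seq(0, d - 2, by = 2), n_pos, d / 2, byrow = TRUE)
  angle <- pos / 10000^(i / d)
  out <- matrix(0, n_pos, d)
  out[, seq(1, d, by = 2)] <- sin(angle)
  out[, seq(2, d, by = 2)] <- cos(angle)
  out
}

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

zeros <- function(nr, nc) matrix(0, nr, nc)
ones_row <- function(d) matrix(1, 1, d)

# parameter set of one transformer encoder layer (pre-attention projections,
# output projection, two layernorms, position-wise FFN)
init_tf_layer <- function(params, prefix, d, ffn_mult) {
  params[[paste0(prefix, "_Wq")]] <- glorot(d, d)
  params[[paste0(prefix, "_Wk")]] <- glorot(d, d)
  params[[paste0(prefix, "_Wv")]] <- glorot(d, d)
  params[[paste0(prefix, "_Wo")]] <- glorot(d, d)
  params[[paste0(prefix, "_ln1_g")]] <- ones_row(d)
  params[[paste0(prefix, "_ln1_b")]] <- zeros(1, d)
  params[[paste0(prefix, "_W1")]] <- glorot(d, ffn_mult * d)
  params[[paste0(prefix, "_b1")]] <- zeros(1, ffn_mult * d)
  params[[paste0(prefix, "_W2")]] <- glorot(ffn_mult * d, d)
  params[[paste0(prefix, "_b2")]] <- zeros(1, d)
  params[[paste0(prefix, "_ln2_g")]] <- ones_row(d)
  params[[paste0(prefix, "_ln2_b")]] <- zeros(1, d)
  params
}

# one transformer encoder layer: multi-head self-attention -> residual +
# layernorm -> position-wise FFN (ReLU) -> residual + layernorm.
# `mask` is an additive S x S matrix (0 allowed / -Inf blocked) or NULL.
tf_layer <- function(tp, params, x, prefix, n_heads, mask = NULL,
                     dropmask = NULL) {
  d <- ncol(tp_value(tp, x))
  dk <- d %/% n_heads
  Wq <- tp_param(tp, params, paste0(prefix, "_Wq"))
  Wk <- tp_param(tp, params, paste0(prefix, "_Wk"))
  Wv <- tp_param(tp, params, paste0(prefix, "_Wv"))
  Wo <- tp_param(tp, params, paste0(prefix, "_Wo"))
  q <- tp_mm(tp, x, Wq)
  k <- tp_mm(tp, x, Wk)
  v <- tp_mm(tp, x, Wv)
  heads <- integer(n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- tp_cols(tp, q, idx)
    kh <- tp_cols(tp, k, idx)
    vh <- tp_cols(tp, v, idx)
    heads[h] <- tp_attention(tp, qh, kh, vh, 1 / sqrt(dk), mask)
  }
  mh <- if (n_heads == 1) heads[1] else tp_cbind(tp, heads)
  o <- tp_mm(tp, mh, Wo)
  if (!is.null(dropmask)) o <- tp_mulc(tp, o, dropmask$attn)
  x <- tp_layernorm(tp, tp_add(tp, x, o),
                    tp_param(tp, params, paste0(prefix, "_ln1_g")),
                    tp_param(tp, params, paste0(prefix, "_ln1_b")))
  W1 <- tp_param(tp, params, paste0(prefix, "_W1"))
  b1 <- tp_param(tp, params, paste0(prefix, "_b1"))
  W2 <- tp_param(tp, params, paste0(prefix, "_W2"))
  b2 <- tp_param(tp, params, paste0(prefix, "_b2"))
  f <- tp_addvec(tp, tp_mm(tp, tp_relu(tp, tp_addvec(tp, tp_mm(tp, x, W1), b1)),
                           W2), b2)
  if (!is.null(dropmask)) f <- tp_mulc(tp, f, dropmask$ffn)
  tp_layernorm(tp, tp_add(tp, x, f),
               tp_param(tp, params, paste0(prefix, "_ln2_g")),
               tp_param(tp, params, paste0(prefix, "_ln2_b")))
}

# inverted-dropout masks for one transformer layer call (training only)
tf_dropmask <- function(nr, d, p) {
  if (is.null(p) || p <= 0) return(NULL)
  keep <- function() matrix(stats::rbinom(nr * d, 1, 1 - p) / (1 - p), nr, d)
  list(attn = keep(), ffn = keep())
}

init_attn_pool <- function(params, prefix, h_dim, attn_size) {
  params[[paste0(prefix, "_W")]] <- glorot(h_dim, attn_size)
  params[[paste0(prefix, "_v")]] <- glorot(1, attn_size)
  params
}

# additive (Bahdanau-style) attention pooling over the rows of H (T x h):
# alpha_i = softmax_i(v' tanh(W h_i)); returns list(pooled 1 x h, alpha 1 x T)
attn_pool <- function(tp, params, H, prefix) {
  W <- tp_param(tp, params, paste0(prefix, "_W"))
  v <- tp_param(tp, params, paste0(prefix, "_v"))
  s <- tp_mmT(tp, v, tp_tanh(tp, tp_mm(tp, H, W)))
  alpha <- tp_softmax_rows(tp, s)
  list(pooled = tp_mm(tp, alpha, H), alpha = alpha)
}

init_lstm <- function(params, prefix, d_in, hidden) {
  params[[paste0(prefix, "_Wx")]] <- glorot(d_in, 4 * hidden)
  params[[paste0(prefix, "_Wh")]] <- glorot(hidden, 4 * hidden)
  b <- zeros(1, 4 * hidden)
  b[1, (hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
  params[[paste0(prefix, "_b")]] <- b
  params
}

# run an LSTM over the rows of X (T x d); returns the T x hidden node of
# stacked hidden states
lstm_encode <- function(tp, params, X, prefix, hidden, reverse = FALSE) {
  Wx <- tp_param(tp, params, paste0(prefix, "_Wx"))
  Wh <- tp_param(tp, params, paste0(prefix, "_Wh"))
  b <- tp_param(tp, params, paste0(prefix, "_b"))
  n <- nrow(tp_value(tp, X))
  h <- tp_const(tp, zeros(1, hidden))
  cc <- tp_const(tp, zeros(1, hidden))
  steps <- if (reverse) n:1 else 1:n
  hs <- integer(n)
  for (t in steps) {
    xt <- tp_rows(tp, X, t)
    hc <- tp_lstm_step(tp, xt, h, cc, Wx, Wh, b)
    h <- tp_cols(tp, hc, 1:hidden)
    cc <- tp_cols(tp, hc, (hidden + 1):(2 * hidden))
    hs[t] <- h
  }
  if (n == 1) hs[1] else tp_rbind(tp, hs)
}

init_gru <- function(params, prefix, d_in, hidden) {
  params[[paste0(prefix, "_Wx")]] <- glorot(d_in, 3 * hidden)
  params[[paste0(prefix, "_Wh")]] <- glorot(hidden, 3 * hidden)
  params[[paste0(prefix, "_bx")]] <- zeros(1, 3 * hidden)
  params[[paste0(prefix, "_bh")]] <- zeros(1, 3 * hidden)
  params
}

gru_encode <- function(tp, params, X, prefix, hidden, reverse = FALSE) {
  Wx <- tp_param(tp, params, paste0(prefix, "_Wx"))
  Wh <- tp_param(tp, params, paste0(prefix, "_Wh"))
  bx <- tp_param(tp, params, paste0(prefix, "_bx"))
  bh <- tp_param(tp, params, paste0(prefix, "_bh"))
  n <- nrow(tp_value(tp, X))
  h <- tp_const(tp, zeros(1, hidden))
  steps <- if (reverse) n:1 else 1:n
  hs <- integer(n)
  for (t in steps) {
    xt <- tp_rows(tp, X, t)
    h <- tp_gru_step(tp, xt, h, Wx, Wh, bx, bh)
    hs[t] <- h
  }
  if (n == 1) hs[1] else tp_rbind(tp, hs)
}

init_cnn <- function(params, prefix, d_in, kernel_sizes, filters) {
  for (k in kernel_sizes) {
    params[[paste0(prefix, "_W", k)]] <- glorot(k * d_in, filters)
    params[[paste0(prefix, "_b", k)]] <- zeros(1, filters)
  }
  params
}

# 1-D convolutions over the rows of E (T x d) with ReLU and max-over-time
# pooling per kernel size, concatenated -> 1 x (|kernel_sizes| * filters)
conv_encode <- function(tp, params, E, prefix, kernel_sizes, filters) {
  t_len <- nrow(tp_value(tp, E))
  d <- ncol(tp_value(tp, E))
  kmax <- max(kernel_sizes)
  if (t_len < kmax) {
    pad <- tp_const(tp, zeros(kmax - t_len, d))
    E <- tp_rbind(tp, c(E, pad))
    t_len <- kmax
  }
  pooled <- integer(length(kernel_sizes))
  for (ki in seq_along(kernel_sizes)) {
    k <- kernel_sizes[ki]
    n_win <- t_len - k + 1L
    shifted <- integer(k)
    for (j in seq_len(k)) shifted[j] <- tp_rows(tp, E, j:(n_win + j - 1L))
    U <- if (k == 1) shifted[1] else tp_cbind(tp, shifted)
    W <- tp_param(tp, params, paste0(prefix, "_W", k))
    b <- tp_param(tp, params, paste0(prefix, "_b", k))
    conv <- tp_relu(tp, tp_addvec(tp, tp_mm(tp, U, W), b))
    pooled[ki] <- tp_colmax(tp, conv)
  }
  if (length(pooled) == 1) pooled[1] else tp_cbind(tp, pooled)
}

# Adam optimiser state and in-place style update (returns new params/state)
adam_new <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr = 1e-3) {
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}
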