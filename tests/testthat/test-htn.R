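tiny_htn <- function(d = 8, heads = 2, seed = 7, ...) {
  words <- c(sprintf("w%02d", 1:12), "sig1", "sig2")
  emb <- tiny_embeddings(words, d = d, seed = 3)
  cfg <- htn_config(d_model = d, n_heads = heads, n_word_layers = 1,
                    n_post_layers = 1, ffn_mult = 2, lstm_hidden = 6,
                    attn_size = 5, dropout = 0, ...)
  htn_model(cfg, emb, seed = seed)
}

test_that("sinusoidal positional encoding starts at (0, 1, 0, 1, ...)", {
  pe <- deprscreen:::pe_matrix(4, 6)
  expect_equal(pe[1, ], c(0, 1, 0, 1, 0, 1))
  # position 1, first pair is (sin 1, cos 1)
  expect_equal(pe[2, 1:2], c(sin(1), cos(1)))
})

test_that("padding mask: a post's encoding ignores other posts' padded slots", {
  m <- tiny_htn()
  short <- c("w01", "w02")
  long <- c("w03", "w04", "w05", "w06", "w07")
  alone <- encode_post(short, m)
  # encoded together, the short post is padded up to the long post's length
  tp <- deprscreen:::tape_new()
  both <- deprscreen:::tp_value(
    tp, deprscreen:::htn_word_level(tp, m, list(short, long)))
  expect_equal(both[1, ], alone, tolerance = 1e-12)
  expect_equal(both[2, ], encode_post(long, m), tolerance = 1e-12)
  expect_error(encode_post(character(0), m), "empty")
})

test_that("post-level encoder is length-preserving and order-sensitive", {
  m <- tiny_htn()
  x1 <- matrix(stats::rnorm(8), 1)
  out1 <- encode_post_sequence(x1, m)
  expect_equal(dim(out1), c(1, 8))

  set.seed(5)
  x3 <- matrix(stats::rnorm(24), 3)
  out3 <- encode_post_sequence(x3, m)
  expect_equal(dim(out3), c(3, 8))
  perm <- encode_post_sequence(x3[c(2, 3, 1), ], m)
  expect_false(isTRUE(all.equal(out3[c(2, 3, 1), ], perm)))
})

test_that("without positional encodings, identical post vectors stay identical", {
  m <- tiny_htn(use_positional = FALSE)
  x <- matrix(rep(stats::rnorm(8), each = 3), 3)
  out <- encode_post_sequence(x, m)
  expect_equal(out[1, ], out[2, ], tolerance = 1e-12)
  expect_equal(out[2, ], out[3, ], tolerance = 1e-12)
})

test_that("attention-LSTM aggregation: weights sum to 1; singleton gives h1", {
  m <- tiny_htn()
  set.seed(2)
  x <- matrix(stats::rnorm(4 * 8), 4)
  agg <- aggregate_posts(x, m)
  expect_equal(sum(agg$attention), 1, tolerance = 1e-9)

  one <- aggregate_posts(x[1, , drop = FALSE], m)
  expect_equal(one$attention, 1)
  # with one step the pooled vector IS the single hidden state
  tp <- deprscreen:::tape_new()
  X <- deprscreen:::tp_const(tp, x[1, , drop = FALSE])
  H <- deprscreen:::lstm_encode(tp, m$params, X, "lstm", 6)
  expect_equal(one$user_vector, as.numeric(deprscreen:::tp_value(tp, H)),
               tolerance = 1e-12)
})

test_that("aggregation matches a hand-traced scalar LSTM + softmax attention", {
  m <- tiny_htn(d = 2, heads = 1)
  m$config$lstm_hidden <- 1L
  m$config$attn_size <- 1L
  # hand-set scalar parameters; gate layout [input, forget, cell, output]
  m$params$lstm_Wx <- matrix(c(0.5, -0.3,   # input gate
                               0.2, 0.1,    # forget gate
                               1.0, -0.5,   # cell candidate
                               0.3, 0.7), 2, 4)
  m$params$lstm_Wh <- matrix(c(0.25, -0.5, 0.75, 0.1), 1, 4)
  m$params$lstm_b <- matrix(c(0.1, 1, -0.2, 0.05), 1, 4)
  m$params$attn_W <- matrix(0.8, 1, 1)
  m$params$attn_v <- matrix(1.5, 1, 1)
  x <- matrix(c(0.6, -0.4, -0.2, 0.9), 2, 2, byrow = TRUE)

  h <- 0; cc <- 0; hs <- numeric(2)
  for (t in 1:2) {
    z <- x[t, ] %*% m$params$lstm_Wx + h * m$params$lstm_Wh + m$params$lstm_b
    i <- o_sigmoid(z[1]); f <- o_sigmoid(z[2]); g <- tanh(z[3])
    o <- o_sigmoid(z[4])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    hs[t] <- h
  }
  alpha <- o_softmax(1.5 * tanh(0.8 * hs))
  want <- sum(alpha * hs)

  got <- aggregate_posts(x, m)
  expect_equal(got$user_vector, want, tolerance = 1e-8)
  expect_equal(got$attention, as.numeric(alpha), tolerance = 1e-8)
})

test_that("classifier head: sigmoid behaviour and threshold", {
  m <- tiny_htn()
  m$params$clf_w <- matrix(0, 6, 1)
  m$params$clf_b <- matrix(0, 1, 1)
  expect_equal(classify_user(stats::rnorm(6), m)$probability, 0.5)

  m$params$clf_b <- matrix(2, 1, 1)
  p2 <- classify_user(rep(0, 6), m)
  expect_equal(p2$probability, 0.8808, tolerance = 1e-4)
  expect_equal(p2$label, "depressed")
  m$params$clf_b <- matrix(3, 1, 1)
  expect_gt(classify_user(rep(0, 6), m)$probability, p2$probability)
  m$params$clf_b <- matrix(-1, 1, 1)
  expect_equal(classify_user(rep(0, 6), m)$label, "control")
})

test_that("predict_user is deterministic, view-consistent, and per-post encodings shared", {
  m <- tiny_htn()
  posts <- make_posts(list(c("w01", "sig1"), c("w02", "w03"),
                           c("sig2", "w04", "w05")))
  p1 <- predict_user(posts, NULL, m)
  p2 <- predict_user(posts, NULL, m)
  expect_identical(p1$probability, p2$probability)

  # a rate-1 view equals no view at all
  corpus <- new_corpus(list(list(user_id = "u1", label = "depressed",
                                 posts = posts)))
  v_all <- sample_corpus(corpus, "none")
  expect_identical(predict_user(posts, v_all, m)$probability, p1$probability)

  # duplicated posts encode identically post-by-post (shared word encoder)
  e1 <- encode_post(c("w01", "sig1"), m)
  e2 <- encode_post(c("w01", "sig1"), m)
  expect_identical(e1, e2)
})

test_that("every softmax in a forward pass sums to one", {
  m <- tiny_htn()
  tp <- deprscreen:::tape_new()
  deprscreen:::forward_user(m, tp, list(c("w01", "w02"), c("sig1", "w03", "w04")))
  for (i in seq_len(tp$n)) {
    if (tp$op[i] == "softmaxr") {
      expect_equal(rowSums(deprscreen:::tp_value(tp, i)),
                   rep(1, nrow(deprscreen:::tp_value(tp, i))),
                   tolerance = 1e-6)
    }
    if (tp$op[i] %in% c("attn", "attnb")) {
      aux <- tp$aux[[i]]
      As <- if (tp$op[i] == "attn") list(aux$A) else aux$As
      for (A in As) expect_equal(rowSums(A), rep(1, nrow(A)),
                                 tolerance = 1e-6)
    }
  }
})

test_that("checkpoints reload bit-exactly", {
  m <- tiny_htn()
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  posts <- make_posts(list(c("w01", "w02"), c("sig1", "w03")))
  expect_identical(predict_user(posts, NULL, m)$probability,
                   predict_user(posts, NULL, back)$probability)
})

test_that("config invariants are enforced", {
  expect_error(htn_config(d_model = 10, n_heads = 4), "divisible")
  expect_error(htn_config(dropout = 1), "dropout")
  expect_silent(htn_config())
})
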