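test_that("metrics match hand-computed confusion-matrix cases", {
  # perfect predictions
  perfect <- metrics_report(rep(c("depressed", "control"), 3),
                            rep(c("depressed", "control"), 3))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)

  # truth DDDNNN, predictions DDNDNN: accuracy 4/6, macro-F1 2/3
  truth <- c("depressed", "depressed", "depressed",
             "control", "control", "control")
  pred <- c("depressed", "depressed", "control",
            "depressed", "control", "control")
  rep <- metrics_report(truth, pred)
  expect_equal(rep$accuracy, 4 / 6, tolerance = 1e-12)
  expect_equal(rep$macro_f1, 2 / 3, tolerance = 1e-12)

  # constant predictor on a balanced set: accuracy one half
  const <- suppressWarnings(
    metrics_report(rep(c("depressed", "control"), 10),
                   rep("depressed", 20)))
  expect_equal(const$accuracy, 0.5)
})

test_that("0/0 metrics fall back to zero with a warning", {
  truth <- rep("control", 4)
  pred <- rep("control", 4)
  w <- capture_warnings(r <- metrics_report(truth, pred))
  expect_true(any(grepl("0/0", w)))
  expect_equal(r$per_class$precision[r$per_class$class == "depressed"], 0)
  expect_equal(r$accuracy, 1)
})

test_that("evaluate agrees with the brute-force metric oracle on random vectors", {
  set.seed(99)
  classes <- c("depressed", "control")
  for (i in 1:200) {
    n <- sample(4:40, 1)
    truth <- sample(classes, n, replace = TRUE)
    if (length(unique(truth)) == 1) truth[1] <- setdiff(classes, truth[1])
    pred <- sample(classes, n, replace = TRUE)
    got <- suppressWarnings(metrics_report(truth, pred))
    want <- brute_metrics(truth, pred)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$macro_precision, want$macro_precision, tolerance = 1e-12)
    expect_equal(got$macro_recall, want$macro_recall, tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
  }
})

test_that("stratified split honours exact per-class counts, determinism, disjointness", {
  corpus <- generate_corpus(gen_config(n_users_per_class = 16,
                                       posts_per_user = c(4, 5),
                                       tokens_per_post = c(5, 6), seed = 3))
  split <- split_corpus(corpus, c(10, 3, 3), seed = 2)
  tab <- table(split$label, split$split)
  expect_true(all(tab["depressed", c("train", "validation", "test")] ==
                    c(10, 3, 3)))
  expect_true(all(tab["control", c("train", "validation", "test")] ==
                    c(10, 3, 3)))
  split2 <- split_corpus(corpus, c(10, 3, 3), seed = 2)
  expect_identical(split$split, split2$split)
  split3 <- split_corpus(corpus, c(10, 3, 3), seed = 5)
  expect_false(identical(split$split, split3$split))
  expect_error(split_corpus(corpus, c(15, 3, 3), seed = 1),
               "class 'depressed'")
})

toy_study <- function() {
  # linearly separable toy task: signal tokens perfectly predict the label
  words <- c(sprintf("w%02d", 1:10), "sig1", "sig2")
  emb <- tiny_embeddings(words, d = 6, seed = 8)
  mk <- function(signal) {
    purrr::map(1:3, function(i) {
      if (signal) list(c("sig1", "sig2", "w01"), c("sig2", "w02", "sig1"))
      else list(c("w03", "w04", "w05"), c("w06", "w07", "w08"))
    })
  }
  users <- c(
    purrr::imap(mk(TRUE), ~ list(user_id = paste0("d", .y),
                                 label = "depressed",
                                 posts = make_posts(.x))),
    purrr::imap(mk(FALSE), ~ list(user_id = paste0("c", .y),
                                  label = "control",
                                  posts = make_posts(.x))))
  corpus <- new_corpus(users)
  corpus$split <- rep(c("train", "train", "validation"), 2)
  list(corpus = corpus, emb = emb)
}

test_that("zero training epochs returns the initial parameters", {
  st <- toy_study()
  m <- make_encoder("htn", st$emb, seed = 1,
                    model_args = list(d_model = 6, n_heads = 2,
                                      n_word_layers = 1, n_post_layers = 1,
                                      ffn_mult = 2, lstm_hidden = 4,
                                      attn_size = 4, dropout = 0))
  fit <- train_model(m, st$corpus, NULL,
                     train_config(max_epochs = 0, seed = 1))
  expect_identical(fit$params, m$params)
  expect_equal(nrow(fit$log), 0)
})

test_that("training separates a separable toy task and the loss decreases", {
  st <- toy_study()
  m <- make_encoder("htn", st$emb, seed = 1,
                    model_args = list(d_model = 6, n_heads = 2,
                                      n_word_layers = 1, n_post_layers = 1,
                                      ffn_mult = 2, lstm_hidden = 4,
                                      attn_size = 4, dropout = 0))
  fit <- suppressWarnings(
    train_model(m, st$corpus, NULL,
                train_config(max_epochs = 40, batch_size = 4, seed = 1,
                             patience = 40)))
  expect_true(all(diff(fit$log$train_loss[1:5]) < 0))
  final <- evaluate_model(fit, st$corpus, NULL, split = "train")
  expect_equal(final$accuracy, 1)
})

test_that("training is bit-identical across repeated seeded runs", {
  st <- toy_study()
  run <- function() {
    m <- make_encoder("htn", st$emb, seed = 4,
                      model_args = list(d_model = 6, n_heads = 2,
                                        n_word_layers = 1, n_post_layers = 1,
                                        ffn_mult = 2, lstm_hidden = 4,
                                        attn_size = 4, dropout = 0.1))
    train_model(m, st$corpus, NULL,
                train_config(max_epochs = 2, batch_size = 2, seed = 4))
  }
  f1 <- suppressWarnings(run())
  f2 <- suppressWarnings(run())
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("non-finite loss aborts with a diagnostic", {
  st <- toy_study()
  m <- make_encoder("htn", st$emb, seed = 1,
                    model_args = list(d_model = 6, n_heads = 2,
                                      n_word_layers = 1, n_post_layers = 1,
                                      ffn_mult = 2, lstm_hidden = 4,
                                      attn_size = 4, dropout = 0))
  m$params$clf_b <- matrix(NaN, 1, 1)
  expect_error(train_model(m, st$corpus, NULL,
                           train_config(max_epochs = 1, seed = 1)),
               "non-finite training loss")
})

test_that("grid runner enumerates cells, treats 'none' as rate-free, and matches rate 1", {
  st <- toy_study()
  args <- list(d_model = 6, n_heads = 2, n_word_layers = 1, n_post_layers = 1,
               ffn_mult = 2, lstm_hidden = 4, attn_size = 4, dropout = 0)
  lex <- new_lexicon(c("sig1", "sig2"))
  # test split needed for grid evaluation: reuse validation users as test
  corpus <- st$corpus
  corpus$split[corpus$split == "validation"] <- "test"
  corpus$split[c(2, 5)] <- "validation"
  grid <- suppressWarnings(run_grid(corpus, strategies = c("none", "random"),
                   rates = c(0.5, 1), encoders = "htn", seeds = c(1, 2),
                   embeddings = st$emb, lexicon = lex,
                   train_cfg = train_config(max_epochs = 1, batch_size = 2),
                   model_args = args))
  # none ignores rate: 1 x 2 seeds; random: 2 rates x 2 seeds
  expect_equal(nrow(grid), 6)
  expect_true(all(is.na(grid$error)))
  expect_true(all(is.na(grid$rate[grid$strategy == "none"])))

  # retrieval at rate 1 equals strategy none for the same seed
  g2 <- suppressWarnings(
    run_grid(corpus, strategies = c("none", "retrieval"), rates = 1,
             encoders = "htn", seeds = 1, embeddings = st$emb,
             lexicon = lex,
             train_cfg = train_config(max_epochs = 1, batch_size = 2),
             model_args = args))
  expect_equal(g2$macro_f1[g2$strategy == "retrieval"],
               g2$macro_f1[g2$strategy == "none"], tolerance = 1e-12)
  summ <- summarize_grid(grid)
  expect_true(all(c("macro_f1_mean", "macro_f1_sd") %in% names(summ)))
})

test_that("tidiers expose metrics and model summaries as tibbles", {
  r <- metrics_report(c("depressed", "control"), c("depressed", "control"))
  td <- tidy(r)
  expect_equal(td$value, rep(1, 4))
  gl <- glance(r)
  expect_equal(gl$n, 2)
  st <- toy_study()
  m <- make_encoder("cnn", st$emb, seed = 1,
                    model_args = list(cnn_filters = 4,
                                      cnn_kernel_sizes = c(2, 3)))
  expect_equal(glance(m)$encoder, "cnn")
})
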