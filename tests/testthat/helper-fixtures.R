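# Fixture builders shared across test files; everything is generated in code.

# posts tibble from a list of token vectors, hourly timestamps
make_posts <- function(token_lists, texts = NULL, t0 = "2023-01-01T00:00:00") {
  n <- length(token_lists)
  ts0 <- as.POSIXct(t0, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  tibble::tibble(
    post_id = sprintf("p%03d", seq_len(n)),
    ts = ts0 + 3600 * (seq_len(n) - 1),
    text = if (is.null(texts)) purrr::map_chr(token_lists, paste, collapse = " ")
           else texts,
    tokens = token_lists
  )
}

mini_corpus <- function(user_tokens, labels) {
  users <- purrr::map(seq_along(user_tokens), function(i) {
    uid <- names(user_tokens)[i]
    if (is.null(uid) || !nzchar(uid)) uid <- sprintf("u%03d", i)
    list(user_id = uid, label = labels[i], posts = make_posts(user_tokens[[i]]))
  })
  new_corpus(users)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# whitespace tokenizer test double for the pluggable segmenter contract
ws_tokenizer <- function(text, vocab = NULL) {
  strsplit(trimws(text), "\\s+")[[1]]
}

tiny_embeddings <- function(words, d = 8, seed = 11) {
  generate_embeddings(words, d, seed = seed)
}

# an independent brute-force implementation of accuracy and macro metrics,
# written with explicit per-element loops (the oracle for evaluate())
brute_metrics <- function(truth, predicted) {
  classes <- c("depressed", "control")
  n <- length(truth)
  correct <- 0
  for (i in seq_len(n)) if (truth[i] == predicted[i]) correct <- correct + 1
  ps <- rs <- f1s <- numeric(2)
  for (ci in 1:2) {
    cl <- classes[ci]
    tp <- fp <- fn <- 0
    for (i in seq_len(n)) {
      if (predicted[i] == cl && truth[i] == cl) tp <- tp + 1
      if (predicted[i] == cl && truth[i] != cl) fp <- fp + 1
      if (predicted[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    ps[ci] <- p; rs[ci] <- r; f1s[ci] <- f
  }
  list(accuracy = correct / n, macro_precision = mean(ps),
       macro_recall = mean(rs), macro_f1 = mean(f1s))
}

# brute-force retrieval sampling oracle: score by token loops, then pick the
# top k by repeated max-selection with the documented tie rules
brute_retrieval <- function(posts, lex_terms, rate) {
  n <- nrow(posts)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    for (tok in posts$tokens[[i]]) {
      if (tok %in% lex_terms) scores[i] <- scores[i] + 1
    }
  }
  k <- as.integer(ceiling(rate * n - 1e-9))
  remaining <- seq_len(n)
  picked <- integer(0)
  for (j in seq_len(k)) {
    best <- remaining[1]
    for (cand in remaining) {
      if (scores[cand] > scores[best]) best <- cand
      else if (scores[cand] == scores[best] && cand != best) {
        if (posts$ts[cand] > posts$ts[best]) best <- cand
        else if (posts$ts[cand] == posts$ts[best] && cand > best) best <- cand
      }
    }
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
  }
  sort(picked)
}

# plain (non-tape) numeric helpers for the straight-line forward oracle
o_softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
o_layernorm <- function(x, g, b, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  (x - mu) / sqrt(v + eps) * g + b
}
o_sigmoid <- function(x) 1 / (1 + exp(-x))
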