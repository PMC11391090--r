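#' Hierarchical transformer network configuration
#'
#' Architecture hyperparameters of the two-level transformer with
#' attention-LSTM aggregation. Defaults follow the canonical setting: hidden
#' and attention size 256, posts padded/truncated to 512 words; layer and
#' head counts are configurable (2 layers / 4 heads by default, the smallest
#' capacity exercising multi-layer, multi-head paths).
#'
#' @param d_model Width of word/post representations (divisible by `n_heads`).
#' @param n_heads Attention heads per transformer layer.
#' @param n_word_layers,n_post_layers Depths of the word-level and post-level
#'   transformers.
#' @param ffn_mult Feed-forward expansion factor.
#' @param lstm_hidden Hidden size of the aggregation LSTM.
#' @param attn_size Additive-attention projection size.
#' @param max_post_tokens Posts are truncated to this many words.
#' @param max_posts_per_user Cap on encoded posts per user; the most recent
#'   are kept.
#' @param dropout Dropout rate in `[0, 1)` applied inside transformer layers
#'   during training.
#' @param use_positional Add sinusoidal positional encodings (disable only
#'   for diagnostic symmetry checks).
#' @return An `htn_config` object.
#' @export
htn_config <- function(d_model = 256L, n_heads = 4L, n_word_layers = 2L,
                       n_post_layers = 2L, ffn_mult = 4L, lstm_hidden = 256L,
                       attn_size = 256L, max_post_tokens = 512L,
                       max_posts_per_user = 128L, dropout = 0.1,
                       use_positional = TRUE) {
  assert_that(d_model %% n_heads == 0, "d_model must be divisible by n_heads")
  assert_that(all(c(d_model, n_heads, n_word_layers, n_post_layers, ffn_mult,
                    lstm_hidden, attn_size, max_post_tokens,
                    max_posts_per_user) >= 1), "all sizes must be positive")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_word_layers = as.integer(n_word_layers),
                 n_post_layers = as.integer(n_post_layers),
                 ffn_mult = as.integer(ffn_mult),
                 lstm_hidden = as.integer(lstm_hidden),
                 attn_size = as.integer(attn_size),
                 max_post_tokens = as.integer(max_post_tokens),
                 max_posts_per_user = as.integer(max_posts_per_user),
                 dropout = dropout, use_positional = use_positional),
            class = "htn_config")
}

#' Initialise a hierarchical transformer network
#'
#' Builds the parameter set: a trainable word-embedding matrix initialised
#' from `embeddings` (plus a trainable `<unk>` row following the table's
#' out-of-vocabulary policy), a learned `[CLS]` vector, the word-level
#' transformer (shared across all posts), the post-level transformer, the
#' aggregation LSTM with additive attention, and the sigmoid classifier head.
#' The embedding is projected to `d_model` via a trainable linear map when
#' the table dimension differs from `d_model`.
#'
#' @param config An [htn_config()].
#' @param embeddings An `embedding_table` used for initialisation.
#' @param seed Integer seed for parameter initialisation.
#' @return An `htn_model` object.
#' @export
htn_model <- function(config, embeddings, seed = 1L) {
  stopifnot(inherits(config, "htn_config"),
            inherits(embeddings, "embedding_table"))
  d <- config$d_model
  vocab_words <- embeddings$words
  emb0 <- rbind(embeddings$vectors,
                embedding_lookup(embeddings, "<unk>"))
  with_seed(seed, {
    params <- list()
    params$emb <- unname(emb0)
    if (ncol(emb0) != d) {
      params$emb_proj <- glorot(ncol(emb0), d)
    }
    params$cls <- matrix(stats::rnorm(d, sd = 0.02), 1, d)
    for (l in seq_len(config$n_word_layers)) {
      params <- init_tf_layer(params, paste0("wl", l), d, config$ffn_mult)
    }
    for (l in seq_len(config$n_post_layers)) {
      params <- init_tf_layer(params, paste0("pl", l), d, config$ffn_mult)
    }
    params <- init_lstm(params, "lstm", d, config$lstm_hidden)
    params <- init_attn_pool(params, "attn", config$lstm_hidden,
                             config$attn_size)
    params$clf_w <- glorot(config$lstm_hidden, 1)
    params$clf_b <- zeros(1, 1)
    structure(
      list(config = config, params = params,
           vocab = stats::setNames(seq_along(vocab_words), vocab_words),
           unk_id = length(vocab_words) + 1L, encoder = "htn"),
      class = c("htn_model", "deprscreen_model")
    )
  })
}

tokens_to_ids <- function(model, tokens) {
  ids <- unname(model$vocab[tokens])
  ids[is.na(ids)] <- model$unk_id
  as.integer(ids)
}

# embed a vector of token ids (0 = pad -> zero row), projecting to d_model
embed_ids <- function(tp, model, ids) {
  E <- tp_gather(tp, tp_param(tp, model$params, "emb"), ids)
  if (!is.null(model$params$emb_proj)) {
    E <- tp_mm(tp, E, tp_param(tp, model$params, "emb_proj"))
  }
  E
}

# truncate tokens to max_post_tokens, keep most recent max_posts_per_user
clip_user_posts <- function(model, token_list) {
  cfg <- model$config
  token_list <- lapply(token_list, utils::head, n = cfg$max_post_tokens)
  if (length(token_list) > cfg$max_posts_per_user) {
    token_list <- utils::tail(token_list, cfg$max_posts_per_user)
  }
  token_list
}

# word-level encoder over all posts of one user at once: posts are padded to
# a common length and stacked with a block-diagonal attention mask, so no
# token attends outside its own post and padded positions are inert.
# Returns the P x d_model node of [CLS] states.
htn_word_level <- function(tp, model, token_list, train = FALSE) {
  cfg <- model$config
  d <- cfg$d_model
  ids_list <- lapply(token_list, function(tk) tokens_to_ids(model, tk))
  P <- length(ids_list)
  L <- max(lengths(ids_list))
  S <- P * (L + 1L)
  flat <- unlist(lapply(ids_list, function(v) c(v, rep(0L, L - length(v)))))
  tok <- embed_ids(tp, model, flat)
  cls <- tp_param(tp, model$params, "cls")
  cls_rep <- if (P == 1) cls else tp_rows(tp, cls, rep(1L, P))
  stacked <- tp_rbind(tp, c(cls_rep, tok))
  # interleave: row (p-1)(L+1)+1 is post p's CLS, then its L token slots
  perm <- integer(S)
  for (p in seq_len(P)) {
    base <- (p - 1L) * (L + 1L)
    perm[base + 1L] <- p
    perm[base + 1L + seq_len(L)] <- P + (p - 1L) * L + seq_len(L)
  }
  x <- tp_rows(tp, stacked, perm)
  if (cfg$use_positional) {
    pe <- pe_matrix(L + 1L, d)
    x <- tp_addc(tp, x, pe[rep(seq_len(L + 1L), P), , drop = FALSE])
  }
  masks <- lapply(seq_len(P), function(p) {
    keys <- c(TRUE, seq_len(L) <= length(ids_list[[p]]))
    mk <- matrix(-Inf, L + 1L, L + 1L)
    mk[, keys] <- 0
    mk
  })
  mask <- list(bsize = L + 1L, masks = masks)
  for (l in seq_len(cfg$n_word_layers)) {
    dm <- if (train) tf_dropmask(S, d, cfg$dropout) else NULL
    x <- tf_layer(tp, model$params, x, paste0("wl", l), cfg$n_heads, mask, dm)
  }
  tp_rows(tp, x, (seq_len(P) - 1L) * (L + 1L) + 1L)
}

# post-level transformer over the chronological sequence of post vectors
htn_post_level <- function(tp, model, post_vecs, train = FALSE) {
  cfg <- model$config
  P <- nrow(tp_value(tp, post_vecs))
  x <- post_vecs
  if (cfg$use_positional) {
    x <- tp_addc(tp, x, pe_matrix(P, cfg$d_model))
  }
  for (l in seq_len(cfg$n_post_layers)) {
    dm <- if (train) tf_dropmask(P, cfg$d_model, cfg$dropout) else NULL
    x <- tf_layer(tp, model$params, x, paste0("pl", l), cfg$n_heads, NULL, dm)
  }
  x
}

# attention-LSTM aggregation to a single user vector (1 x lstm_hidden)
htn_aggregate <- function(tp, model, context) {
  H <- lstm_encode(tp, model$params, context, "lstm", model$config$lstm_hidden)
  attn_pool(tp, model$params, H, "attn")
}

htn_logit <- function(tp, model, context_or_user) {
  tp_addvec(tp, tp_mm(tp, context_or_user,
                      tp_param(tp, model$params, "clf_w")),
            tp_param(tp, model$params, "clf_b"))
}

# full forward pass for one user; returns the logit node (1 x 1)
forward_user <- function(model, tp, token_list, train = FALSE) {
  UseMethod("forward_user")
}

#' @export
forward_user.htn_model <- function(model, tp, token_list, train = FALSE) {
  token_list <- clip_user_posts(model, token_list)
  post_vecs <- htn_word_level(tp, model, token_list, train)
  context <- htn_post_level(tp, model, post_vecs, train)
  user_vec <- htn_aggregate(tp, model, context)$pooled
  htn_logit(tp, model, user_vec)
}

#' Encode a single post to its \[CLS\] vector
#'
#' Prepends the learned `[CLS]` token, adds sinusoidal positional encodings,
#' applies the word-level transformer with a padding mask and returns the
#' final-layer `[CLS]` state. Padded positions never change the output.
#'
#' @param tokens Character vector of segmented tokens (non-empty).
#' @param model An [htn_model()].
#' @return Numeric vector of length `d_model`.
#' @export
encode_post <- function(tokens, model) {
  assert_that(length(tokens) >= 1, "cannot encode an empty token sequence")
  tp <- tape_new()
  out <- htn_word_level(tp, model, list(as.character(tokens)))
  as.numeric(tp_value(tp, out))
}

#' Contextualize a chronological sequence of post vectors
#'
#' Runs the post-level transformer (with positional encodings on the post
#' index) over rows of `post_vectors`; length-preserving.
#'
#' @param post_vectors Numeric matrix, one post vector per row, in posting
#'   order.
#' @param model An [htn_model()].
#' @return Numeric matrix of the same shape.
#' @export
encode_post_sequence <- function(post_vectors, model) {
  if (is.numeric(post_vectors) && !is.matrix(post_vectors)) {
    post_vectors <- matrix(post_vectors, 1)
  }
  assert_that(nrow(post_vectors) >= 1, "post sequence must be non-empty")
  tp <- tape_new()
  x <- tp_const(tp, post_vectors)
  out <- htn_post_level(tp, model, x)
  tp_value(tp, out)
}

#' Aggregate contextualized post vectors into a user vector
#'
#' LSTM over the sequence followed by additive attention over the hidden
#' states: `alpha_i = softmax_i(v' tanh(W h_i))`, user vector
#' `sum_i alpha_i h_i`.
#'
#' @param context_vectors Numeric matrix of contextualized post vectors.
#' @param model An [htn_model()].
#' @return A list with `user_vector` (length `lstm_hidden`) and `attention`
#'   (weights summing to 1).
#' @export
aggregate_posts <- function(context_vectors, model) {
  if (is.numeric(context_vectors) && !is.matrix(context_vectors)) {
    context_vectors <- matrix(context_vectors, 1)
  }
  assert_that(nrow(context_vectors) >= 1, "sequence must be non-empty")
  tp <- tape_new()
  x <- tp_const(tp, context_vectors)
  res <- htn_aggregate(tp, model, x)
  list(user_vector = as.numeric(tp_value(tp, res$pooled)),
       attention = as.numeric(tp_value(tp, res$alpha)))
}

#' Classify a user vector
#'
#' `sigmoid(w'u + b)`; the predicted label is `depressed` when the
#' probability reaches `threshold`.
#'
#' @param user_vector Numeric vector of length `lstm_hidden`.
#' @param model A fitted or initialised model with a classifier head.
#' @param threshold Decision threshold (default 0.5).
#' @return A list with `probability` and `label`.
#' @export
classify_user <- function(user_vector, model, threshold = 0.5) {
  tp <- tape_new()
  u <- tp_const(tp, matrix(user_vector, 1))
  z <- tp_value(tp, htn_logit(tp, model, u))[1, 1]
  p <- 1 / (1 + exp(-z))
  list(probability = p,
       label = if (p >= threshold) "depressed" else "control")
}

#' Predict the depression risk of one user under a sampled view
#'
#' End-to-end forward pass over the posts the view selects; deterministic in
#' evaluation mode.
#'
#' @param posts The user's chronological posts tibble (tokens set).
#' @param view One-row sampled-view tibble for this user (or `NULL` for all
#'   posts).
#' @param model A `deprscreen_model`.
#' @param threshold Decision threshold.
#' @return A list with `probability` and `label`.
#' @export
predict_user <- function(posts, view = NULL, model, threshold = 0.5) {
  sel <- if (is.null(view)) seq_len(nrow(posts)) else view$selected[[1]]
  assert_that(length(sel) >= 1, "view selects no posts")
  token_list <- posts$tokens[sel]
  tp <- tape_new()
  z <- tp_value(tp, forward_user(model, tp, token_list))[1, 1]
  p <- 1 / (1 + exp(-z))
  list(probability = p,
       label = if (p >= threshold) "depressed" else "control")
}

#' Predict every user of a corpus
#'
#' @param corpus A corpus tibble.
#' @param views A sampled-view tibble ([sample_corpus()]); `NULL` means all
#'   posts.
#' @param model A `deprscreen_model`.
#' @param threshold Decision threshold.
#' @return A tibble with `user_id`, `label` (truth), `probability`,
#'   `predicted`.
#' @export
predict_corpus <- function(corpus, views = NULL, model, threshold = 0.5) {
  view_of <- if (is.null(views)) NULL else split(views, views$user_id)
  out <- purrr::map2(corpus$posts, corpus$user_id, function(p, uid) {
    v <- if (is.null(view_of)) NULL else view_of[[uid]]
    pr <- predict_user(p, v, model, threshold)
    tibble::tibble(user_id = uid, probability = pr$probability,
                   predicted = pr$label)
  })
  dplyr::bind_rows(out) |>
    dplyr::left_join(dplyr::select(corpus, "user_id", "label"),
                     by = "user_id") |>
    dplyr::select("user_id", "label", "probability", "predicted")
}

#' Save / load model checkpoints
#'
#' A checkpoint is a plain-text JSON archive of the configuration, vocabulary
#' and named parameter matrices; reload is bit-exact.
#'
#' @param model A `deprscreen_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    encoder = model$encoder,
    config = unclass(model$config),
    config_class = class(model$config),
    vocab_words = names(model$vocab),
    unk_id = model$unk_id,
    # doubles stored as %.17g strings: decimal round-trip is bit-exact
    params = purrr::map(model$params,
                        ~ list(dim = dim(.x),
                               data = sprintf("%.17g", as.numeric(.x))))
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"),
                            simplifyVector = TRUE)
  config <- structure(as.list(obj$config), class = obj$config_class)
  params <- purrr::map(obj$params,
                       ~ matrix(as.numeric(.x$data), .x$dim[1], .x$dim[2]))
  cls <- if (identical(obj$encoder, "htn")) "htn_model" else "baseline_model"
  structure(
    list(config = config, params = params,
         vocab = stats::setNames(seq_along(obj$vocab_words), obj$vocab_words),
         unk_id = obj$unk_id, encoder = obj$encoder),
    class = c(cls, "deprscreen_model")
  )
}
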