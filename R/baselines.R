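#' Baseline encoder configuration
#'
#' Flat "concatenated long text" encoders (CNN, LSTM, GRU, BiLSTM, BiGRU,
#' each optionally with additive attention pooling) and the hierarchical
#' convolutional network (HCN, the convolutional mirror of the hierarchical
#' transformer). Defaults follow the canonical setting: kernel sizes
#' \{2, 3, 4\} with 100 filters each, hidden and attention size 256.
#'
#' @param encoder One of `"cnn"`, `"lstm"`, `"gru"`, `"bilstm"`, `"bigru"`,
#'   `"hcn"`.
#' @param attention Use additive attention pooling over recurrent states
#'   instead of the final hidden state (recurrent encoders only).
#' @param cnn_kernel_sizes Integer vector of convolution kernel sizes.
#' @param cnn_filters Filters per kernel size.
#' @param hidden Recurrent hidden size.
#' @param attn_size Additive-attention projection size.
#' @param d_embed Width of the (projected) word embeddings fed to the encoder.
#' @param max_concat_tokens Truncation length of the concatenated document.
#' @param max_posts_per_user Cap on posts entering the concatenation / the
#'   HCN hierarchy (most recent kept).
#' @return A `baseline_config` object.
#' @export
baseline_config <- function(encoder = c("cnn", "lstm", "gru", "bilstm",
                                        "bigru", "hcn"),
                            attention = FALSE, cnn_kernel_sizes = c(2L, 3L, 4L),
                            cnn_filters = 100L, hidden = 256L,
                            attn_size = 256L, d_embed = NULL,
                            max_concat_tokens = 2048L,
                            max_posts_per_user = 128L) {
  encoder <- match.arg(encoder)
  assert_that(all(cnn_kernel_sizes >= 1), "kernel sizes must be >= 1")
  assert_that(hidden > 0, "hidden must be positive")
  structure(list(encoder = encoder, attention = attention,
                 cnn_kernel_sizes = as.integer(cnn_kernel_sizes),
                 cnn_filters = as.integer(cnn_filters),
                 hidden = as.integer(hidden), attn_size = as.integer(attn_size),
                 d_embed = if (is.null(d_embed)) NULL else as.integer(d_embed),
                 max_concat_tokens = as.integer(max_concat_tokens),
                 max_posts_per_user = as.integer(max_posts_per_user)),
            class = "baseline_config")
}

#' Initialise a baseline encoder model
#'
#' All baselines share the trainable embedding, the sigmoid classifier head
#' and the training loop with the hierarchical transformer; the encoder is
#' the only degree of freedom.
#'
#' @param config A [baseline_config()].
#' @param embeddings An `embedding_table` for initialisation.
#' @param seed Integer seed.
#' @return A `baseline_model` object.
#' @export
baseline_model <- function(config, embeddings, seed = 1L) {
  stopifnot(inherits(config, "baseline_config"),
            inherits(embeddings, "embedding_table"))
  d <- config$d_embed %||% embeddings$dimension
  emb0 <- rbind(embeddings$vectors, embedding_lookup(embeddings, "<unk>"))
  cnn_width <- length(config$cnn_kernel_sizes) * config$cnn_filters
  with_seed(seed, {
    params <- list()
    params$emb <- unname(emb0)
    if (ncol(emb0) != d) params$emb_proj <- glorot(ncol(emb0), d)
    out_width <- switch(config$encoder,
      cnn = {
        params <- init_cnn(params, "cnn", d, config$cnn_kernel_sizes,
                           config$cnn_filters)
        cnn_width
      },
      hcn = {
        params <- init_cnn(params, "hcnw", d, config$cnn_kernel_sizes,
                           config$cnn_filters)
        params <- init_cnn(params, "hcnp", cnn_width, config$cnn_kernel_sizes,
                           config$cnn_filters)
        cnn_width
      },
      lstm = { params <- init_lstm(params, "rnnf", d, config$hidden)
               config$hidden },
      gru = { params <- init_gru(params, "rnnf", d, config$hidden)
              config$hidden },
      bilstm = {
        params <- init_lstm(params, "rnnf", d, config$hidden)
        params <- init_lstm(params, "rnnb", d, config$hidden)
        2L * config$hidden
      },
      bigru = {
        params <- init_gru(params, "rnnf", d, config$hidden)
        params <- init_gru(params, "rnnb", d, config$hidden)
        2L * config$hidden
      }
    )
    if (config$attention && !config$encoder %in% c("cnn", "hcn")) {
      params <- init_attn_pool(params, "attn", out_width, config$attn_size)
    }
    params$clf_w <- glorot(out_width, 1)
    params$clf_b <- zeros(1, 1)
    structure(
      list(config = config, params = params,
           vocab = stats::setNames(seq_along(embeddings$words),
                                   embeddings$words),
           unk_id = length(embeddings$words) + 1L, encoder = config$encoder,
           out_width = out_width),
      class = c("baseline_model", "deprscreen_model")
    )
  })
}

#' Concatenate a user's selected posts into one token sequence
#'
#' Tokens of the selected posts in chronological order, truncated to
#' `max_concat_tokens`.
#'
#' @param posts The user's chronological posts tibble (tokens set).
#' @param view One-row sampled-view tibble or `NULL` for all posts.
#' @param max_concat_tokens Truncation length.
#' @return Character vector of tokens.
#' @export
concat_user_text <- function(posts, view = NULL, max_concat_tokens = 2048L) {
  sel <- if (is.null(view)) seq_len(nrow(posts)) else view$selected[[1]]
  assert_that(length(sel) >= 1, "view selects no posts")
  toks <- unlist(posts$tokens[sel], use.names = FALSE)
  utils::head(toks, max_concat_tokens)
}

# document vector node for a flat encoder over one token sequence
encode_flat_node <- function(tp, model, tokens) {
  assert_that(length(tokens) >= 1, "cannot encode an empty token sequence")
  cfg <- model$config
  ids <- tokens_to_ids(model, tokens)
  E <- embed_ids(tp, model, ids)
  enc <- cfg$encoder
  if (enc == "cnn") {
    return(conv_encode(tp, model$params, E, "cnn", cfg$cnn_kernel_sizes,
                       cfg$cnn_filters))
  }
  run <- function(prefix, reverse) {
    if (enc %in% c("lstm", "bilstm")) {
      lstm_encode(tp, model$params, E, prefix, cfg$hidden, reverse)
    } else {
      gru_encode(tp, model$params, E, prefix, cfg$hidden, reverse)
    }
  }
  H <- run("rnnf", FALSE)
  if (enc %in% c("bilstm", "bigru")) {
    H <- tp_cbind(tp, c(H, run("rnnb", TRUE)))
  }
  n <- nrow(tp_value(tp, H))
  if (cfg$attention) {
    attn_pool(tp, model$params, H, "attn")$pooled
  } else if (enc %in% c("bilstm", "bigru")) {
    # final state of each direction: last row forward, first row backward
    hf <- tp_cols(tp, tp_rows(tp, H, n), 1:cfg$hidden)
    hb <- tp_cols(tp, tp_rows(tp, H, 1L), (cfg$hidden + 1L):(2L * cfg$hidden))
    tp_cbind(tp, c(hf, hb))
  } else {
    tp_rows(tp, H, n)
  }
}

#' Encode a token sequence with a flat baseline encoder
#'
#' CNN: per-kernel-size 1-D convolutions with ReLU and max-over-time pooling,
#' concatenated (width 300 at the defaults). Recurrent encoders: final hidden
#' state, or additive-attention-pooled states when `attention = TRUE`;
#' bidirectional variants concatenate the two directions. Sequences shorter
#' than the largest kernel are zero-padded.
#'
#' @param tokens Character vector of tokens (non-empty).
#' @param model A [baseline_model()].
#' @return Numeric document vector.
#' @export
encode_flat <- function(tokens, model) {
  tp <- tape_new()
  as.numeric(tp_value(tp, encode_flat_node(tp, model, tokens)))
}

# HCN: shared CNN post-encoder per post, then CNN + max-pool over the
# chronological post-vector sequence
encode_hcn_node <- function(tp, model, token_list) {
  cfg <- model$config
  if (length(token_list) > cfg$max_posts_per_user) {
    token_list <- utils::tail(token_list, cfg$max_posts_per_user)
  }
  post_vecs <- integer(length(token_list))
  for (i in seq_along(token_list)) {
    ids <- tokens_to_ids(model, utils::head(token_list[[i]],
                                            cfg$max_concat_tokens))
    E <- embed_ids(tp, model, ids)
    post_vecs[i] <- conv_encode(tp, model$params, E, "hcnw",
                                cfg$cnn_kernel_sizes, cfg$cnn_filters)
  }
  Pmat <- if (length(post_vecs) == 1) post_vecs[1] else tp_rbind(tp, post_vecs)
  conv_encode(tp, model$params, Pmat, "hcnp", cfg$cnn_kernel_sizes,
              cfg$cnn_filters)
}

#' Encode a user with the hierarchical convolutional network
#'
#' @param posts The user's chronological posts tibble (tokens set).
#' @param view One-row sampled-view tibble or `NULL`.
#' @param model A [baseline_model()] with `encoder = "hcn"`.
#' @return Numeric user vector.
#' @export
encode_hcn <- function(posts, view = NULL, model) {
  sel <- if (is.null(view)) seq_len(nrow(posts)) else view$selected[[1]]
  assert_that(length(sel) >= 1, "view selects no posts")
  tp <- tape_new()
  as.numeric(tp_value(tp, encode_hcn_node(tp, model, posts$tokens[sel])))
}

#' @export
forward_user.baseline_model <- function(model, tp, token_list, train = FALSE) {
  doc <- if (model$config$encoder == "hcn") {
    encode_hcn_node(tp, model, token_list)
  } else {
    toks <- utils::head(unlist(token_list, use.names = FALSE),
                        model$config$max_concat_tokens)
    encode_flat_node(tp, model, toks)
  }
  htn_logit(tp, model, doc)
}
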