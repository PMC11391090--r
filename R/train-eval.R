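#' Training configuration
#'
#' @param learning_rate Learning rate (canonical value 1e-3).
#' @param batch_size Users per gradient step, from \{32, 64, 128\}.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stop epochs without validation macro-F1 improvement.
#' @param seed Integer seed driving initial shuffling, dropout and batching.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 10L, patience = 3L, seed = 1L,
                         optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(patience >= 1, "patience must be >= 1")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 optimizer = optimizer),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Assigns exactly `per_class_counts` users of each class to each split,
#' deterministically given `seed`; splits are disjoint.
#'
#' @param corpus A corpus tibble.
#' @param per_class_counts Integer vector `c(train, validation, test)` of
#'   users per class per split.
#' @param seed Integer seed.
#' @return The corpus with its `split` column filled; users beyond the
#'   requested per-class counts are dropped so the assignment covers every
#'   returned user exactly once.
#' @export
split_corpus <- function(corpus, per_class_counts, seed = 1L) {
  stopifnot(length(per_class_counts) == 3)
  need <- sum(per_class_counts)
  corpus$split <- NA_character_
  for (cl in c("depressed", "control")) {
    idx <- which(corpus$label == cl)
    if (length(idx) < need) {
      stop(sprintf(
        "class '%s' has %d users but %d are required for the requested split",
        cl, length(idx), need), call. = FALSE)
    }
    perm <- with_seed(seed + fnv1a32(cl), sample(idx))
    corpus$split[perm[seq_len(per_class_counts[1])]] <- "train"
    corpus$split[perm[per_class_counts[1] + seq_len(per_class_counts[2])]] <-
      "validation"
    corpus$split[perm[per_class_counts[1] + per_class_counts[2] +
                        seq_len(per_class_counts[3])]] <- "test"
  }
  if (anyNA(corpus$split)) {
    corpus[!is.na(corpus$split), , drop = FALSE]
  } else {
    corpus
  }
}

# token lists of the posts a view selects, per user id
view_token_lists <- function(corpus, views) {
  view_of <- if (is.null(views)) NULL else split(views, views$user_id)
  stats::setNames(purrr::map2(corpus$posts, corpus$user_id, function(p, uid) {
    sel <- if (is.null(view_of)) seq_len(nrow(p)) else
      view_of[[uid]]$selected[[1]]
    p$tokens[sel]
  }), corpus$user_id)
}

#' Train a model with binary cross-entropy
#'
#' Minimises binary cross-entropy on the training split (users are the batch
#' unit, shuffled each epoch with the run seed), evaluates the validation
#' split after every epoch and keeps the parameters of the epoch with the
#' best validation macro-F1 (early stopping after `config$patience` epochs
#' without improvement). With `max_epochs = 0` the returned parameters equal
#' the initial ones. Deterministic given the seed.
#'
#' @param model An initialised `deprscreen_model`.
#' @param corpus A corpus tibble with `split` assigned.
#' @param views A sampled-view tibble or `NULL` (all posts).
#' @param config A [train_config()].
#' @param quiet Suppress the per-epoch progress line.
#' @return The model with trained parameters and a `log` tibble
#'   (`epoch`, `train_loss`, `val_accuracy`, `val_macro_f1`).
#' @export
train_model <- function(model, corpus, views = NULL,
                        config = train_config(), quiet = TRUE) {
  assert_that(!all(is.na(corpus$split)), "corpus must carry a split assignment")
  train_set <- corpus[corpus$split == "train", , drop = FALSE]
  val_set <- corpus[corpus$split == "validation", , drop = FALSE]
  toks <- view_token_lists(train_set, views)
  assert_that(all(lengths(toks) > 0), "every training user needs a non-empty view")
  y <- as.numeric(train_set$label == "depressed")
  n <- nrow(train_set)

  params <- model$params
  state <- adam_new(params)
  best <- list(params = params, f1 = -Inf, epoch = 0L)
  log <- list()
  stall <- 0L
  if (model$config$dropout %||% 0 > 0) set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(config$seed * 1000 + epoch, sample.int(n))
    epoch_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n)]
      gsum <- NULL
      for (u in batch) {
        tp <- tape_new()
        model$params <- params
        z <- forward_user(model, tp, toks[[u]], train = TRUE)
        loss_id <- tp_bce(tp, z, y[u])
        loss <- tp_value(tp, loss_id)[1, 1]
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss for user %s (epoch %d)",
                       train_set$user_id[u], epoch), call. = FALSE)
        }
        epoch_loss <- epoch_loss + loss
        g <- tp_backward(tp, loss_id)
        gsum <- if (is.null(gsum)) g else {
          for (nm in names(g)) gsum[[nm]] <- (gsum[[nm]] %||% 0) + g[[nm]]
          gsum
        }
      }
      gmean <- purrr::map(gsum, ~ .x / length(batch))
      if (config$optimizer == "adam") {
        upd <- adam_step(params, gmean, state, lr = config$learning_rate)
        params <- upd$params
        state <- upd$state
      } else {
        params <- sgd_step(params, gmean, lr = config$learning_rate)
      }
    }
    model$params <- params
    val <- evaluate_model(model, corpus, views, split = "validation")
    log[[epoch]] <- tibble::tibble(epoch = epoch,
                                   train_loss = epoch_loss / n,
                                   val_accuracy = val$accuracy,
                                   val_macro_f1 = val$macro_f1)
    if (!quiet) {
      message(sprintf("epoch %d  loss %.4f  val acc %.4f  val F1 %.4f",
                      epoch, epoch_loss / n, val$accuracy, val$macro_f1))
    }
    if (val$macro_f1 > best$f1) {
      best <- list(params = params, f1 = val$macro_f1, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    if (nrow(val_set) == 0) best <- list(params = params, f1 = 0, epoch = epoch)
  }
  model$params <- best$params
  model$log <- dplyr::bind_rows(log)
  model$best_epoch <- best$epoch
  model$train_config <- config
  model
}

#' Evaluate a model on one split of a corpus
#'
#' @param model A `deprscreen_model`.
#' @param corpus A corpus tibble with `split` assigned.
#' @param views A sampled-view tibble or `NULL`.
#' @param split `"train"`, `"validation"` or `"test"`.
#' @param threshold Decision threshold.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, corpus, views = NULL, split = "test",
                           threshold = 0.5) {
  subset <- corpus[!is.na(corpus$split) & corpus$split == split, , drop = FALSE]
  assert_that(nrow(subset) > 0, paste0("split '", split, "' is empty"))
  preds <- predict_corpus(subset, views, model, threshold)
  metrics_report(preds$label, preds$predicted)
}

#' Glance at a trained model
#'
#' @param x A trained `deprscreen_model`.
#' @param ... Unused.
#' @return One-row tibble with encoder, parameter count, epochs run and best
#'   validation macro-F1.
#' @method glance deprscreen_model
#' @export
glance.deprscreen_model <- function(x, ...) {
  tibble::tibble(
    encoder = x$encoder,
    n_parameters = sum(purrr::map_int(x$params, length)),
    epochs = if (is.null(x$log)) 0L else nrow(x$log),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_macro_f1 = if (is.null(x$log) || nrow(x$log) == 0) NA_real_
                        else max(x$log$val_macro_f1)
  )
}

#' Run the strategy x rate x encoder x seed grid
#'
#' Re-initialises and trains one model per grid cell and evaluates the test
#' split; strategy `"none"` ignores the rate (one cell per encoder/seed).
#' Cell failures are recorded in the `error` column and the grid continues.
#'
#' @param corpus A corpus tibble with `split` assigned and tokens set.
#' @param strategies Character vector from `none`, `random`, `retrieval`.
#' @param rates Numeric sampling rates in (0, 1].
#' @param encoders Character vector: `"htn"` or any [baseline_config()]
#'   encoder name (suffix `"+attn"` adds attention pooling, e.g.
#'   `"gru+attn"`).
#' @param seeds Integer vector of run seeds.
#' @param embeddings An `embedding_table` for model initialisation.
#' @param lexicon A lexicon for the retrieval strategy.
#' @param train_cfg A [train_config()] (its seed is overridden per run).
#' @param model_args Named list of overrides passed to [htn_config()] /
#'   [baseline_config()].
#' @return A tibble with one row per grid cell: strategy, rate, encoder,
#'   seed, accuracy, macro_p, macro_r, macro_f1, error.
#' @export
run_grid <- function(corpus, strategies, rates, encoders, seeds,
                     embeddings, lexicon = NULL,
                     train_cfg = train_config(), model_args = list()) {
  cells <- list()
  for (strategy in strategies) {
    cell_rates <- if (strategy == "none") NA_real_ else rates
    for (rate in cell_rates) {
      for (encoder in encoders) {
        for (seed in seeds) {
          cells[[length(cells) + 1L]] <-
            list(strategy = strategy, rate = rate, encoder = encoder,
                 seed = seed)
        }
      }
    }
  }
  rows <- purrr::map(cells, function(cell) {
    out <- tibble::tibble(strategy = cell$strategy, rate = cell$rate,
                          encoder = cell$encoder, seed = cell$seed,
                          accuracy = NA_real_, macro_p = NA_real_,
                          macro_r = NA_real_, macro_f1 = NA_real_,
                          error = NA_character_)
    tryCatch({
      views <- sample_corpus(
        corpus,
        strategy = cell$strategy,
        rate = if (is.na(cell$rate)) 1 else cell$rate,
        lexicon = lexicon, seed = cell$seed)
      model <- make_encoder(cell$encoder, embeddings, seed = cell$seed,
                            model_args = model_args)
      cfg <- train_cfg
      cfg$seed <- as.integer(cell$seed)
      fitted <- train_model(model, corpus, views, cfg)
      rep <- evaluate_model(fitted, corpus, views, split = "test")
      out$accuracy <- rep$accuracy
      out$macro_p <- rep$macro_precision
      out$macro_r <- rep$macro_recall
      out$macro_f1 <- rep$macro_f1
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  dplyr::bind_rows(rows)
}

#' Construct an encoder model by name
#'
#' @param encoder `"htn"` or a baseline encoder name, with optional
#'   `"+attn"` suffix.
#' @param embeddings An `embedding_table`.
#' @param seed Integer seed.
#' @param model_args Named overrides for the config constructor.
#' @return A `deprscreen_model`.
#' @export
make_encoder <- function(encoder, embeddings, seed = 1L, model_args = list()) {
  if (encoder == "htn") {
    cfg <- do.call(htn_config, model_args)
    htn_model(cfg, embeddings, seed = seed)
  } else {
    attention <- grepl("\\+attn$", encoder)
    base <- sub("\\+attn$", "", encoder)
    args <- c(list(encoder = base, attention = attention), model_args)
    cfg <- do.call(baseline_config, args)
    baseline_model(cfg, embeddings, seed = seed)
  }
}

#' Aggregate grid results over seeds
#'
#' @param grid The tibble returned by [run_grid()].
#' @return A tibble with mean and sd of each metric per
#'   (strategy, rate, encoder).
#' @export
summarize_grid <- function(grid) {
  grid |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$strategy, .data$rate, .data$encoder) |>
    dplyr::summarize(
      n_seeds = dplyr::n(),
      dplyr::across(c("accuracy", "macro_p", "macro_r", "macro_f1"),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    )
}

#' Plot macro-F1 against sampling rate by strategy
#'
#' @param grid The tibble returned by [run_grid()].
#' @return A ggplot object.
#' @export
plot_rate_sweep <- function(grid) {
  summ <- summarize_grid(grid) |>
    dplyr::mutate(rate = ifelse(is.na(.data$rate), 1, .data$rate))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$rate, y = .data$macro_f1_mean,
                                     colour = .data$strategy,
                                     group = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~encoder) +
    ggplot2::labs(x = "sampling rate", y = "macro-F1 (mean over seeds)",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}
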