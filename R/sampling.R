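#' Lexicon match score of a post
#'
#' Counts token occurrences that are lexicon terms (multiset count, exact
#' token match after lowercasing/NFC).
#'
#' @param tokens Character vector of segmented tokens.
#' @param lexicon A [new_lexicon()] object.
#' @return Non-negative integer score.
#' @export
score_post <- function(tokens, lexicon) {
  assert_that(inherits(lexicon, "lexicon") && length(lexicon$terms) > 0,
              "lexicon must be a non-empty lexicon object")
  sum(tolower(nfc(as.character(tokens))) %in% lexicon$terms)
}

new_sampled_view <- function(user_id, strategy, rate, selected, n_posts) {
  selected <- as.integer(selected)
  assert_that(all(diff(selected) > 0), "selected indices must be increasing")
  assert_that(length(selected) == sample_size(rate, n_posts),
              "|selected| must equal ceil(rate * N)")
  tibble::tibble(user_id = user_id, strategy = strategy, rate = rate,
                 selected = list(selected))
}

#' Retrieval-based post sampling for one user
#'
#' Ranks the user's chronological posts by depression-lexicon match score
#' (descending), breaking ties by recency (later post first, then later
#' chronological position first), takes the top `ceiling(rate * N)`, and
#' returns their indices in chronological order. Nested: the selection at a
#' higher rate contains the selection at any lower rate.
#'
#' @param posts One user's chronological posts tibble (tokens set).
#' @param lexicon A [new_lexicon()] object.
#' @param rate Sampling rate in (0, 1].
#' @param user_id User identifier recorded in the view.
#' @return A one-row sampled-view tibble (`user_id`, `strategy`, `rate`,
#'   `selected` list-column of increasing post indices).
#' @export
retrieval_sample <- function(posts, lexicon, rate, user_id = "user") {
  n <- nrow(posts)
  assert_that(n >= 1, "user must have at least one post")
  assert_that(rate > 0 && rate <= 1, "rate must be in (0, 1]")
  scores <- purrr::map_int(posts$tokens, ~ as.integer(score_post(.x, lexicon)))
  # total order: score desc, then recency (timestamp desc, position desc)
  ord <- order(-scores, -as.numeric(posts$ts), -seq_len(n))
  k <- sample_size(rate, n)
  new_sampled_view(user_id, "retrieval", rate, sort(ord[seq_len(k)]), n)
}

#' Uniform random post sampling for one user
#'
#' Samples `ceiling(rate * N)` posts without replacement, uniformly at
#' random, deterministically given `(seed, user_id)`: the draw uses a private
#' RNG stream seeded with `seed` combined with a stable hash of `user_id`, so
#' adding or removing other users never perturbs this user's sample.
#'
#' @param posts One user's chronological posts tibble.
#' @param rate Sampling rate in (0, 1].
#' @param seed Integer seed.
#' @param user_id User identifier (also drives the per-user RNG stream).
#' @return A one-row sampled-view tibble; indices in chronological order.
#' @export
random_sample <- function(posts, rate, seed, user_id = "user") {
  n <- nrow(posts)
  assert_that(n >= 1, "user must have at least one post")
  assert_that(rate > 0 && rate <= 1, "rate must be in (0, 1]")
  k <- sample_size(rate, n)
  idx <- with_seed((as.numeric(seed) + fnv1a32(user_id)) %% 2147483647,
                   sample.int(n, k))
  new_sampled_view(user_id, "random", rate, sort(idx), n)
}

#' Build sampled views for every user of a corpus
#'
#' Applies one of the three post-selection strategies per user. `"none"`
#' selects every post (and ignores `rate`); `"retrieval"` needs a lexicon;
#' `"random"` needs a seed. Sampling is always per user, never pooled across
#' users.
#'
#' @param corpus A corpus tibble.
#' @param strategy `"none"`, `"random"` or `"retrieval"`.
#' @param rate Sampling rate in (0, 1] (ignored for `"none"`).
#' @param lexicon A [new_lexicon()] for `"retrieval"`.
#' @param seed Integer seed for `"random"`.
#' @return A sampled-view tibble, one row per user.
#' @export
sample_corpus <- function(corpus, strategy = c("none", "random", "retrieval"),
                          rate = 1, lexicon = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  views <- purrr::map2(corpus$posts, corpus$user_id, function(p, uid) {
    switch(strategy,
      none = new_sampled_view(uid, "none", 1, seq_len(nrow(p)), nrow(p)),
      retrieval = retrieval_sample(p, lexicon, rate, user_id = uid),
      random = {
        assert_that(!is.null(seed), "random strategy requires a seed")
        random_sample(p, rate, seed, user_id = uid)
      }
    )
  })
  dplyr::bind_rows(views)
}

#' Write / read sampled views as JSONL
#'
#' @param views A sampled-view tibble.
#' @param path File path.
#' @return `path` (write) or the views tibble (read).
#' @export
write_views <- function(views, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(views))) {
    writeLines(jsonlite::toJSON(
      list(user_id = views$user_id[i], strategy = views$strategy[i],
           rate = views$rate[i], selected = views$selected[[i]]),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_views
#' @export
read_views <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  dplyr::bind_rows(purrr::map(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    tibble::tibble(user_id = obj$user_id, strategy = obj$strategy,
                   rate = obj$rate, selected = list(as.integer(obj$selected)))
  }))
}
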