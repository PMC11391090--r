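#' Synthetic corpus generator configuration
#'
#' Generates two balanced user cohorts whose timelines carry the statistical
#' contrasts the detection method assumes: depressed users write fewer and
#' shorter posts, a much larger fraction of their posts are "signal" posts
#' drawing tokens from a depression lexicon, and they use the first-person
#' singular more (the controls use the plural more). Post and token counts
#' are negative binomial (overdispersed); timestamps are uniform over a
#' one-year window. Class-valued arguments are length-2 vectors
#' `c(depressed, control)`.
#'
#' @param n_users_per_class Users per cohort.
#' @param posts_per_user Mean posts per user, per class (depressed < control).
#' @param posts_dispersion Negative-binomial size parameter for post counts.
#' @param tokens_per_post Mean tokens per post, per class (depressed <
#'   control).
#' @param tokens_dispersion Negative-binomial size for token counts.
#' @param signal_lexicon_size,background_vocab_size Vocabulary sizes.
#' @param p_signal_post Probability a post is a signal post, per class
#'   (depressed must exceed control unless both are equal for a null model).
#' @param p_signal_token_in_signal_post Fraction of a signal post's tokens
#'   drawn from the signal lexicon.
#' @param pronoun_sing,pronoun_plur Per-token emission rates of the
#'   first-person singular (我) and plural (我们), per class.
#' @param period_rate,comma_rate,exclaim_rate Probability that a post's raw
#'   text ends with 。 / ，-separated clause / ！, per class; these exist so
#'   the punctuation profile of the two cohorts differs in a controlled way.
#' @param seed Integer seed.
#' @return A `gen_config` object.
#' @export
gen_config <- function(n_users_per_class = 200L,
                       posts_per_user = c(depressed = 25, control = 35),
                       posts_dispersion = 8,
                       tokens_per_post = c(depressed = 8, control = 12),
                       tokens_dispersion = 10,
                       signal_lexicon_size = 15L,
                       background_vocab_size = 400L,
                       p_signal_post = c(depressed = 0.5, control = 0.05),
                       p_signal_token_in_signal_post = 0.35,
                       pronoun_sing = c(depressed = 0.06, control = 0.02),
                       pronoun_plur = c(depressed = 0.005, control = 0.02),
                       period_rate = c(depressed = 0.5, control = 0.2),
                       comma_rate = c(depressed = 0.2, control = 0.5),
                       exclaim_rate = c(depressed = 0.05, control = 0.2),
                       seed = 42L) {
  probs <- c(p_signal_post, p_signal_token_in_signal_post, pronoun_sing,
             pronoun_plur, period_rate, comma_rate, exclaim_rate)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0, 1]")
  assert_that(p_signal_post[1] >= p_signal_post[2],
              "depressed p_signal_post must be >= control")
  assert_that(all(posts_per_user > 0) && all(tokens_per_post > 0),
              "class means must be positive")
  structure(list(
    n_users_per_class = as.integer(n_users_per_class),
    posts_per_user = posts_per_user, posts_dispersion = posts_dispersion,
    tokens_per_post = tokens_per_post, tokens_dispersion = tokens_dispersion,
    signal_lexicon_size = as.integer(signal_lexicon_size),
    background_vocab_size = as.integer(background_vocab_size),
    p_signal_post = p_signal_post,
    p_signal_token_in_signal_post = p_signal_token_in_signal_post,
    pronoun_sing = pronoun_sing, pronoun_plur = pronoun_plur,
    period_rate = period_rate, comma_rate = comma_rate,
    exclaim_rate = exclaim_rate, seed = as.integer(seed)
  ), class = "gen_config")
}

#' Preset generator configurations
#'
#' `strong`: clearly separable cohorts (signal-post prevalence 0.50 vs 0.05).
#' `weak`: reduced prevalence gap (0.15 vs 0.05).
#' `null`: identical cohorts (both 0.05, equal behavioural marginals) — a
#' negative control on which every classifier should sit at chance.
#'
#' @param preset One of `"strong"`, `"weak"`, `"null"`.
#' @param n_users_per_class Users per cohort.
#' @param seed Integer seed.
#' @return A [gen_config()].
#' @export
gen_preset <- function(preset = c("strong", "weak", "null"),
                       n_users_per_class = 200L, seed = 42L) {
  preset <- match.arg(preset)
  switch(preset,
    strong = gen_config(n_users_per_class = n_users_per_class, seed = seed),
    weak = gen_config(n_users_per_class = n_users_per_class, seed = seed,
                      p_signal_post = c(depressed = 0.15, control = 0.05)),
    null = gen_config(
      n_users_per_class = n_users_per_class, seed = seed,
      posts_per_user = c(depressed = 30, control = 30),
      tokens_per_post = c(depressed = 10, control = 10),
      p_signal_post = c(depressed = 0.05, control = 0.05),
      pronoun_sing = c(depressed = 0.04, control = 0.04),
      pronoun_plur = c(depressed = 0.01, control = 0.01),
      period_rate = c(depressed = 0.3, control = 0.3),
      comma_rate = c(depressed = 0.3, control = 0.3),
      exclaim_rate = c(depressed = 0.1, control = 0.1))
  )
}

#' Generate the signal lexicon and background vocabulary
#'
#' Synthetic "words" are abstract symbols (`sig001...`, `w0001...`), so the
#' two sets are disjoint by construction and the pipeline stays
#' script-agnostic; deterministic given the config seed.
#'
#' @param config A [gen_config()].
#' @return A list with `lexicon` (a [new_lexicon()]) and `background`
#'   (character vector).
#' @export
make_lexicon <- function(config) {
  assert_that(config$signal_lexicon_size >= 1 &&
                config$background_vocab_size >= 1, "sizes must be >= 1")
  # letter-only symbols survive the digit-stripping preprocessing pass
  signal <- paste0("sig", letter_suffixes(config$signal_lexicon_size))
  background <- paste0("w", letter_suffixes(config$background_vocab_size))
  list(lexicon = new_lexicon(signal), background = background)
}

# "aa", "ab", ... base-26 suffixes, width chosen to fit n
letter_suffixes <- function(n) {
  width <- max(2L, ceiling(log(n + 1) / log(26)))
  out <- character(n)
  for (i in seq_len(n)) {
    x <- i - 1L
    chars <- character(width)
    for (k in width:1) {
      chars[k] <- letters[x %% 26L + 1L]
      x <- x %/% 26L
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

draw_count <- function(n, mean, size) {
  pmax(1L, stats::rnbinom(n, size = size, mu = mean))
}

#' Generate a labeled synthetic corpus
#'
#' Per user: the post count is drawn from the class's negative-binomial
#' distribution; each post is a signal post with the class's probability, in
#' which case the configured fraction of its tokens comes from the signal
#' lexicon; first-person pronouns are emitted at class-specific per-token
#' rates; the remaining tokens are uniform over the background vocabulary.
#' Raw text is the space-joined token sequence plus class-dependent
#' punctuation; `tokens` are set directly, so the corpus is ready for
#' sampling and training (or can be round-tripped through the preprocessing
#' pipeline). Timestamps are uniform over 2023, sorted per user.
#'
#' @param config A [gen_config()].
#' @return A corpus tibble.
#' @export
generate_corpus <- function(config) {
  voc <- make_lexicon(config)
  signal_terms <- voc$lexicon$terms
  background <- voc$background
  classes <- c("depressed", "control")
  t0 <- as.POSIXct("2023-01-01T00:00:00", format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC")
  year_s <- 365 * 24 * 3600
  with_seed(config$seed, {
    users <- list()
    for (ci in 1:2) {
      cl <- classes[ci]
      for (u in seq_len(config$n_users_per_class)) {
        uid <- sprintf("%s%04d", if (ci == 1) "d" else "c", u)
        n_posts <- draw_count(1, config$posts_per_user[ci],
                              config$posts_dispersion)
        ts <- sort(t0 + stats::runif(n_posts, 0, year_s))
        is_signal <- stats::runif(n_posts) < config$p_signal_post[ci]
        n_tok <- draw_count(n_posts, config$tokens_per_post[ci],
                            config$tokens_dispersion)
        toks <- vector("list", n_posts)
        text <- character(n_posts)
        for (p in seq_len(n_posts)) {
          r <- stats::runif(n_tok[p])
          rs <- config$pronoun_sing[ci]
          rp <- config$pronoun_plur[ci]
          tk <- character(n_tok[p])
          pron_s <- r < rs
          pron_p <- !pron_s & r < rs + rp
          rest <- !(pron_s | pron_p)
          tk[pron_s] <- "我"        # 我
          tk[pron_p] <- "我们"  # 我们
          n_rest <- sum(rest)
          if (n_rest > 0) {
            if (is_signal[p]) {
              from_sig <- stats::runif(n_rest) <
                config$p_signal_token_in_signal_post
              draw <- character(n_rest)
              draw[from_sig] <- sample(signal_terms, sum(from_sig),
                                       replace = TRUE)
              draw[!from_sig] <- sample(background, sum(!from_sig),
                                        replace = TRUE)
              tk[rest] <- draw
            } else {
              tk[rest] <- sample(background, n_rest, replace = TRUE)
            }
          }
          toks[[p]] <- tk
          rtext <- paste(tk, collapse = " ")
          rr <- stats::runif(1)
          tail_mark <- if (rr < config$period_rate[ci]) "。"
            else if (rr < config$period_rate[ci] + config$comma_rate[ci]) "，"
            else if (rr < config$period_rate[ci] + config$comma_rate[ci] +
                       config$exclaim_rate[ci]) "！"
            else ""
          text[p] <- paste0(rtext, tail_mark)
        }
        posts <- tibble::tibble(
          post_id = sprintf("%s_p%04d", uid, seq_len(n_posts)),
          ts = ts, text = text, tokens = toks)
        users[[length(users) + 1L]] <-
          list(user_id = uid, label = cl, posts = posts)
      }
    }
    new_corpus(users)
  })
}

#' Generate a synthetic embedding table
#'
#' Unit-norm random vectors for every word. With `cluster_signal`, the given
#' signal words are placed in a common half-space (shared mean direction), so
#' linear separability of signal vs background tokens is controllable.
#'
#' @param vocabulary Character vector of words.
#' @param dimension Embedding width (>= 2).
#' @param seed Integer seed.
#' @param cluster_signal Optional character vector of signal words to
#'   cluster.
#' @return An `embedding_table`.
#' @export
generate_embeddings <- function(vocabulary, dimension, seed = 1L,
                                cluster_signal = NULL) {
  assert_that(dimension >= 2, "dimension must be >= 2")
  with_seed(seed, {
    mat <- matrix(stats::rnorm(length(vocabulary) * dimension),
                  length(vocabulary), dimension)
    if (!is.null(cluster_signal)) {
      mu <- stats::rnorm(dimension)
      mu <- mu / sqrt(sum(mu^2))
      hit <- vocabulary %in% cluster_signal
      mat[hit, ] <- 0.45 * mat[hit, , drop = FALSE] +
        matrix(mu, sum(hit), dimension, byrow = TRUE)
    }
    mat <- mat / sqrt(rowSums(mat^2))
    new_embedding_table(vocabulary, mat)
  })
}

#' Full synthetic study inputs for a preset
#'
#' Convenience wrapper: generates the corpus, lexicon and a clustered
#' embedding table (vocabulary = signal + background + pronouns) in one call.
#'
#' @param preset Passed to [gen_preset()].
#' @param n_users_per_class Users per cohort.
#' @param dimension Embedding width.
#' @param seed Integer seed.
#' @return A list with `corpus`, `lexicon`, `embeddings`, `config`.
#' @export
simulate_study <- function(preset = "strong", n_users_per_class = 200L,
                           dimension = 32L, seed = 42L) {
  config <- gen_preset(preset, n_users_per_class, seed = seed)
  voc <- make_lexicon(config)
  corpus <- generate_corpus(config)
  vocabulary <- c(voc$lexicon$terms, voc$background,
                  "我", "我们")
  embeddings <- generate_embeddings(vocabulary, dimension, seed = seed + 1L,
                                    cluster_signal = voc$lexicon$terms)
  list(corpus = corpus, lexicon = voc$lexicon, embeddings = embeddings,
       config = config)
}
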