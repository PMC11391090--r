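#' Preprocessing configuration
#'
#' Controls the cleaning pipeline for microblog posts: bracketed-emoticon
#' replacement, URL/number/punctuation stripping, bot-post filtering,
#' exact-duplicate removal and the short-post exclusion threshold.
#'
#' @param emoticon_map Named character vector mapping a bracketed emoticon
#'   string (e.g. `"[泪]"`) to an emotion word (e.g. `"流泪"`). Defaults to the
#'   small editable seed list shipped in `extdata/emoticons.tsv`.
#' @param bot_patterns Character vector of regular expressions (literal
#'   substrings are valid patterns) marking platform-generated posts such as
#'   birthday reminders. Defaults to `extdata/bot_patterns.txt`.
#' @param min_tokens Posts with fewer than this many tokens after segmentation
#'   are excluded (default 3).
#' @param strip_urls,strip_numbers,strip_punct Logical toggles for the three
#'   noise-stripping passes (all default `TRUE`).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(emoticon_map = default_emoticon_map(),
                              bot_patterns = default_bot_patterns(),
                              min_tokens = 3L,
                              strip_urls = TRUE, strip_numbers = TRUE,
                              strip_punct = TRUE) {
  assert_that(min_tokens >= 1, "min_tokens must be >= 1")
  assert_that(!anyDuplicated(names(emoticon_map)),
              "emoticon_map keys must be unique")
  structure(
    list(emoticon_map = emoticon_map, bot_patterns = bot_patterns,
         min_tokens = as.integer(min_tokens), strip_urls = strip_urls,
         strip_numbers = strip_numbers, strip_punct = strip_punct),
    class = "preprocess_config"
  )
}

#' @rdname preprocess_config
#' @export
default_emoticon_map <- function() {
  path <- system.file("extdata", "emoticons.tsv", package = "deprscreen")
  tab <- utils::read.delim(path, header = FALSE, quote = "",
                           fileEncoding = "UTF-8",
                           col.names = c("emoticon", "word"))
  stats::setNames(nfc(tab$word), nfc(tab$emoticon))
}

#' @rdname preprocess_config
#' @export
default_bot_patterns <- function() {
  path <- system.file("extdata", "bot_patterns.txt", package = "deprscreen")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  nfc(lines[nzchar(lines)])
}

#' Clean raw post text
#'
#' Applies, in order: emoticon substitution, URL removal, number removal,
#' punctuation removal, whitespace squeeze. The fixed order stops URL
#' fragments from surviving punctuation stripping. Total function: empty
#' input gives empty output.
#'
#' @param raw_text Character vector of raw post texts.
#' @param config A [preprocess_config()].
#' @return Character vector of cleaned texts (possibly empty strings).
#' @export
clean_text <- function(raw_text, config = preprocess_config()) {
  x <- nfc(raw_text)
  if (length(config$emoticon_map) > 0) {
    x <- stringi::stri_replace_all_fixed(
      x, names(config$emoticon_map), unname(config$emoticon_map),
      vectorize_all = FALSE)
  }
  if (config$strip_urls) {
    x <- stringr::str_replace_all(
      x, "(?i)(https?://\\S+|www\\.\\S+|t\\.cn/\\S+)", " ")
  }
  if (config$strip_numbers) {
    x <- stringr::str_replace_all(x, "[0-9０-９]+", " ")
  }
  if (config$strip_punct) {
    x <- stringr::str_replace_all(x, "[\\p{P}\\p{S}]+", " ")
  }
  stringr::str_squish(x)
}

#' Segment text into a word sequence
#'
#' The segmenter is pluggable: `tokenizer` is any
#' `function(text, vocab)` returning a character vector of tokens. The shipped
#' default, [max_match_tokenizer()], splits on whitespace, keeps Latin/digit
#' runs whole, and segments CJK runs by greedy forward maximum matching
#' against `external_vocab`, falling back to single characters. Whitespace is
#' never emitted as a token and no token is empty.
#'
#' @param text Character scalar to segment.
#' @param tokenizer A segmentation function (default [max_match_tokenizer()]).
#' @param external_vocab Optional character vector of words injected into the
#'   segmenter's lexicon before segmentation (e.g. an embedding vocabulary).
#' @return Character vector of tokens.
#' @export
segment_text <- function(text, tokenizer = max_match_tokenizer,
                         external_vocab = NULL) {
  toks <- tokenizer(text, external_vocab)
  toks <- toks[nzchar(toks) & !grepl("^\\s+$", toks)]
  as.character(toks)
}

#' Greedy forward maximum-matching segmenter
#'
#' @param text Character scalar.
#' @param vocab Optional character vector of multi-character words to match
#'   greedily (longest first) inside CJK runs.
#' @return Character vector of tokens.
#' @export
max_match_tokenizer <- function(text, vocab = NULL) {
  chunks <- strsplit(stringr::str_squish(nfc(text)), " ", fixed = TRUE)[[1]]
  if (length(chunks) == 0) return(character(0))
  vocab_set <- if (is.null(vocab)) character(0) else nfc(vocab)
  max_len <- if (length(vocab_set) > 0) max(nchar(vocab_set)) else 1L
  unlist(lapply(chunks, function(chunk) {
    chars <- strsplit(chunk, "")[[1]]
    is_cjk <- grepl("[\\p{Han}\\p{Hiragana}\\p{Katakana}\\p{Hangul}]",
                    chars, perl = TRUE)
    if (!any(is_cjk)) return(chunk)
    toks <- character(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      if (!is_cjk[i]) {
        j <- i
        while (j < n && !is_cjk[j + 1L]) j <- j + 1L
        toks <- c(toks, paste(chars[i:j], collapse = ""))
        i <- j + 1L
      } else {
        matched <- 1L
        if (length(vocab_set) > 0) {
          for (len in min(max_len, n - i + 1L):2L) {
            if (len < 2L) break
            cand <- paste(chars[i:(i + len - 1L)], collapse = "")
            if (cand %in% vocab_set) { matched <- len; break }
          }
        }
        toks <- c(toks, paste(chars[i:(i + matched - 1L)], collapse = ""))
        i <- i + matched
      }
    }
    toks
  }), use.names = FALSE)
}

#' Filter one user's cleaned, segmented posts
#'
#' Applies, in order and preserving chronology: bot-post removal (raw text
#' matched against `config$bot_patterns`), exact-duplicate removal (two posts
#' are duplicates when their cleaned token sequences are identical; the
#' earlier post is kept), and short-post exclusion (fewer than
#' `config$min_tokens` tokens). Idempotent. If nothing survives, the returned
#' tibble has zero rows and attribute `flagged_empty = TRUE`; the caller
#' decides whether to drop the user.
#'
#' @param posts One user's posts tibble (columns `post_id`, `ts`, `text`,
#'   `tokens` with tokens set).
#' @param config A [preprocess_config()].
#' @return The filtered posts tibble.
#' @export
filter_user <- function(posts, config = preprocess_config()) {
  assert_that(all(!purrr::map_lgl(posts$tokens, is.null)),
              "posts must be segmented before filter_user()")
  keep <- rep(TRUE, nrow(posts))
  if (length(config$bot_patterns) > 0) {
    bot <- Reduce(`|`, lapply(config$bot_patterns,
                              function(p) stringr::str_detect(posts$text, p)),
                  accumulate = FALSE)
    keep <- keep & !bot
  }
  # dedup runs after the bot filter: only surviving posts can shadow a later one
  key <- purrr::map_chr(posts$tokens, paste, collapse = "\u001f")
  key[!keep] <- NA_character_
  keep <- keep & !duplicated(key, incomparables = NA)
  keep <- keep & lengths(posts$tokens) >= config$min_tokens
  out <- posts[keep, , drop = FALSE]
  if (nrow(out) == 0) attr(out, "flagged_empty") <- TRUE
  out
}

#' Clean, segment and filter a whole corpus
#'
#' Runs [clean_text()], [segment_text()] and [filter_user()] over every user.
#' The raw `text` column is preserved unchanged so that the linguistics
#' functions can analyse the pre-strip text (punctuation and particles);
#' the classifier path reads only the `tokens` column.
#'
#' @param corpus A corpus tibble.
#' @param config A [preprocess_config()].
#' @param tokenizer,external_vocab Passed to [segment_text()].
#' @param drop_empty Drop users left with zero posts (default `TRUE`, with a
#'   warning naming them).
#' @return The preprocessed corpus tibble.
#' @export
preprocess_corpus <- function(corpus, config = preprocess_config(),
                              tokenizer = max_match_tokenizer,
                              external_vocab = NULL, drop_empty = TRUE) {
  corpus$posts <- purrr::map(corpus$posts, function(p) {
    cleaned <- clean_text(p$text, config)
    p$tokens <- purrr::map(cleaned, segment_text, tokenizer = tokenizer,
                           external_vocab = external_vocab)
    filter_user(p, config)
  })
  empty <- purrr::map_int(corpus$posts, nrow) == 0
  if (any(empty)) {
    warning("users left with zero posts after preprocessing: ",
            paste(corpus$user_id[empty], collapse = ", "), call. = FALSE)
    if (drop_empty) corpus <- corpus[!empty, , drop = FALSE]
  }
  corpus
}
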