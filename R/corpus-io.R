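#' Build a user-post corpus tibble
#'
#' A corpus is a tibble with one row per user and columns `user_id` (character),
#' `label` (`"depressed"` or `"control"`), `split` (`"train"`, `"validation"`,
#' `"test"` or `NA`), `posts` (a list-column of per-user post tibbles with
#' columns `post_id`, `ts` (POSIXct, UTC), `text`, and a list-column `tokens`)
#' and `meta` (a list-column preserving unknown on-disk keys). Posts are kept
#' sorted ascending by timestamp, ties broken by `post_id`.
#'
#' @param users A list of user records, each a list with `user_id`, `label`,
#'   `posts` (a tibble or data frame of posts) and optionally `split`, `meta`.
#' @return A corpus tibble.
#' @export
new_corpus <- function(users) {
  rows <- purrr::map(users, function(u) {
    tibble::tibble(
      user_id = as.character(u$user_id),
      label   = match.arg(u$label, c("depressed", "control")),
      split   = if (is.null(u$split)) NA_character_ else u$split,
      posts   = list(sort_posts(as_posts_tbl(u$posts))),
      meta    = list(u$meta %||% list())
    )
  })
  corpus <- dplyr::bind_rows(rows)
  validate_corpus(corpus)
  corpus
}

as_posts_tbl <- function(posts) {
  if (is.data.frame(posts)) {
    stopifnot(all(c("post_id", "ts", "text") %in% names(posts)))
    tb <- tibble::as_tibble(posts)
    if (!inherits(tb$ts, "POSIXct")) tb$ts <- parse_ts(as.character(tb$ts))
    if (!"tokens" %in% names(tb)) tb$tokens <- rep(list(NULL), nrow(tb))
    tb$text <- nfc(tb$text)
    tb[, c("post_id", "ts", "text", "tokens")]
  } else {
    stop("posts must be a data frame", call. = FALSE)
  }
}

sort_posts <- function(posts) {
  posts[order(posts$ts, posts$post_id), , drop = FALSE]
}

#' Validate a corpus tibble
#'
#' Checks user-id uniqueness, post ordering, label values and (when present)
#' that the split assignment covers every user exactly once.
#'
#' @param corpus A corpus tibble.
#' @return The corpus, invisibly, or an error.
#' @export
validate_corpus <- function(corpus) {
  dup <- corpus$user_id[duplicated(corpus$user_id)]
  if (length(dup) > 0) {
    stop("duplicate user_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  assert_that(all(corpus$label %in% c("depressed", "control")),
              "labels must be 'depressed' or 'control'")
  if (!all(is.na(corpus$split))) {
    assert_that(!anyNA(corpus$split),
                "split assignment, when present, must cover every user")
    assert_that(all(corpus$split %in% c("train", "validation", "test")),
                "split values must be train/validation/test")
  }
  ok <- purrr::map_lgl(corpus$posts, function(p) {
    !is.unsorted(order(p$ts, p$post_id)) &&
      identical(order(p$ts, p$post_id), seq_len(nrow(p)))
  })
  assert_that(all(ok), "posts must be sorted ascending by timestamp")
  invisible(corpus)
}

#' Read a corpus from newline-delimited JSON
#'
#' One user object per line:
#' `{"user_id": str, "label": "depressed"|"control", "posts":
#' [{"post_id": str, "ts": "YYYY-MM-DDTHH:MM:SS", "text": str}]}`.
#' A `tokens` array per post (written back by [preprocess_corpus()]) and a
#' `split` field are honoured when present; any other keys are preserved in
#' the `meta` list-column. Posts are re-sorted ascending by timestamp on read
#' (ties broken by `post_id`); all text is NFC-normalized.
#'
#' @param path Path to a JSONL corpus file.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  users <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed JSON on line %d of %s: %s", i, path,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    known <- c("user_id", "label", "posts", "split")
    meta <- obj[setdiff(names(obj), known)]
    posts <- tibble::tibble(
      post_id = purrr::map_chr(obj$posts, ~ as.character(.x$post_id)),
      ts      = parse_ts(purrr::map_chr(obj$posts, ~ .x$ts)),
      text    = nfc(purrr::map_chr(obj$posts, ~ .x$text)),
      tokens  = purrr::map(obj$posts, function(p) {
        if (is.null(p$tokens)) NULL else nfc(unlist(p$tokens, use.names = FALSE))
      })
    )
    users[[i]] <- list(user_id = obj$user_id, label = obj$label,
                       split = obj$split, posts = posts, meta = meta)
  }
  new_corpus(users)
}

#' Write a corpus to newline-delimited JSON
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` reproduces
#' `x` on the data model (ids, labels, splits, timestamps at second precision,
#' text, tokens, preserved metadata).
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    p <- corpus$posts[[i]]
    posts <- purrr::pmap(
      list(p$post_id, format_ts(p$ts), p$text, p$tokens),
      function(id, ts, text, tokens) {
        rec <- list(post_id = id, ts = ts, text = text)
        if (!is.null(tokens)) rec$tokens <- as.list(tokens)
        rec
      }
    )
    obj <- list(user_id = corpus$user_id[i], label = corpus$label[i],
                posts = posts)
    if (!is.na(corpus$split[i])) obj$split <- corpus$split[i]
    obj <- c(obj, corpus$meta[[i]])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a term lexicon
#'
#' Plain UTF-8 text, one term per line; `#` starts a comment. Terms are
#' lowercased, NFC-normalized and deduplicated.
#'
#' @param path Path to the lexicon file.
#' @return A `lexicon` object (list with a `terms` character vector).
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  terms <- trimws(lines)
  terms <- terms[nzchar(terms)]
  new_lexicon(terms)
}

#' Construct a lexicon from a character vector of terms
#'
#' @param terms Character vector of terms (lowercased/NFC-normalized and
#'   deduplicated on construction).
#' @return A `lexicon` object.
#' @export
new_lexicon <- function(terms) {
  terms <- unique(tolower(nfc(as.character(terms))))
  assert_that(length(terms) > 0, "lexicon must be non-empty")
  structure(list(terms = terms), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$terms), " terms: ",
      paste(utils::head(x$terms, 8), collapse = ", "),
      if (length(x$terms) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a LIWC-style category dictionary
#'
#' Format: a line `%`, then one `id<TAB>name` line per category, a second `%`
#' line, then `term<TAB>id[,id...]` entries (whitespace-separated ids also
#' accepted, as in common .dic files). A trailing `*` on a term makes it a
#' prefix pattern matching any token it prefixes. An entry naming an
#' undeclared category id is an error.
#'
#' @param path Path to the .dic-style file.
#' @return A `category_dictionary` object.
#' @export
read_category_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  pct <- which(lines == "%")
  assert_that(length(pct) >= 2, "dictionary must contain a %%-delimited header")
  cat_lines <- lines[(pct[1] + 1):(pct[2] - 1)]
  cat_lines <- cat_lines[nzchar(cat_lines)]
  parts <- strsplit(cat_lines, "[\t ]+")
  ids <- purrr::map_chr(parts, 1)
  names_ <- purrr::map_chr(parts, 2)
  categories <- stats::setNames(names_, ids)

  entry_lines <- lines[-seq_len(pct[2])]
  entry_lines <- entry_lines[nzchar(entry_lines)]
  patterns <- character(0)
  cats <- list()
  for (ln in entry_lines) {
    fields <- strsplit(ln, "[\t ]+")[[1]]
    term <- nfc(fields[1])
    entry_ids <- unlist(strsplit(fields[-1], ","))
    entry_ids <- entry_ids[nzchar(entry_ids)]
    unknown <- setdiff(entry_ids, names(categories))
    if (length(unknown) > 0) {
      stop("dictionary entry '", term, "' references undeclared category id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (term %in% patterns) {
      stop("duplicate dictionary pattern: ", term, call. = FALSE)
    }
    patterns <- c(patterns, term)
    cats <- c(cats, list(unname(categories[entry_ids])))
  }
  is_wild <- endsWith(patterns, "*")
  structure(
    list(
      categories = unname(categories),
      literal = stats::setNames(cats[!is_wild], patterns[!is_wild]),
      wildcard_prefix = sub("\\*$", "", patterns[is_wild]),
      wildcard_cats = cats[is_wild]
    ),
    class = "category_dictionary"
  )
}

#' Look up the categories of tokens in a category dictionary
#'
#' A token matching both a literal entry and one or more wildcard prefixes
#' receives the union of all matched category sets.
#'
#' @param dictionary A `category_dictionary`.
#' @param tokens Character vector of tokens.
#' @return A list (one element per token) of character vectors of category
#'   names; empty vector where nothing matches.
#' @export
lookup_categories <- function(dictionary, tokens) {
  purrr::map(tokens, function(tok) {
    hit <- dictionary$literal[[tok]] %||% character(0)
    if (length(dictionary$wildcard_prefix) > 0) {
      wm <- startsWith(tok, dictionary$wildcard_prefix)
      if (any(wm)) {
        hit <- c(hit, unlist(dictionary$wildcard_cats[wm], use.names = FALSE))
      }
    }
    unique(hit)
  })
}

#' @export
print.category_dictionary <- function(x, ...) {
  cat("<category_dictionary> ", length(x$categories), " categories, ",
      length(x$literal), " literal and ", length(x$wildcard_prefix),
      " wildcard entries\n", sep = "")
  invisible(x)
}

#' Read a word-embedding table in word2vec text format
#'
#' First line `V D` (vocabulary size, dimension), then one `word v1 ... vD`
#' line per word. Rows with the wrong number of values are an error.
#'
#' @param path Path to the embedding file.
#' @param oov_policy How [embedding_lookup()] treats unknown words: `"zero"`
#'   returns the zero vector; `"seeded-random"` returns a reproducible
#'   standard-normal vector derived from the word and `seed`.
#' @param seed Integer seed controlling the `"seeded-random"` policy.
#' @return An `embedding_table` object.
#' @export
read_embeddings <- function(path, oov_policy = c("zero", "seeded-random"),
                            seed = 0L) {
  oov_policy <- match.arg(oov_policy)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  assert_that(length(header) == 2 && !anyNA(header),
              "embedding header must be 'V D'")
  v <- header[1]; d <- header[2]
  body <- lines[-1]
  body <- body[nzchar(body)]
  assert_that(length(body) == v,
              sprintf("embedding file declares %d rows but has %d", v, length(body)))
  words <- character(v)
  mat <- matrix(0, v, d)
  for (i in seq_len(v)) {
    fields <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(fields) != d + 1) {
      stop(sprintf("embedding row %d ('%s') has %d values, expected %d",
                   i + 1L, fields[1], length(fields) - 1L, d), call. = FALSE)
    }
    words[i] <- nfc(fields[1])
    mat[i, ] <- as.numeric(fields[-1])
  }
  assert_that(!anyNA(mat), "non-numeric embedding value")
  new_embedding_table(words, mat, oov_policy = oov_policy, seed = seed)
}

#' Construct an embedding table from a word vector and matrix
#'
#' @param words Character vector of words (rows of `vectors`).
#' @param vectors Numeric matrix, one row per word.
#' @param oov_policy,seed See [read_embeddings()].
#' @return An `embedding_table` object.
#' @export
new_embedding_table <- function(words, vectors,
                                oov_policy = c("zero", "seeded-random"),
                                seed = 0L) {
  oov_policy <- match.arg(oov_policy)
  assert_that(length(words) == nrow(vectors), "one row per word required")
  assert_that(!anyDuplicated(words), "duplicate word in embedding table")
  rownames(vectors) <- NULL
  structure(
    list(dimension = ncol(vectors), words = words,
         index = stats::setNames(seq_along(words), words),
         vectors = vectors, oov_policy = oov_policy, seed = as.integer(seed)),
    class = "embedding_table"
  )
}

#' Look up embedding vectors for words
#'
#' Unknown words follow the table's out-of-vocabulary policy deterministically.
#'
#' @param table An `embedding_table`.
#' @param words Character vector of words.
#' @return A numeric matrix with one row per requested word.
#' @export
embedding_lookup <- function(table, words) {
  idx <- table$index[words]
  out <- matrix(0, length(words), table$dimension)
  known <- !is.na(idx)
  if (any(known)) out[known, ] <- table$vectors[idx[known], , drop = FALSE]
  if (any(!known) && table$oov_policy == "seeded-random") {
    for (i in which(!known)) {
      out[i, ] <- with_seed(
        (table$seed + fnv1a32(words[i])) %% 2147483647,
        stats::rnorm(table$dimension)
      )
    }
  }
  rownames(out) <- words
  out
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", length(x$words), " words x ", x$dimension,
      " dims (oov: ", x$oov_policy, ")\n", sep = "")
  invisible(x)
}

#' Write an embedding table in word2vec text format
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(table$words), table$dimension), con)
  rows <- apply(table$vectors, 1, function(v)
    paste(format(v, digits = 17, scientific = TRUE, trim = TRUE), collapse = " "))
  writeLines(paste(table$words, rows), con)
  invisible(path)
}
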