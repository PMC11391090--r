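#' Per-group behavioural statistics
#'
#' Computes, for each cohort: average words per post (Word/Post), posts per
#' user (Post/User), posts per user per week (weeks = `ceiling(span in
#' days / 7)` per user, at least 1), first-person singular and plural counts
#' per post (token-level exact match, so 我 inside 我们 counts only as
#' plural), depression-keyword mentions per post, and drug-term mentions per
#' post. Counts are pooled within group (totals over the group divided by
#' the group's post/user totals).
#'
#' @param corpus A labeled corpus tibble with tokens set.
#' @param keywords Character vector counted as depression keywords
#'   (default 抑郁症, 抑郁).
#' @param drug_terms Character vector of medication-related terms.
#' @return A feature-profile tibble: `group`, `feature`, `value`,
#'   `denominator`.
#' @export
behavior_stats <- function(corpus,
                           keywords = c("抑郁症", "抑郁"),
                           drug_terms = character(0)) {
  keywords <- nfc(keywords)
  drug_terms <- nfc(drug_terms)
  groups <- c("depressed", "control")
  assert_that(all(groups %in% corpus$label),
              "corpus must contain both depressed and control users")
  purrr::map(groups, function(gr) {
    sub <- corpus[corpus$label == gr, , drop = FALSE]
    n_users <- nrow(sub)
    n_posts <- sum(purrr::map_int(sub$posts, nrow))
    all_tokens <- purrr::map(sub$posts, function(p)
      unlist(p$tokens, use.names = FALSE))
    n_tokens <- sum(lengths(all_tokens))
    weeks <- purrr::map_dbl(sub$posts, function(p) {
      span <- as.numeric(difftime(max(p$ts), min(p$ts), units = "days"))
      max(1, ceiling(span / 7))
    })
    count_terms <- function(terms) {
      if (length(terms) == 0) return(0)
      sum(purrr::map_dbl(all_tokens, ~ sum(.x %in% terms)))
    }
    tibble::tibble(
      group = gr,
      feature = c("word_per_post", "post_per_user", "post_per_user_week",
                  "first_sing_per_post", "first_plur_per_post",
                  "keyword_per_post", "drugs_per_post"),
      value = c(
        n_tokens / n_posts,
        n_posts / n_users,
        mean(purrr::map_int(sub$posts, nrow) / weeks),
        count_terms("我") / n_posts,
        count_terms("我们") / n_posts,
        count_terms(keywords) / n_posts,
        count_terms(drug_terms) / n_posts
      ),
      denominator = c("per-post", "per-user", "per-user-week", "per-post",
                      "per-post", "per-post", "per-post")
    )
  }) |> dplyr::bind_rows()
}

#' LIWC-style category relative frequencies per group
#'
#' Per category: the number of tokens matching any of the category's
#' patterns (literal or trailing-wildcard prefix) divided by the total token
#' count — pooled over the group (`"pooled"`, default) or computed per user
#' and averaged (`"per-user"`). The convention used is recorded in the
#' `denominator` column.
#'
#' @param corpus A labeled corpus tibble with tokens set.
#' @param dictionary A [read_category_dictionary()] object.
#' @param denominator `"pooled"` or `"per-user"`.
#' @return A feature-profile tibble (`group`, `feature`, `value`,
#'   `denominator`).
#' @export
category_frequencies <- function(corpus, dictionary,
                                 denominator = c("pooled", "per-user")) {
  denominator <- match.arg(denominator)
  assert_that(length(dictionary$categories) > 0, "dictionary must be non-empty")
  cats <- dictionary$categories
  groups <- c("depressed", "control")
  count_user <- function(posts) {
    toks <- unlist(posts$tokens, use.names = FALSE)
    hits <- lookup_categories(dictionary, toks)
    counts <- stats::setNames(numeric(length(cats)), cats)
    tab <- table(unlist(hits, use.names = FALSE))
    counts[names(tab)] <- as.numeric(tab)
    list(counts = counts, n = length(toks))
  }
  purrr::map(groups, function(gr) {
    sub <- corpus[corpus$label == gr, , drop = FALSE]
    per_user <- purrr::map(sub$posts, count_user)
    value <- if (denominator == "pooled") {
      tot <- Reduce(`+`, purrr::map(per_user, "counts"))
      n <- sum(purrr::map_dbl(per_user, "n"))
      tot / max(n, 1)
    } else {
      freqs <- purrr::map(per_user, ~ .x$counts / max(.x$n, 1))
      Reduce(`+`, freqs) / length(freqs)
    }
    tibble::tibble(group = gr, feature = unname(cats), value = unname(value),
                   denominator = paste0("per-token-", denominator))
  }) |> dplyr::bind_rows()
}

#' Modal-particle / punctuation profile per group
#'
#' Counts each symbol's occurrences in the raw (pre-strip) post text,
#' averaged per post within each group. Defaults cover the modal particles
#' 的, 呢, 吗, 吧, 啊 and the punctuation marks 。, ，, ！, ？, ~, …….
#'
#' @param corpus A labeled corpus tibble (raw `text` column used).
#' @param symbols Character vector of symbols to count.
#' @return A feature-profile tibble.
#' @export
symbol_profile <- function(corpus, symbols = default_symbols()) {
  symbols <- nfc(symbols)
  groups <- c("depressed", "control")
  purrr::map(groups, function(gr) {
    sub <- corpus[corpus$label == gr, , drop = FALSE]
    texts <- unlist(purrr::map(sub$posts, "text"), use.names = FALSE)
    n_posts <- length(texts)
    counts <- purrr::map_dbl(symbols, function(sym)
      sum(stringr::str_count(texts, stringr::fixed(sym))))
    tibble::tibble(group = gr, feature = symbols, value = counts / n_posts,
                   denominator = "per-post")
  }) |> dplyr::bind_rows()
}

#' @rdname symbol_profile
#' @export
default_symbols <- function() {
  c("的", "呢", "吗", "吧", "啊",      # 的 呢 吗 吧 啊
    "。", "，", "！", "？", "~", "……")
}

#' Compare the two group profiles feature by feature
#'
#' @param profile A combined feature-profile tibble (both groups), as
#'   returned by [behavior_stats()], [category_frequencies()] or
#'   [symbol_profile()]; alternatively pass the depressed-only profile here
#'   and the control profile as `profile_control`.
#' @param profile_control Optional control-group profile tibble.
#' @param n_tokens Optional length-2 vector `c(depressed, control)` of group
#'   token totals; when supplied, a two-proportion z statistic is attached
#'   per feature (an extension beyond the descriptive comparison; only
#'   meaningful for per-token relative frequencies).
#' @return A tibble sorted by absolute difference (descending): `feature`,
#'   `depressed`, `control`, `abs_diff`, `ratio`, `direction` (and `z` when
#'   requested).
#' @export
compare_groups <- function(profile, profile_control = NULL,
                           n_tokens = NULL) {
  if (is.null(profile_control)) {
    dep <- profile[profile$group == "depressed", , drop = FALSE]
    ctl <- profile[profile$group == "control", , drop = FALSE]
  } else {
    dep <- profile
    ctl <- profile_control
  }
  only_dep <- setdiff(dep$feature, ctl$feature)
  only_ctl <- setdiff(ctl$feature, dep$feature)
  if (length(only_dep) > 0 || length(only_ctl) > 0) {
    stop("profiles have mismatched feature sets; only in depressed: [",
         paste(only_dep, collapse = ", "), "], only in control: [",
         paste(only_ctl, collapse = ", "), "]", call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(dep, "feature", depressed = "value"),
    dplyr::select(ctl, "feature", control = "value"),
    by = "feature") |>
    dplyr::mutate(
      abs_diff = abs(.data$depressed - .data$control),
      ratio = ifelse(.data$control == 0, NA_real_,
                     .data$depressed / .data$control),
      direction = dplyr::case_when(
        .data$depressed > .data$control ~ "depressed>control",
        .data$depressed < .data$control ~ "depressed<control",
        TRUE ~ "equal")) |>
    dplyr::arrange(dplyr::desc(.data$abs_diff))
  if (!is.null(n_tokens)) {
    n1 <- n_tokens[1]
    n2 <- n_tokens[2]
    pool <- (out$depressed * n1 + out$control * n2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    out$z <- ifelse(se == 0, 0, (out$depressed - out$control) / se)
  }
  out
}

#' Plot a feature profile as paired group bars
#'
#' @param profile A combined feature-profile tibble.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$feature, y = .data$value,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "value", fill = "group") +
    ggplot2::theme_minimal()
}
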