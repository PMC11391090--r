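two_group_corpus <- function() {
  new_corpus(list(
    list(user_id = "d1", label = "depressed",
         posts = make_posts(
           list(c("我", "很", "难过"), c("我", "想", "哭", "了"),
                c("抑郁症", "药", "我")),
           texts = c("我 很 难过。", "我 想 哭 了……", "抑郁症 药 我。"))),
    list(user_id = "c1", label = "control",
         posts = make_posts(
           list(c("我们", "出去", "玩", "啊"), c("今天", "天气", "好")),
           texts = c("我们 出去 玩 啊！", "今天 天气 好，")))
  ))
}

test_that("behaviour statistics compute the documented rates", {
  corpus <- two_group_corpus()
  stats <- behavior_stats(corpus, drug_terms = c("药"))
  dep <- stats[stats$group == "depressed", ]
  val <- function(f) dep$value[dep$feature == f]
  expect_equal(val("word_per_post"), (3 + 4 + 3) / 3)
  expect_equal(val("post_per_user"), 3)
  # 我 appears once in each of the three posts; 我们 never (token-level
  # matching: 我 inside 我们 is not a singular hit)
  expect_equal(val("first_sing_per_post"), 1)
  expect_equal(val("first_plur_per_post"), 0)
  expect_equal(val("keyword_per_post"), 1 / 3)
  expect_equal(val("drugs_per_post"), 1 / 3)

  ctl <- stats[stats$group == "control", ]
  expect_equal(ctl$value[ctl$feature == "first_plur_per_post"], 1 / 2)
  expect_equal(ctl$value[ctl$feature == "first_sing_per_post"], 0)
})

test_that("posts per user-week uses ceil(span/7) weeks with a floor of one week", {
  # 10 posts spanning exactly 35 days -> 5 weeks -> 2 posts per week
  ts0 <- as.POSIXct("2023-01-01T00:00:00", format = "%Y-%m-%dT%H:%M:%S",
                    tz = "UTC")
  posts <- tibble::tibble(
    post_id = sprintf("p%02d", 1:10),
    ts = ts0 + as.numeric(seq(0, 35, length.out = 10)) * 86400,
    text = "x y z",
    tokens = rep(list(c("x", "y", "z")), 10))
  corpus <- new_corpus(list(
    list(user_id = "d1", label = "depressed", posts = posts),
    list(user_id = "c1", label = "control",
         posts = make_posts(list(c("a", "b", "c"))))))
  stats <- behavior_stats(corpus)
  expect_equal(stats$value[stats$group == "depressed" &
                             stats$feature == "post_per_user_week"], 2)
  # a single post spans zero days but still counts one week
  expect_equal(stats$value[stats$group == "control" &
                             stats$feature == "post_per_user_week"], 1)
})

test_that("category frequencies: pooled counting, saturation and empty cases", {
  path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tNegEmo", "2\tAll", "3\tNone", "%",
               "难过\t1", "哭\t1", "难*\t2", "哭*\t2", "我*\t2", "很*\t2",
               "想*\t2", "了*\t2", "抑*\t2", "药*\t2"), path)
  dict <- read_category_dictionary(path)
  dep_posts <- list(c("我", "很", "难过"), c("我", "想", "哭", "了"),
                    c("抑郁症", "药", "我"))
  corpus <- two_group_corpus()
  freqs <- category_frequencies(corpus, dict)
  dep <- freqs[freqs$group == "depressed", ]
  # 2 of the 10 depressed tokens are NegEmo
  expect_equal(dep$value[dep$feature == "NegEmo"], 2 / 10)
  # the wildcard set covers every depressed token
  expect_equal(dep$value[dep$feature == "All"], 1)
  # a category with no matches scores zero
  expect_equal(dep$value[dep$feature == "None"], 0)
})

test_that("category frequencies agree with a brute-force nested-loop counter", {
  set.seed(17)
  path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tA", "2\tB", "%",
               "t1\t1", "t2\t1,2", "t3\t2", "t4*\t2"), path)
  dict <- read_category_dictionary(path)
  words <- c("t1", "t2", "t3", "t4x", "t4", "zz", "yy")
  for (rep in 1:10) {
    users <- purrr::map(1:6, function(i) {
      list(user_id = sprintf("u%d", i),
           label = if (i <= 3) "depressed" else "control",
           posts = make_posts(purrr::map(1:3, ~ sample(words, 5, TRUE))))
    })
    corpus <- new_corpus(users)
    got <- category_frequencies(corpus, dict)
    for (gr in c("depressed", "control")) {
      toks <- unlist(purrr::map(corpus$posts[corpus$label == gr],
                                ~ unlist(.x$tokens)))
      for (cat_name in c("A", "B")) {
        hits <- 0
        for (tok in toks) {
          matched <- FALSE
          if (cat_name == "A" && tok %in% c("t1", "t2")) matched <- TRUE
          if (cat_name == "B" && (tok %in% c("t2", "t3") ||
                                    startsWith(tok, "t4"))) matched <- TRUE
          if (matched) hits <- hits + 1
        }
        expect_equal(
          got$value[got$group == gr & got$feature == cat_name],
          hits / length(toks))
      }
    }
  }
})

test_that("disjoint categories pool to at most one", {
  path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tX", "2\tY", "%", "a\t1", "b\t2"), path)
  dict <- read_category_dictionary(path)
  corpus <- mini_corpus(list(u1 = list(c("a", "b", "c")),
                             u2 = list(c("c", "c", "a"))),
                        labels = c("depressed", "control"))
  freqs <- category_frequencies(corpus, dict)
  sums <- tapply(freqs$value, freqs$group, sum)
  expect_true(all(sums <= 1 + 1e-12))
})

test_that("symbol profile counts particles and punctuation in raw text", {
  corpus <- two_group_corpus()
  prof <- symbol_profile(corpus)
  dep <- prof[prof$group == "depressed", ]
  val <- function(s) dep$value[dep$feature == s]
  expect_equal(val("。"), 2 / 3)
  expect_equal(val("……"), 1 / 3)
  expect_equal(val("！"), 0)
  ctl <- prof[prof$group == "control", ]
  expect_equal(ctl$value[ctl$feature == "啊"], 1 / 2)
  # a symbol absent everywhere scores zero in both groups
  none <- symbol_profile(corpus, symbols = "？")
  expect_true(all(none$value == 0))
})

test_that("compare_groups computes differences, ratios, direction and sorting", {
  prof <- tibble::tibble(
    group = rep(c("depressed", "control"), each = 3),
    feature = rep(c("a", "b", "c"), 2),
    value = c(0.02, 0.01, 0.5, 0.01, 0.01, 0.1),
    denominator = "per-token-pooled")
  cmp <- compare_groups(prof)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$feature[1], "c")  # largest absolute difference first
  row_a <- cmp[cmp$feature == "a", ]
  expect_equal(row_a$abs_diff, 0.01)
  expect_equal(row_a$ratio, 2)
  expect_equal(row_a$direction, "depressed>control")
  expect_equal(cmp$direction[cmp$feature == "b"], "equal")

  ident <- compare_groups(prof[prof$group == "depressed", ],
                          prof[prof$group == "depressed", ])
  expect_true(all(ident$abs_diff == 0))

  bad <- prof[-1, ]
  expect_error(compare_groups(bad), "mismatched feature sets")
})

test_that("punctuation direction in generated corpora follows the configured rates", {
  corpus <- generate_corpus(gen_config(n_users_per_class = 80, seed = 23))
  prof <- symbol_profile(corpus, symbols = c("。", "，"))
  wide <- tidyr::pivot_wider(prof[, c("group", "feature", "value")],
                             names_from = "group", values_from = "value")
  expect_gt(wide$depressed[wide$feature == "。"],
            wide$control[wide$feature == "。"])
  expect_lt(wide$depressed[wide$feature == "，"],
            wide$control[wide$feature == "，"])
})
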