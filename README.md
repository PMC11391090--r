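# deprscreen

User-level depression-risk screening from timelines of short social-media
posts, for researchers in mental-health informatics and clinical NLP who
want a self-contained, inspectable reference implementation of a
hierarchical neural screening pipeline — plus the linguistic analysis layer
used to characterise how at-risk and control cohorts differ in language use.

## What it implements

**The classifier.** Each user is a chronological sequence of posts; the
label is `depressed` or `control`. A hierarchical transformer network (HTN)
encodes the timeline in three stages:

1. *word level* — tokens of each post are embedded (any word2vec-format
   table), a learned `[CLS]` token is prepended, sinusoidal positional
   encodings are added, and a shared transformer encoder produces the post
   embedding as the final `[CLS]` state;
2. *post level* — a second transformer contextualises the post-embedding
   sequence in posting order;
3. *aggregation* — an LSTM with additive attention
   (`alpha_i = softmax_i(v' tanh(W h_i))`) pools the hidden states into one
   user vector, classified by `sigmoid(w'u + b)`.

**Post sampling.** Before training, each user's posts can be subsampled:
`retrieval` keeps the `ceiling(rate * N)` posts with the most
depression-lexicon term matches (ties to the most recent), `random` draws
uniformly, `none` keeps everything. Sampling is per user and fully
deterministic given the seed.

**Baselines.** The flat "concatenated long text" family — CNN
(kernels {2,3,4} × 100 filters), LSTM, GRU, BiLSTM, BiGRU, each optionally
with additive attention pooling — and a hierarchical convolutional network,
all sharing the classifier head and training loop.

**Linguistics.** Behavioural statistics (words/post, posts/user/week,
first-person pronoun use, keyword and medication mentions), LIWC-style
category frequencies with trailing-wildcard dictionaries, modal-particle and
punctuation profiles, and a group comparison table.

**Synthetic benchmark.** A generator producing balanced cohorts whose
depressed users write fewer, shorter posts, carry far more lexicon "signal"
posts, and use 我 more / 我们 less — so the whole pipeline is testable with
no private data. Neural training runs on a small reverse-mode autodiff
engine written in base R; the package has no deep-learning framework
dependency.

## Worked example

```r
library(deprscreen)

study  <- simulate_study("strong", n_users_per_class = 200,
                         dimension = 32, seed = 42)
corpus <- split_corpus(study$corpus, c(100, 30, 70), seed = 1)
views  <- sample_corpus(corpus, "retrieval", rate = 0.5,
                        lexicon = study$lexicon)

cfg <- htn_config(d_model = 16, n_heads = 2, n_word_layers = 1,
                  n_post_layers = 1, ffn_mult = 2, lstm_hidden = 16,
                  attn_size = 16, max_post_tokens = 24,
                  max_posts_per_user = 24)
fit <- train_model(htn_model(cfg, study$embeddings, seed = 5),
                   corpus, views,
                   train_config(max_epochs = 3, batch_size = 8, seed = 5),
                   quiet = FALSE)
#> epoch 1  loss 0.6950  val acc 0.8333  val F1 0.8316
#> epoch 2  loss 0.6641  val acc 0.9667  val F1 0.9666
#> epoch 3  loss 0.4955  val acc 0.9500  val F1 0.9500

evaluate_model(fit, corpus, views, split = "test")
#> <metrics_report> n=140  accuracy=0.8929  macroP=0.8929  macroR=0.8929  macroF1=0.8929
```

140 held-out users (70 per cohort), generated with a strong lexical signal,
are classified at ~89% accuracy after three quick epochs on half of each
user's posts — the posts the retrieval strategy ranked most
depression-relevant (means over several seeds land in the mid-90s; see
the reproduction section).
`tidy()` on the report gives the four metrics as a tibble; `glance(fit)`
summarises the fitted model. The linguistics layer runs on the same corpus:

```r
behavior_stats(study$corpus) |> compare_groups()
#> # A tibble: 7 x 6
#>   feature             depressed control abs_diff ratio direction
#>   <chr>                   <dbl>   <dbl>    <dbl> <dbl> <chr>
#> 1 post_per_user          26.4    35.0      8.62  0.754 depressed<control
#> 2 word_per_post           7.97   12.0      4.03  0.664 depressed<control
#> 3 first_sing_per_post     0.470   0.247    0.224 1.91  depressed>control
#> # ... 4 more rows
```

A thin command-line front end over these functions ships in
`inst/cli/deprscreen.R` (subcommands `simulate`, `prep`, `sample`, `train`,
`eval`, `analyze`).

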