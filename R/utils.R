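# Internal helpers shared across modules.

# 32-bit FNV-1a hash of a character scalar, returned as a double in [0, 2^31).
# Used to derive stable per-user random seeds; arithmetic kept in doubles
# (exact below 2^53) to avoid R's 32-bit integer overflow.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483647
}

# xor of two non-negative doubles < 2^32 (base bitwXor is integer-only)
bitwXor64 <- function(a, b) {
  res <- 0
  bit <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) res <- res + bit
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  res
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# ceiling(rate * n) with protection against 0.75 * 4 style FP undershoot
sample_size <- function(rate, n) {
  k <- ceiling(rate * n - 1e-9)
  as.integer(max(1L, min(n, k)))
}

nfc <- function(x) stringi::stri_trans_nfc(x)

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("unparseable timestamp: ", x[bad], call. = FALSE)
  }
  out
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
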