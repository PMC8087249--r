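#' @importFrom stats coef cor cor.test lm.fit pchisq pnorm pt qnorm rbeta rbinom
#'   rnorm runif sd setNames t.test var predict quantile
#' @importFrom utils head
NULL

# Derive a child seed from a base seed and a stream index, staying inside the
# 32-bit integer range the base RNG seeding accepts.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647L)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable, order-free integer hash of a label (for per-gene seed streams).
string_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

# Format doubles so that read-back reproduces them bit-exactly (17 significant
# digits round-trips IEEE doubles); integers stay integers.
format_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
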