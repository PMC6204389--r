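# Internal helpers shared across the package.

# round half up (away from the IEEE round-half-even of base::round), used for
# all printed percentages so that e.g. 26.15 -> 26.2 and 64.97 -> 65.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# truncate (floor) towards zero at `digits` decimals; used for reporting
# adjacency values the way thresholds are conventionally printed (0.064).
trunc_digits <- function(x, digits) {
  m <- 10^digits
  trunc(x * m) / m
}

# nearest-rank percentile: smallest value whose rank >= ceil(p/100 * n)
nearest_rank_percentile <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 100)
  xs <- sort(x)
  xs[ceiling(p / 100 * length(xs))]
}

# derive a reproducible substream seed from a master seed and a stream label;
# keeps results of one generator stage invariant to changes in another.
substream_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
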