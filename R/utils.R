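# Internal numerical helpers.

# log(sum(exp(x))) without overflow; returns -Inf for empty input.
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Probabilities are clamped inside log terms only; simulation uses raw p.
P_FLOOR <- 1e-300
P_CEIL <- 1 - 1e-15

clamp_p <- function(p) pmin(pmax(p, P_FLOOR), P_CEIL)

# Derive a reproducible child seed from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483562L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
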