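# Internal numerical helpers.

# Row-wise log-sum-exp for a matrix of log weights.  Guards the all -Inf row
# (returns -Inf rather than NaN).
row_logsumexp <- function(lw) {
  m <- apply(lw, 1L, max)
  bad <- !is.finite(m)
  m_safe <- ifelse(bad, 0, m)
  out <- m_safe + log(rowSums(exp(lw - m_safe)))
  out[bad] <- -Inf
  out
}

logsumexp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lw - m)))
}

# Deterministic substream seeds: one master seed spawns per-stream seeds,
# kept below 2^31 so they remain valid R integers.
substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7907 * as.numeric(stream)) %% 2147483647
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_config <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
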