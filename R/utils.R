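#' @keywords internal
"_PACKAGE"

# Derive a child RNG seed from a user seed and a stream offset. Keeps results
# below 2^31 - 1 so they remain valid R integers.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(offset) * 104729 + 1) %% 2147483647)
}

clip_pct <- function(x) pmin(pmax(x, 0), 100)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

r_squared <- function(obs, pred) {
  ss <- sum((obs - mean(obs))^2)
  if (ss == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
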