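# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# FNV-1a 32-bit hash of a character scalar; used for stage-seed fan-out and
# config fingerprints in file headers. Arithmetic kept in double (< 2^53).
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  h
}

# Derive a per-stage seed from one global seed; stays below 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + fnv1a32(stage)) %% 2147483587L)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Canonical unordered pair key, used to compare edge sets.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
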