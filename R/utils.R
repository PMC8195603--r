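#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without under/overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# sample one integer uniformly from lo..hi (safe when lo == hi, unlike
# sample(lo:hi, 1) which falls into sample.int semantics)
sample_range <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  as.integer(sample(lo:hi, 1L))
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# streams without risking integer overflow (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647L)
}
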