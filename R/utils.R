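## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ..., class = "devmqtl_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.checkProb <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    .stopf("%s must lie in [0,1]", what, class = "devmqtl_domain_error")
  invisible(x)
}

## derive a stream-specific 32-bit seed from a master seed; keeps every
## simulation stage independently reproducible under one --seed
.deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483647L)
}
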