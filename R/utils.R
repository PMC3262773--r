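`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash over UTF-8 bytes, mod 2^31-1. Used for config
# fingerprints and stage-seed derivation; stability across platforms matters,
# cryptographic strength does not.
poly_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in as.integer(charToRaw(x))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Derive a per-stage RNG seed from a single pipeline seed so that changing the
# draw count of one stage never shifts another stage's stream.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) %% 65536 + 1) * 29269 + poly_hash(stage) %% 1e6) %% 2147483647L
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("mircoord_config_error", "error")))
}

stage_error <- function(stage, parent) {
  stop(errorCondition(
    sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(parent)),
    class = c("mircoord_stage_error", "error")
  ))
}
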