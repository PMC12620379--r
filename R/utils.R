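# internal helpers: error conditions and seed scoping

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("eegfd_invalid_parameter", "eegfd_error")))
}

stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("eegfd_invalid_input", "eegfd_error")))
}

stop_unrecoverable <- function(msg) {
  stop(errorCondition(msg, class = c("eegfd_unrecoverable_recording", "eegfd_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("eegfd_degenerate_signal", "eegfd_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage child seeds: adding a stage never perturbs the
# streams of earlier stages (named-substream scheme, kept below 2^31).
child_seed <- function(seed, stage) {
  stages <- c("simulate", "preprocess", "features", "transform",
              "rank", "classify", "stats", "replicate")
  i <- match(stage, stages)
  if (is.na(i)) stop_invalid(sprintf("unknown stage '%s'", stage))
  as.integer((as.numeric(seed) * 48271 + i * 2654435) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)
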