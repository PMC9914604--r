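# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every sampling routine so that seed arguments are local.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (values here are non-negative, so half-up),
# matching the fixed-point convention used for 8-bit pixel data.
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pulsebeat_input_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pulsebeat_config_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
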