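# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error class.
stop_morphherit <- function(msg, class = "morphherit_error", ...) {
  rlang::abort(msg, class = class, ...)
}

# Derive independent sub-seeds from one master seed, so adding a downstream
# stage never perturbs the draws of an earlier one.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code under a temporary seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}

check_count <- function(x, name) {
  if (!is_count(x)) {
    stop_morphherit(sprintf("`%s` must be a single positive integer.", name))
  }
  as.integer(x)
}
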