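# internal helpers shared across modules

abort_domain <- function(msg, call = rlang::caller_env()) {
  rlang::abort(msg, class = "sarmact_domain_error", call = call)
}

abort_config <- function(msg, call = rlang::caller_env()) {
  rlang::abort(msg, class = "sarmact_config_error", call = call)
}

abort_fit <- function(msg, call = rlang::caller_env()) {
  rlang::abort(msg, class = "sarmact_fit_error", call = call)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    abort_domain(sprintf("`%s` must be finite and numeric.", name))
  if (any(x < 0))
    abort_domain(sprintf("`%s` must be non-negative.", name))
  invisible(x)
}

check_pos <- function(x, name) {
  check_nonneg(x, name)
  if (any(x <= 0)) abort_domain(sprintf("`%s` must be strictly positive.", name))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomised code in the package funnels through this so that a single
# user-facing `seed` argument makes every result reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_domain("`seed` must be a single finite number.")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Fixed seed-splitting rule: one global seed fans out to independent
# per-stream seeds. Streams: 1 dose-response, 2 time-course, 3 isotherm,
# 4 fitting multi-starts.
split_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream)) %% .Machine$integer.max
}
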