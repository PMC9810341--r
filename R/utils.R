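# Internal helpers shared across modules.

#' Evaluate code with a private, reproducible RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package operations never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from a global one; offsets keep stages
# individually reproducible while remaining inside 32-bit integer range.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stop_if_not_scalar_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", what), call. = FALSE)
  invisible(x)
}
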