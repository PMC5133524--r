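#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed parameter error
#' @noRd
stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("trajgwas_param_error", "error")))
}

#' Stop with a classed structural/invariant error
#' @noRd
stop_invariant <- function(...) {
  stop(errorCondition(paste0(...), class = c("trajgwas_invariant_error", "error")))
}

#' Signal that a SNP should be skipped (not an error for the caller loop)
#' @noRd
signal_snp_skip <- function(msg) {
  stop(errorCondition(msg, class = c("trajgwas_snp_skip", "error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop_param(name, " must be a finite number in [", min, ", ", max, "]")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_param(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

#' Derive a per-stage seed from a single pipeline seed
#'
#' One global seed fans out to independent per-stage seeds so each stage is
#' individually reproducible.  The rule is `(seed * 97 + 13 * index) mod
#' (2^31 - 1)`, kept within the 32-bit integer range R requires.
#'
#' @param seed integer master seed.
#' @param index nonnegative integer stage index.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, index) {
  seed <- assert_count(seed, "seed", min = 0L)
  index <- assert_count(index, "index", min = 0L)
  as.integer((as.double(seed) * 97 + 13 * as.double(index)) %% (2^31 - 1))
}

## Evaluate expr with a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
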