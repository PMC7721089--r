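## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so package functions are reproducible without
#' clobbering the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Lightweight logging: informational messages go through message() so callers
## can suppressMessages(); they are part of the documented behaviour (dropped
## sample counts etc.), not debug chatter.
log_info <- function(...) message(sprintf(...))

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop2(...)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x > 0

## Check an expression matrix: numeric, dimnames present and unique.
validate_expression <- function(x, what = "expression matrix") {
  assert_that(is.matrix(x) && is.numeric(x), "%s must be a numeric matrix", what)
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "%s must have gene rownames and sample colnames", what)
  assert_that(!anyDuplicated(rownames(x)), "%s has duplicated gene symbols", what)
  assert_that(!anyDuplicated(colnames(x)), "%s has duplicated sample IDs", what)
  invisible(x)
}
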