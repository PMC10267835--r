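#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the prior
#' RNG state, so package functions are reproducible without clobbering the
#' caller's random stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stream child seed from a master seed
#'
#' Deterministically maps (master seed, stream index) to a 31-bit integer so
#' that each simulated spot or sweep cell gets an independent, reproducible
#' stream.
#'
#' @param seed Master integer seed.
#' @param i Stream index (positive integer).
#' @return An integer seed in `[0, 2^31)`.
#' @keywords internal
child_seed <- function(seed, i) {
  # splitmix-style integer hash, kept in 31-bit range for R's set.seed
  x <- (as.double(seed) * 2654435761 + as.double(i) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write a small run manifest as JSON
#'
#' @param path Output file path.
#' @param ... Named fields to record (seeds, parameters, hashes).
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
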