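# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the current RNG state, sets the seed, runs the expression, and
#' restores the state afterwards, so that seeded package internals never
#' perturb the caller's random-number stream.
#'
#' @param seed integer seed, or `NULL` to run without touching the RNG.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive reproducible child seeds from a root seed. Each dataset, replicate
# and method consumes its own sub-stream, so adding a method to a study never
# changes how the data are generated.
make_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_feature_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'", arg, "' must be a numeric matrix (samples in rows)", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("'", arg, "' contains missing or non-finite values", call. = FALSE)
  x
}

check_conformable <- function(x, y) {
  if (length(y) != nrow(x))
    stop("length(y) [", length(y), "] does not match nrow(x) [", nrow(x), "]",
         call. = FALSE)
  invisible(TRUE)
}

stop_input <- function(...) stop(..., call. = FALSE)
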