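# internal helpers shared across modules

#' @keywords internal
#' @importFrom Matrix sparseMatrix crossprod tcrossprod
#' @importFrom methods as
#' @importFrom stats rnorm runif
#' @importFrom utils head write.table
"_PACKAGE"

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("`%s` must contain only finite values", what), call. = FALSE)
  invisible(x)
}

check_scalar <- function(x, what, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", what), call. = FALSE)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stop(sprintf("`%s` must be %s %s", what, if (strict) ">" else ">=", format(lower)), call. = FALSE)
  invisible(x)
}

check_count <- function(x, what, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    stop(sprintf("`%s` must be an integer >= %d", what, lower), call. = FALSE)
  as.integer(x)
}

l2norm <- function(x) sqrt(sum(x * x))

# Evaluate `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
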