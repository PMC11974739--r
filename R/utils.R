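#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All stochastic operations in the
## package route through this so that library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

## Row-major flattening helpers for 3-d arrays (trials x T x D) so that the
## on-disk JSON layout is independent of R's column-major memory order.
flatten_rowmajor <- function(a) as.vector(aperm(a, c(3L, 2L, 1L)))

unflatten_rowmajor <- function(v, dims) {
  aperm(array(v, dim = rev(dims)), c(3L, 2L, 1L))
}
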