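#' @keywords internal
"_PACKAGE"

#' @importFrom stats median runif
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All stochastic entry points route
## through this so that library code never clobbers user RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop2 <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}
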