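#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois rlnorm runif quantile median mad
#'   density cor sd var p.adjust pbinom dnbinom dpois setNames
#' @importFrom utils head read.table write.table
NULL

# Stop with a consistent message prefix.
stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators do not perturb the
# session stream.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stop2("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) guarded against -Inf-only input.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}
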