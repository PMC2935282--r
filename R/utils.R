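## Small internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats fft optim rnorm runif sd
#' @importFrom utils head read.table write.table
NULL

.deg2rad <- function(x) x * pi / 180

## Wrap fractional coordinates into [0, 1).
.wrapFrac <- function(x) x - floor(x)

## Wrap fractional deltas into [-0.5, 0.5) (minimum image).
.wrapHalf <- function(x) x - round(x)

## Smallest integer >= n whose prime factors are all in {2, 3, 5, 7}.
## FFT-friendly grid dimensions.
.nextSmooth <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

.isSmooth <- function(n) {
  for (p in c(2L, 3L, 5L, 7L)) while (n %% p == 0L) n <- n %/% p
  n == 1L
}

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
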