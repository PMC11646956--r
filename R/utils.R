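#' @importFrom methods new is validObject slot setValidity show
#' @importFrom stats sd median quantile loess loess.control predict spline
#'   rnorm runif rbinom plogis uniroot wilcox.test kruskal.test t.test
#'   p.adjust phyper cor prcomp setNames complete.cases dist
#' @importFrom utils read.csv write.csv read.delim head combn
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. All stochastic entry points funnel through
## this so that a given seed yields bit-identical output regardless of what
## the session RNG was doing.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Per-iteration substreams: a master seed deterministically spawns one child
## seed per iteration (kept below 2^31 - 1).
spawnSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

## Truncated-normal draw by rejection; fine for the mild truncation used for
## ages on [40, 86].
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
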