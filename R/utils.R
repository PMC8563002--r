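#' @keywords internal
"_PACKAGE"

#' @importFrom stats approxfun coef dnorm dpois integrate lm.fit median optim
#'   plogis plogis pnorm printCoefmat qlogis qnorm quantile rbinom rgamma
#'   rlnorm rnorm runif sd setNames uniroot var complete.cases pchisq rpois
#' @importFrom utils combn modifyList head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a locally seeded RNG, restoring the caller's RNG state.
## All generators funnel through this so a given seed is reproducible and
## library use does not disturb the user's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

fs_log <- function(..., verbose = getOption("firesib.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[firesib] ", ...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## calendar month arithmetic: months are indexed as count since Jan of
## `origin` year (Jan origin == 1), so windows are plain integer ranges
ym_index <- function(year, month, origin = 2000L) {
  (as.integer(year) - origin) * 12L + as.integer(month)
}

index_ym <- function(idx, origin = 2000L) {
  idx <- as.integer(idx)
  list(year = origin + (idx - 1L) %/% 12L, month = (idx - 1L) %% 12L + 1L)
}

## trapezoid quadrature of f(z) against the standard normal density,
## accurate for bounded, piecewise-smooth f (used by the calibration code;
## polynomial quadrature is unreliable for mixture quantile transforms)
norm_quad <- function(f, n = 8192L, zmax = 9) {
  z <- seq(-zmax, zmax, length.out = n)
  w <- dnorm(z) * (z[2L] - z[1L])
  list(z = z, w = w, value = sum(f(z) * w))
}
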