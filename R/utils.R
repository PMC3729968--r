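#' @useDynLib megconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var sd cor median quantile pt lm coef
#'   wilcox.test cor.test complete.cases
#' @importFrom utils read.csv write.csv read.delim write.table combn
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept below .Machine$integer.max.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483587)
}

#' Wrap phase angles to (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

vnorm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
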