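#' @import data.table
#' @importFrom stats cor kmeans pnorm qnorm pchisq p.adjust rbinom rpois
#'   rmultinom rhyper rnorm runif sd quantile fisher.test wilcox.test pt
#'   rlnorm median setNames
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib sc3dmulti, .registration = TRUE
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 3181 * stream) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
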