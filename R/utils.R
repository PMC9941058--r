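#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef cor sd var quantile rnorm runif rexp rbinom
#'   pchisq pnorm median complete.cases predict as.formula setNames
#'   aggregate
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a local RNG state: seeds the generator, restores the caller's
# stream afterwards so package functions never disturb user-level randomness.
with_seed <- function(seed, code) {
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Stable per-stage child seeds fanned out from one master seed, so pipeline
# stages are independently re-runnable. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, exclusions = 2L, survival = 3L, bootstrap = 4L,
              fit = 5L, report = 6L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 48271 + off * 2654435) %% 2147483399) + 1L
}

stop_kdm <- function(...) stop(sprintf(...), call. = FALSE)
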