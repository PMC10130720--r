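#' @importFrom stats rnorm rbinom rpois runif rchisq var sd cor quantile
#'   dnorm pnorm qnorm pchisq qchisq rWishart optim integrate uniroot
#'   coef predict lm as.formula setNames aggregate ave ar
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so package functions never leak RNG state into the
#' caller's session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministically derive a sub-seed from a master seed and a stage label.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
sub_seed <- function(seed, label) {
  h <- sum(as.integer(charToRaw(label)) * seq_along(charToRaw(label)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483629)
}

# Effective sample size of a (roughly stationary) MCMC draw vector, via the
# initial positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(as.numeric(n))
  acf_x <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (rho in acf_x) {
    if (rho < 0.05) break
    s <- s + rho
  }
  max(1, n / (1 + 2 * s))
}

vlog <- function(...) {
  if (isTRUE(getOption("wildqg.verbose", FALSE))) message(...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
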