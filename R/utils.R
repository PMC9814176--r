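#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; breeding reports conventionally
#' round half up. Used for all reported prediction abilities and percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Effective sample size of an MCMC draw vector
#'
#' Initial-positive-sequence estimator: n / (1 + 2 * sum of autocorrelations
#' until the first non-positive lag).
#'
#' @param x numeric vector of post-burn-in draws.
#' @return effective sample size (numeric, in (0, length(x)]).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(as.numeric(n))
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1L)]
  max(1, n / (1 + 2 * sum(ac)))
}

# Derive a per-stage seed from a global seed; keeps results < 2^31 and makes
# pipeline stages independently reproducible.
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 10000L
  (as.integer(seed) * 131L + offs) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
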