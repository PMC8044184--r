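#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Numerically stable log(sum(exp(x)))
#'
#' @param x numeric vector of log-scale values (may contain -Inf).
#' @return log(sum(exp(x))) as a single double.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## elementwise log(exp(a) + exp(b))
pairwise_logsumexp <- function(a, b) {
  hi <- pmax(a, b)
  out <- hi + log1p(exp(-abs(a - b)))
  out[!is.finite(hi)] <- hi[!is.finite(hi)]
  out
}

## log(exp(a) - exp(b)) for a >= b, -Inf when equal
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a < b) stop("logdiffexp: a < b")
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

## log(2^m - 1) without overflow
log_2m_minus_1 <- function(m) {
  m * log(2) + log1p(-(2^-m))
}

assert_base <- function(b, what = "base") {
  if (!all(b %in% BASES)) {
    stop(sprintf("%s must be one of A, C, G, T (got: %s)", what,
                 paste(setdiff(unique(b), BASES), collapse = ", ")),
         call. = FALSE)
  }
  invisible(b)
}

#' Convert Phred quality scores to error probabilities
#'
#' Error probabilities are clamped to `[1e-10, 0.75]`: a Phred score of 0
#' (q = 1) and any q >= 0.75 carry no base information under the uniform
#' error model, and q = 0 is numerically degenerate in log space.
#'
#' @param phred integer or numeric vector of Phred scores.
#' @return numeric vector of error probabilities in `[1e-10, 0.75]`.
#' @export
phred_to_error_prob <- function(phred) {
  pmin(pmax(10^(-phred / 10), 1e-10), 0.75)
}

## Phred-scale a posterior probability: -10 log10 p
prob_to_phred <- function(p) -10 * log10(p)
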