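## Gauss-Legendre nodes and weights.
##
## Nodes are roots of the Legendre polynomial P_n, found by Newton iteration
## from the Chebyshev-like asymptotic initial guesses, with P_n evaluated by
## the three-term recurrence (the classic `gauleg` scheme). O(n^2) total and
## fast enough for the orders deep pileups require; results are cached per
## order because the same orders recur across loci.

.gauss_cache <- new.env(parent = emptyenv())

## nodes/weights on [-1, 1]; exact for polynomials of degree <= 2n - 1
gauss_legendre_unit <- function(n) {
  key <- as.character(n)
  hit <- .gauss_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- (n + 1L) %/% 2L
  z <- cos(pi * (seq_len(m) - 0.25) / (n + 0.5))
  pp <- numeric(m)
  for (iter in 1:100) {
    p1 <- rep(1, m)
    p2 <- rep(0, m)
    for (j in seq_len(n)) {
      p3 <- p2
      p2 <- p1
      p1 <- ((2 * j - 1) * z * p2 - (j - 1) * p3) / j
    }
    pp <- n * (z * p1 - p2) / (z^2 - 1)
    z1 <- z
    z <- z1 - p1 / pp
    if (max(abs(z - z1)) < .Machine$double.eps) break
  }
  w_half <- 2 / ((1 - z^2) * pp^2)
  if (n %% 2L == 0L) {
    x <- c(-z, rev(z))
    w <- c(w_half, rev(w_half))
  } else {
    # odd order: middle node at 0 appears once
    x <- c(-z[-m], z[m], rev(z[-m]))
    w <- c(w_half[-m], w_half[m], rev(w_half[-m]))
  }
  # z was computed in decreasing order; -z is increasing
  res <- list(x = x, w = w)
  .gauss_cache[[key]] <- res
  res
}

## nodes/weights rescaled to [a, b]
gauss_legendre <- function(n, a, b) {
  gl <- gauss_legendre_unit(n)
  list(x = (b - a) / 2 * gl$x + (a + b) / 2,
       w = (b - a) / 2 * gl$w)
}
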