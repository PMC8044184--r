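# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route (explicit 2^m enumeration, dense-grid
# integration) and share no code with the package's fast paths.

BASES4 <- c("A", "C", "G", "T")

# literal emission probability
oracle_emission <- function(b, x, q) if (b == x) 1 - q else q / 3

# pileup likelihood at fixed f, literal product over reads (no rho)
oracle_lik_given_f <- function(pileup, f, N, T) {
  out <- 1
  for (j in seq_len(nrow(pileup))) {
    b <- pileup$base[j]; q <- pileup$error_prob[j]
    out <- out * ((1 - f) * oracle_emission(b, N, q) + f * oracle_emission(b, T, q))
  }
  out
}

oracle_log_rho <- function(pileup, N, T) {
  d_n <- sum(pileup$base == N)
  d_t <- sum(pileup$base == T)
  d_e <- nrow(pileup) - d_n - d_t
  lfactorial(nrow(pileup)) - lfactorial(d_n) - lfactorial(d_t) - lfactorial(d_e)
}

# z = 0 likelihood, literal
oracle_log_p0 <- function(pileup, N, T) {
  if (nrow(pileup) == 0L) return(0)
  s <- 0
  for (j in seq_len(nrow(pileup))) {
    q <- pileup$error_prob[j]
    s <- s + if (pileup$base[j] == N) log(1 - q) else log(q / 3)
  }
  oracle_log_rho(pileup, N, T) + s
}

# z = 1 likelihood by trapezoid integration on a dense grid
oracle_log_p1 <- function(pileup, N, T, epsilon = 0.05, grid_n = 1e5) {
  if (nrow(pileup) == 0L) return(0)
  f <- seq(epsilon, 1, length.out = grid_n)
  logint <- vapply(f, function(ff) {
    eN <- ifelse(pileup$base == N, 1 - pileup$error_prob, pileup$error_prob / 3)
    eT <- ifelse(pileup$base == T, 1 - pileup$error_prob, pileup$error_prob / 3)
    sum(log((1 - ff) * eN + ff * eT))
  }, numeric(1))
  h <- f[2] - f[1]
  w <- rep(h, grid_n); w[c(1, grid_n)] <- h / 2
  m <- max(logint)
  oracle_log_rho(pileup, N, T) + m + log(sum(w * exp(logint - m))) - log(1 - epsilon)
}

# prior over an indicator vector under the uniform-over-nonzero scheme
oracle_prior_z <- function(z, mu) {
  m <- length(z)
  if (all(z == 0)) 1 - mu else mu / (2^m - 1)
}

# joint marginal over all 2^m indicator vectors, literal enumeration
oracle_joint_marginal <- function(log_p0, log_p1, mu) {
  m <- length(log_p0)
  total <- 0
  for (k in 0:(2^m - 1)) {
    z <- as.integer(intToBits(k))[seq_len(m)]
    total <- total + oracle_prior_z(z, mu) *
      prod(exp(ifelse(z == 1, log_p1, log_p0)))
  }
  log(total)
}

# full somatic posterior by enumeration + dense-grid integration
oracle_somatic_posterior <- function(cohort, N, mu, epsilon = 0.05, grid_n = 2e4) {
  keep <- vapply(cohort, function(p) nrow(p) > 0 && any(p$base != N), logical(1))
  cohort <- cohort[keep]
  if (length(cohort) == 0L) return(NULL)
  alts <- setdiff(BASES4, N)
  num <- 0; den <- 0
  for (T in alts) {
    lp0 <- vapply(cohort, oracle_log_p0, numeric(1), N = N, T = T)
    lp1 <- vapply(cohort, oracle_log_p1, numeric(1), N = N, T = T,
                  epsilon = epsilon, grid_n = grid_n)
    num <- num + (1 - mu) * prod(exp(lp0))
    den <- den + exp(oracle_joint_marginal(lp0, lp1, mu))
  }
  1 - num / den
}

# TIN posterior by enumeration over the 2^(m+1) extended indicator vectors
oracle_tin_posterior <- function(normal, cohort, N, T, mu, epsilon = 0.05,
                                 grid_n = 2e4) {
  all_p <- c(list(normal), cohort)
  lp0 <- vapply(all_p, oracle_log_p0, numeric(1), N = N, T = T)
  lp1 <- vapply(all_p, oracle_log_p1, numeric(1), N = N, T = T,
                epsilon = epsilon, grid_n = grid_n)
  m1 <- length(all_p)
  num <- 0; den <- 0
  for (k in 0:(2^m1 - 1)) {
    z <- as.integer(intToBits(k))[seq_len(m1)]
    term <- oracle_prior_z(z, mu) * prod(exp(ifelse(z == 1, lp1, lp0)))
    den <- den + term
    if (z[1] == 1) num <- num + term
  }
  -10 * log10(num / den)
}

# random pileup generator for property tests
random_pileup <- function(n, N, T, q_range = c(1e-4, 0.1)) {
  base <- sample(c(N, T, setdiff(BASES4, c(N, T))), n, replace = TRUE,
                 prob = c(0.6, 0.3, 0.05, 0.05))
  sample_pileup(base = base,
                error_prob = exp(runif(n, log(q_range[1]), log(q_range[2]))),
                forward_strand = runif(n) < 0.5,
                mapping_quality = rep(60L, n))
}

# uniform pileup of one base
flat_pileup <- function(base, n, q) {
  sample_pileup(rep(base, n), rep(q, n))
}

# mixed pileup: n_ref normal reads + n_alt tumor reads at one quality
two_allele_pileup <- function(N, T, n_ref, n_alt, q = 0.01) {
  sample_pileup(c(rep(N, n_ref), rep(T, n_alt)), rep(q, n_ref + n_alt),
                forward_strand = rep(c(TRUE, FALSE), length.out = n_ref + n_alt))
}
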