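## Core Bayesian model: per-sample pileup likelihoods under the somatic /
## non-somatic states, the linear-time joint marginal over sample-indicator
## vectors, the somatic posterior, tumor-allele estimation, and the
## tumor-in-normal (TIN) contamination score. Everything is log-space.

#' Base emission probability under the uniform sequencing-error model
#'
#' Probability of observing base `b` when the true (error-free) base is `x`
#' and the sequencing error probability is `q`. A sequencing error is
#' assumed unbiased across the three alternative bases, so the emission is
#' `1 - q` on a match and `q/3` otherwise.
#'
#' @param b observed base(s).
#' @param x true base(s).
#' @param q error probability(ies) in (0, 1).
#' @return numeric vector of emission probabilities.
#' @examples
#' base_emission("A", "A", 0.01)  # 0.99
#' base_emission("G", "A", 0.01)  # 0.01 / 3
#' @export
base_emission <- function(b, x, q) {
  assert_base(b, "observed base")
  assert_base(x, "true base")
  stopifnot(all(q > 0), all(q < 1))
  ifelse(b == x, 1 - q, q / 3)
}

#' Pileup likelihood at a fixed variant allele frequency
#'
#' Evaluates the product over reads of the frequency-mixture emission
#' `(1-f) P(b | x=N, q) + f P(b | x=T, q)`, i.e. the pileup likelihood
#' conditioned on the latent variant allele frequency `f`, excluding the
#' multinomial coefficient (applied separately so the same coefficient
#' multiplies both members of a likelihood pair). Reads whose base is
#' neither `N` nor `T` contribute a factor `q/3` independent of `f`.
#'
#' @param pileup a [sample_pileup()].
#' @param f variant allele frequency in \[0, 1\].
#' @param N,T normal and candidate tumor alleles, `N != T`.
#' @return the likelihood (probability scale).
#' @export
likelihood_given_f <- function(pileup, f, N, T) {
  assert_base(c(N, T))
  if (N == T) stop("tumor allele must differ from normal allele", call. = FALSE)
  stopifnot(f >= 0, f <= 1)
  if (nrow(pileup) == 0L) return(1)
  eN <- base_emission(pileup$base, N, pileup$error_prob)
  eT <- base_emission(pileup$base, T, pileup$error_prob)
  prod((1 - f) * eN + f * eT)
}

#' Log multinomial coefficient of an allele-count partition
#'
#' `log n! / (d_n! d_t! d_e!)` for a pileup of depth `n = d_n + d_t + d_e`,
#' computed with `lgamma` for stability at deep coverage.
#'
#' @param counts an [allele_counts()] list (or any list with `d_n`, `d_t`,
#'   `d_e`).
#' @return the log coefficient.
#' @export
log_multinomial_coeff <- function(counts) {
  d <- c(counts$d_n, counts$d_t, counts$d_e)
  stopifnot(all(d >= 0), all(d == round(d)))
  lgamma(sum(d) + 1) - sum(lgamma(d + 1))
}

## per-read emission pairs (towards N and towards T), aggregated into
## unique (eN, eT) groups with multiplicities -- the integrand only depends
## on reads through these pairs, and real pileups have few distinct
## quality values, so this collapses the O(n) product to O(#groups).
emission_groups <- function(pileup, N, T) {
  eN <- base_emission(pileup$base, N, pileup$error_prob)
  eT <- base_emission(pileup$base, T, pileup$error_prob)
  key <- paste(eN, eT)
  idx <- !duplicated(key)
  list(eN = eN[idx], eT = eT[idx],
       count = as.vector(table(factor(key, levels = key[idx]))))
}

#' Log likelihood of a pileup under the non-somatic state (z = 0)
#'
#' With no somatic SNV in the sample the latent frequency is pinned at 0,
#' so every read must be explained as normal allele or sequencing error:
#' the log likelihood is the log multinomial coefficient plus
#' `log(1-q)` for each normal-allele base and `log(q/3)` for every other
#' base. The coefficient is computed from the (N, T) count partition so the
#' identical coefficient enters the z = 1 likelihood.
#'
#' @inheritParams likelihood_given_f
#' @return log probability (0 for an empty pileup).
#' @export
log_likelihood_z0 <- function(pileup, N, T) {
  if (nrow(pileup) == 0L) return(0)
  log_rho <- log_multinomial_coeff(allele_counts(pileup, N, T))
  is_n <- pileup$base == N
  q <- pileup$error_prob
  log_rho + sum(ifelse(is_n, log1p(-q), log(q) - log(3)))
}

#' Log likelihood of a pileup under the somatic state (z = 1)
#'
#' Marginalizes the latent variant allele frequency over its truncated
#' uniform prior `f ~ U[epsilon, 1]`:
#' `rho * (1/(1-epsilon)) * int_epsilon^1 prod_j [(1-f) P(b_j|N,q_j) + f P(b_j|T,q_j)] df`.
#' The integrand is a polynomial in `f` of degree at most the pileup depth
#' `n`, so Gauss-Legendre quadrature of order `max(quad_order, (n+1)/2)`
#' (exact for degree `2*order - 1`) integrates it exactly up to roundoff.
#' The quadrature sum is accumulated in log space.
#'
#' @inheritParams likelihood_given_f
#' @param epsilon lower truncation of the frequency prior.
#' @param quad_order minimum quadrature order.
#' @return log probability (0 for an empty pileup).
#' @export
log_likelihood_z1 <- function(pileup, N, T, epsilon = 0.05, quad_order = 32L) {
  assert_base(c(N, T))
  if (N == T) stop("tumor allele must differ from normal allele", call. = FALSE)
  stopifnot(epsilon > 0, epsilon < 1)
  n <- nrow(pileup)
  if (n == 0L) return(0)
  log_rho <- log_multinomial_coeff(allele_counts(pileup, N, T))
  g <- emission_groups(pileup, N, T)
  order <- max(quad_order, ceiling((n + 1) / 2))
  gl <- gauss_legendre(order, epsilon, 1)
  ## log integrand at all nodes: sum_g count_g * log((1-f) eN_g + f eT_g)
  mix <- outer(1 - gl$x, g$eN) + outer(gl$x, g$eT)
  log_integrand <- as.vector(log(mix) %*% g$count)
  log_rho + logsumexp(log(gl$w) + log_integrand) - log1p(-epsilon)
}

#' Likelihood pairs for a cohort under one candidate tumor allele
#'
#' @param cohort list of [sample_pileup()]s.
#' @return a list with numeric vectors `log_p0`, `log_p1` (length m).
#' @keywords internal
likelihood_pairs <- function(cohort, N, T, params) {
  log_p0 <- vapply(cohort, log_likelihood_z0, numeric(1), N = N, T = T)
  log_p1 <- vapply(cohort, log_likelihood_z1, numeric(1), N = N, T = T,
                   epsilon = params$epsilon, quad_order = params$quad_order)
  list(log_p0 = unname(log_p0), log_p1 = unname(log_p1))
}

#' Joint marginal likelihood over all sample-indicator vectors
#'
#' Computes `log sum_z P(b | z) P(z)` where the prior puts mass `1 - mu` on
#' the all-zero indicator vector and spreads `mu` uniformly over the other
#' `2^m - 1` vectors. The exponential sum collapses to the linear-time form
#' `(1-mu) prod_i P0_i + mu/(2^m - 1) * (prod_i (P0_i + P1_i) - prod_i P0_i)`,
#' evaluated in log space; both terms are nonnegative so no signed
#' cancellation occurs.
#'
#' @param log_p0,log_p1 per-sample log likelihoods under z_i = 0 and 1.
#' @param mu prior somatic probability, `0 <= mu < 1`.
#' @return the log joint marginal.
#' @export
joint_marginal_over_z <- function(log_p0, log_p1, mu) {
  m <- length(log_p0)
  if (m == 0L) stop("at least one informative sample is required", call. = FALSE)
  stopifnot(length(log_p1) == m, mu >= 0, mu < 1)
  s0 <- sum(log_p0)
  s_both <- sum(pairwise_logsumexp(log_p0, log_p1))
  t_null <- log1p(-mu) + s0
  if (mu == 0) return(t_null)
  t_somatic <- log(mu) - log_2m_minus_1(m) + logdiffexp(s_both, s0)
  logsumexp(c(t_null, t_somatic))
}

#' Drop all-normal samples from a cohort
#'
#' Samples in which every quality-filtered base equals the normal allele
#' (including zero-depth samples) carry no somatic evidence, and retaining
#' many of them drives the joint posterior toward zero; they are omitted
#' before computing the posterior.
#'
#' @param cohort named list of [sample_pileup()]s.
#' @param N normal allele.
#' @return list with `retained` (sub-list, order preserved) and `omitted`
#'   (character vector of sample names).
#' @export
omit_all_normal_samples <- function(cohort, N) {
  assert_base(N)
  keep <- vapply(cohort, function(p) nrow(p) > 0L && any(p$base != N),
                 logical(1))
  list(retained = cohort[keep], omitted = names(cohort)[!keep])
}

#' Somatic posterior probability at a candidate locus
#'
#' Computes `P(Z != 0 | N, b, q)`, the posterior probability that at least
#' one tumor sample carries a somatic SNV at the locus, as one minus the
#' posterior of the all-zero indicator vector. The numerator of the
#' complement sums, over the three candidate tumor alleles `T != N`, the
#' z = 0 likelihood times the prior `1 - mu`; the denominator sums the
#' joint marginal over indicator vectors for the same three alleles.
#' All-normal samples are omitted first.
#'
#' @param cohort named list of [sample_pileup()]s (tumor samples).
#' @param N normal allele.
#' @param params a [model_params()].
#' @return `NULL` when every sample is all-normal (no call; the caller
#'   skips the locus). Otherwise a list with `somatic_prob`, the named
#'   per-allele log marginals `log_marginals` (reused for tumor-allele
#'   estimation), the per-allele likelihood `pairs`, the retained cohort
#'   and the omitted sample names.
#' @export
somatic_posterior <- function(cohort, N, params = model_params()) {
  assert_base(N)
  om <- omit_all_normal_samples(cohort, N)
  if (length(om$retained) == 0L) return(NULL)
  alts <- setdiff(BASES, N)
  pairs <- lapply(alts, function(T) likelihood_pairs(om$retained, N, T, params))
  names(pairs) <- alts
  log_num_T <- vapply(pairs, function(p) log1p(-params$mu) + sum(p$log_p0),
                      numeric(1))
  log_den_T <- vapply(pairs, function(p)
    joint_marginal_over_z(p$log_p0, p$log_p1, params$mu), numeric(1))
  log_complement <- logsumexp(log_num_T) - logsumexp(log_den_T)
  prob <- -expm1(log_complement)
  list(somatic_prob = min(max(prob, 0), 1),
       log_marginals = log_den_T,
       pairs = pairs,
       retained = om$retained,
       omitted = om$omitted)
}

#' Maximum-likelihood tumor allele
#'
#' Picks the allele `T != N` maximizing the joint marginal
#' `sum_z P(b | z, T, N, q) P(z)` — the same per-allele terms already
#' computed in the denominator of the somatic posterior. Exact ties break
#' lexicographically (A < C < G < T) for cross-platform determinism.
#'
#' @param log_marginals named numeric vector over the three alleles != N.
#' @param N normal allele.
#' @return the estimated tumor allele (single base).
#' @export
estimate_tumor_allele <- function(log_marginals, N) {
  alts <- setdiff(BASES, N)
  if (!setequal(names(log_marginals), alts)) {
    stop("log_marginals must cover exactly the three alleles different from N",
         call. = FALSE)
  }
  v <- log_marginals[alts]  # lexicographic order; which.max takes the first
  alts[which.max(v)]
}

#' Tumor-in-normal (TIN) contamination score
#'
#' Posterior probability that the *normal* sample itself carries the
#' inferred tumor allele, reported on the Phred scale
#' (`-10 log10 P(Z_0 = 1 | b_0, b, T, N, q)`). The normal sample is
#' prepended to the retained tumor cohort and the indicator-vector prior is
#' applied verbatim to the extended (m+1)-vector; the numerator restricts
#' the sum to vectors with `Z_0 = 1` (all nonzero, hence uniform prior
#' mass), giving `mu/(2^(m+1)-1) * P1_0 * prod_i (P0_i + P1_i)`.
#' Low scores mean the normal shows tumor-allele support (contamination or
#' a mis-identified normal allele); the default filter removes scores
#' below 20 (posterior > 0.01).
#'
#' @param normal the normal sample's [sample_pileup()].
#' @param cohort retained (non-omitted) tumor [sample_pileup()]s.
#' @param N,T normal and inferred tumor allele.
#' @param params a [model_params()].
#' @return nonnegative Phred score.
#' @export
tin_posterior <- function(normal, cohort, N, T, params = model_params()) {
  assert_base(c(N, T))
  if (N == T) stop("tumor allele must differ from normal allele", call. = FALSE)
  all_pileups <- c(list(normal), cohort)
  pr <- likelihood_pairs(all_pileups, N, T, params)
  m1 <- length(all_pileups)
  log_den <- joint_marginal_over_z(pr$log_p0, pr$log_p1, params$mu)
  tumor_both <- if (m1 > 1L) {
    sum(pairwise_logsumexp(pr$log_p0[-1], pr$log_p1[-1]))
  } else 0
  log_num <- log(params$mu) - log_2m_minus_1(m1) + pr$log_p1[1] + tumor_both
  post <- log_num - log_den   # log posterior of Z_0 = 1
  max(-10 / log(10) * post, 0)
}

#' Per-sample support vector for a called SNV
#'
#' After a joint call, each of the m tumor samples is marked supporting
#' iff (a) it retains at least one quality-filtered read carrying the
#' tumor allele and (b) its individual posterior
#' `P(z_i = 1 | b_i) = P1_i / (P0_i + P1_i)` (even per-sample prior odds)
#' exceeds 1/2, i.e. `P1_i > P0_i`. All-normal samples are never
#' supporting. The read-evidence condition keeps a sample with marginal
#' likelihood support but zero observed tumor bases from being reported.
#'
#' @param cohort named list over all m tumor samples.
#' @param N,T normal and called tumor alleles.
#' @param params a [model_params()].
#' @return integer 0/1 vector named by sample.
#' @export
per_sample_support <- function(cohort, N, T, params = model_params()) {
  vapply(cohort, function(p) {
    if (nrow(p) == 0L || !any(p$base == T)) return(0L)
    p0 <- log_likelihood_z0(p, N, T)
    p1 <- log_likelihood_z1(p, N, T, params$epsilon, params$quad_order)
    as.integer(p1 > p0)
  }, integer(1))
}
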