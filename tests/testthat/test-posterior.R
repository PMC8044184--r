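# Joint marginal, somatic posterior, tumor-allele estimation, sample
# omission, TIN score and the per-sample support rule.

test_that("linear-time joint marginal collapses correctly at m = 1", {
  for (mu in c(0, 0.1, 0.5, 0.999)) {
    lp0 <- log(0.3); lp1 <- log(0.8)
    expect_equal(exp(joint_marginal_over_z(lp0, lp1, mu)),
                 (1 - mu) * 0.3 + mu * 0.8, tolerance = 1e-12)
  }
})

test_that("joint marginal equals brute-force enumeration over indicator vectors", {
  set.seed(101)
  for (rep in 1:40) {
    m <- sample(1:12, 1)
    lp0 <- log(runif(m)); lp1 <- log(runif(m))
    mu <- runif(1, 0, 0.99)
    got <- joint_marginal_over_z(lp0, lp1, mu)
    want <- oracle_joint_marginal(lp0, lp1, mu)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("joint marginal handles the prior extremes", {
  lp0 <- log(c(0.2, 0.5)); lp1 <- log(c(0.9, 0.1))
  expect_equal(joint_marginal_over_z(lp0, lp1, 0), sum(lp0))
  # mu -> 1: all prior mass on nonzero vectors
  lim <- (prod(exp(lp0) + exp(lp1)) - prod(exp(lp0))) / 3
  expect_equal(exp(joint_marginal_over_z(lp0, lp1, 1 - 1e-12)), lim,
               tolerance = 1e-6)
  expect_error(joint_marginal_over_z(numeric(0), numeric(0), 0.1),
               "at least one")
})

test_that("somatic posterior is zero under a zero prior and bounded in [0,1]", {
  coh <- list(t1 = two_allele_pileup("A", "G", 20, 10))
  expect_equal(somatic_posterior(coh, "A", model_params(mu = 0))$somatic_prob, 0)
  set.seed(5)
  for (rep in 1:10) {
    coh <- list(t1 = random_pileup(30, "A", "G"), t2 = random_pileup(25, "A", "G"))
    pr <- somatic_posterior(coh, "A", model_params(mu = runif(1, 0, 0.9)))$somatic_prob
    expect_true(pr >= 0 && pr <= 1)
  }
})

test_that("somatic posterior matches full brute-force computation", {
  coh <- list(t1 = two_allele_pileup("A", "G", 20, 10),
              t2 = two_allele_pileup("A", "G", 20, 10))
  params <- model_params(mu = 1e-3)
  got <- somatic_posterior(coh, "A", params)$somatic_prob
  want <- oracle_somatic_posterior(coh, "A", mu = 1e-3)
  expect_gte(got, 0.99)
  expect_equal(got, want, tolerance = 1e-6)
  # and on a messier random cohort
  set.seed(77)
  coh2 <- list(t1 = random_pileup(15, "C", "T"), t2 = random_pileup(8, "C", "T"),
               t3 = random_pileup(22, "C", "T"))
  got2 <- somatic_posterior(coh2, "C", model_params(mu = 0.01))$somatic_prob
  want2 <- oracle_somatic_posterior(coh2, "C", mu = 0.01)
  if (!is.null(want2)) expect_equal(got2, want2, tolerance = 1e-5)
})

test_that("posterior is invariant under sample permutation", {
  set.seed(13)
  coh <- list(a = random_pileup(20, "A", "C"), b = random_pileup(30, "A", "C"),
              c = random_pileup(10, "A", "C"))
  p1 <- somatic_posterior(coh, "A")$somatic_prob
  p2 <- somatic_posterior(coh[c(3, 1, 2)], "A")$somatic_prob
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("all-normal samples are omitted and do not perturb the posterior", {
  om <- omit_all_normal_samples(
    list(s1 = sample_pileup(rep("A", 3), rep(0.01, 3)),
         s2 = sample_pileup(c("A", "T", "A"), rep(0.01, 3)),
         s3 = sample_pileup()), "A")
  expect_identical(names(om$retained), "s2")
  expect_setequal(om$omitted, c("s1", "s3"))

  coh <- list(t1 = two_allele_pileup("A", "T", 25, 5),
              t2 = two_allele_pileup("A", "T", 28, 2))
  base <- somatic_posterior(coh, "A")$somatic_prob
  with_an <- somatic_posterior(c(coh, list(t3 = flat_pileup("A", 40, 0.01))),
                               "A")$somatic_prob
  expect_equal(base, with_an, tolerance = 1e-12)
  # every sample all-normal: no call
  expect_null(somatic_posterior(list(t1 = flat_pileup("A", 10, 0.01)), "A"))
})

test_that("tumor allele estimation takes the argmax with lexicographic ties", {
  expect_identical(estimate_tumor_allele(c(C = -10, G = -5, T = -20), "A"), "G")
  expect_identical(estimate_tumor_allele(c(G = -5, C = -5, T = -20), "A"), "C")
  expect_error(estimate_tumor_allele(c(A = -1, C = -2, G = -3), "A"))
  # cohort where every non-N read is G with high quality
  coh <- list(t1 = two_allele_pileup("A", "G", 20, 8),
              t2 = two_allele_pileup("A", "G", 25, 6),
              t3 = two_allele_pileup("A", "G", 30, 4))
  res <- somatic_posterior(coh, "A")
  expect_identical(estimate_tumor_allele(res$log_marginals, "A"), "G")
})

test_that("TIN score discriminates clean from contaminated normals and matches enumeration", {
  params <- model_params(mu = 1e-3)
  cohort <- list(t1 = two_allele_pileup("A", "G", 15, 15))
  clean <- flat_pileup("A", 30, 0.01)
  contam <- two_allele_pileup("A", "G", 20, 10)
  tin_clean <- tin_posterior(clean, cohort, "A", "G", params)
  tin_contam <- tin_posterior(contam, cohort, "A", "G", params)
  expect_gt(tin_clean, 20)
  expect_lt(tin_contam, 20)
  expect_equal(tin_clean, oracle_tin_posterior(clean, cohort, "A", "G", 1e-3),
               tolerance = 1e-5)
  expect_equal(tin_contam, oracle_tin_posterior(contam, cohort, "A", "G", 1e-3),
               tolerance = 1e-4)
  # Phred mapping: posterior 0.01 <-> score 20
  expect_equal(-10 * log10(0.01), 20)
})

test_that("TIN score is invariant under tumor-sample permutation", {
  set.seed(19)
  cohort <- list(a = random_pileup(20, "A", "G"), b = random_pileup(15, "A", "G"))
  normal <- flat_pileup("A", 25, 0.01)
  expect_equal(tin_posterior(normal, cohort, "A", "G"),
               tin_posterior(normal, rev(cohort), "A", "G"), tolerance = 1e-12)
})

test_that("per-sample support requires both a T read and posterior evidence", {
  params <- model_params()
  coh <- list(
    none = flat_pileup("A", 20, 0.01),                    # all-normal
    strong = two_allele_pileup("A", "T", 10, 10),         # clear support
    lone = sample_pileup(c(rep("A", 50), "T"),
                         c(rep(0.001, 50), 0.2)))         # one noisy T read
  s <- per_sample_support(coh, "A", "T", params)
  expect_identical(unname(s), c(0L, 1L, 0L))
})

test_that("deep-coverage Monte-Carlo: shared VAF >= 0.1 is called, VAF 0 is not", {
  set.seed(2718)
  params <- model_params(mu = 1e-3)
  draw <- function(depth, vaf) {
    nt <- rbinom(1, depth, vaf * 0.99 + (1 - vaf) * 0.01 / 3)
    two_allele_pileup("A", "G", depth - nt, nt, q = 0.01)
  }
  fail_pos <- 0L; fail_neg <- 0L
  n_mc <- 500L
  for (i in seq_len(n_mc)) {
    coh <- list(t1 = draw(sample(60:100, 1), runif(1, 0.1, 0.5)),
                t2 = draw(sample(60:100, 1), runif(1, 0.1, 0.5)))
    res <- somatic_posterior(coh, "A", params)
    if (is.null(res) || res$somatic_prob <= 0.99) fail_pos <- fail_pos + 1L
    coh0 <- list(t1 = draw(60, 0), t2 = draw(70, 0))
    res0 <- somatic_posterior(coh0, "A", params)
    if (!is.null(res0) && res0$somatic_prob >= 0.01) fail_neg <- fail_neg + 1L
  }
  expect_lte(fail_pos / n_mc, 0.01)
  expect_lte(fail_neg / n_mc, 0.01)
})
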