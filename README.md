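# jointsnv

Joint multi-sample Bayesian somatic SNV calling for tumor cohorts with a
matched normal.

## The problem

When several samples from the same patient are sequenced — multi-region
biopsies, longitudinal samples, primary/relapse pairs — somatic
single-nucleotide variants (SNVs) are usually called one sample at a time
against the matched normal. Low-frequency variants (VAF ≲ 0.1) then sit
right at each caller's detection limit: a variant present in every sample
at 5 % support may be missed in *all* of them individually, even though
the evidence across samples is jointly overwhelming.

`jointsnv` is a second-pass caller. You run any single-sample somatic
caller under permissive settings, and `jointsnv` re-evaluates the union
of all nominated loci jointly across the m tumor samples, upgrading the
per-sample call sets into one aggregate multi-sample call set with higher
sensitivity at low VAF.

## The model

At a candidate locus with normal allele 𝒩, each sample *i* contributes a
quality-filtered pileup **b**ᵢ with per-base error probabilities **q**ᵢ.
A latent indicator zᵢ says whether sample *i* carries a somatic SNV with
tumor allele 𝒯 ≠ 𝒩; conditional on zᵢ = 1 the latent variant allele
frequency fᵢ is uniform on [ε, 1] (ε = 0.05), and conditional on zᵢ = 0
it is pinned at 0. Reads are error-free draws from {𝒩, 𝒯} at frequency
fᵢ, observed through a symmetric error channel: P(b | x, q) = 1 − q on a
match and q/3 otherwise.

The prior over the indicator vector **z** puts mass 1 − μ on **z** = **0**
and spreads μ uniformly over the 2ᵐ − 1 nonzero vectors (μ = 10⁻³ by
default). The reported *somatic probability* is

P(**Z** ≠ **0** | 𝒩, **b**, **q**) = 1 −
(Σ_{𝒯≠𝒩} P(**b** | **Z**=**0**, 𝒯, 𝒩, **q**) P(**Z**=**0**)) /
(Σ_{𝒯≠𝒩} Σ_{**z**} P(**b** | **z**, 𝒯, 𝒩, **q**) P(**z**)),

where the exponential sum over **z** collapses, under this prior, to a
closed form linear in m. The tumor allele 𝒯\* is the maximizer of the
per-allele joint marginal (already computed in the denominator). A
Phred-scaled *TIN score* −10·log₁₀ P(Z₀ = 1 | …) — the posterior that the
*normal* sample itself carries 𝒯\* — flags tumor-in-normal contamination,
and empirical filters (normal depth < 6, tumor-allele count < 4 in all
samples, single-strand support, ≥ 3 SNVs within 100 bp) flag common
artifacts. By default these filters remove only variants the original
caller never accepted; when only one tumor sample has variant reads, the
call defers to the original caller's decision.

## Worked example

Three tumor samples share a low-frequency A→G variant (8/60, 4/60 and
3/60 supporting reads at base quality Q20); the matched normal is clean:

```r
library(jointsnv)

normal <- sample_pileup(rep("A", 40), rep(0.01, 40), sample_id = "normal")
cohort <- list(
  t1 = sample_pileup(c(rep("A", 52), rep("G", 8)), rep(0.01, 60), sample_id = "t1"),
  t2 = sample_pileup(c(rep("A", 56), rep("G", 4)), rep(0.01, 60), sample_id = "t2"),
  t3 = sample_pileup(c(rep("A", 57), rep("G", 3)), rep(0.01, 60), sample_id = "t3"))

params <- model_params(mu = 1e-3)
res    <- somatic_posterior(cohort, N = "A", params)
Tstar  <- estimate_tumor_allele(res$log_marginals, N = "A")
tin    <- tin_posterior(normal, res$retained, N = "A", T = Tstar, params)

somatic_posterior(cohort["t3"], "A", params)$somatic_prob
#> [1] 0.003169
res$somatic_prob
#> [1] 1
Tstar
#> [1] "G"
tin
#> [1] 25.01
```

Sample t3 alone (3/60 reads) is far below any calling threshold — its
posterior is 0.003 — but the three samples jointly give somatic
probability ≈ 1. The TIN score of 25 (> 20) says the normal shows no
evidence of carrying the G allele, so the call stands.

The same computation runs from files via the bundled command line tool:

```sh
Rscript inst/scripts/jointsnv call \
  --normal normal.bam --tumor t1.bam,t2.bam,t3.bam \
  --candidates t1.vcf,t2.vcf,t3.vcf --output calls.vcf
```

and `jointsnv simulate` / `jointsnv bench-pr` generate synthetic cohorts
and precision-recall curves. The output VCF carries `PROB`, `TIN` and
`NSUP` INFO fields and per-sample `TCOUNT:DP:SB:ZS` genotype fields.

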