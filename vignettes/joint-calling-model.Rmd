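---
title: "The joint multi-sample somatic calling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The joint multi-sample somatic calling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointsnv)
```

# Scope and assumptions

`jointsnv` re-evaluates candidate somatic SNV loci jointly across the m
tumor samples of one patient, given a matched normal. It is a second-pass
tool: candidate loci come from any single-sample caller run permissively,
and the package's job is to turn per-sample evidence that is individually
weak into a joint decision.

Modeling assumptions, all deliberate simplifications:

* the normal sample is homozygous at each considered locus (heterozygous
  sites are out of scope), so a single normal allele 𝒩 describes it;
* at most one tumor allele 𝒯 ≠ 𝒩 per locus — multi-allelic somatic sites
  are not modeled;
* SNVs only; indels, structural variants and copy-number state are out of
  scope, and the variant allele frequency prior does not attempt to model
  copy-number-driven VAF distortions;
* loci are independent; reads are independent given the latent genotype.

# The generative model

At one locus, sample i contributes nᵢ quality-filtered reads with
observed bases bᵢⱼ and error probabilities qᵢⱼ (from the Phred base
qualities). Latent variables: the binary somatic indicator zᵢ, the
variant allele frequency fᵢ, and per-read error-free bases
xᵢⱼ ∈ {𝒩, 𝒯}.

* xᵢⱼ is 𝒯 with probability fᵢ, else 𝒩;
* the error channel is symmetric: P(b | x, q) = 1 − q if b = x, else q/3
  (an error is equally likely to produce each of the three other bases);
* fᵢ | zᵢ = 1 ~ Uniform[ε, 1] with ε = 0.05 — below 5 % the frequency
  prior deliberately carries no mass, which keeps isolated error reads
  from masquerading as ultra-low-frequency variants;
* fᵢ | zᵢ = 0 is a point mass at 0, so every read must be explained as
  normal allele or sequencing error;
* the indicator vector prior is P(**z** = **0**) = 1 − μ and
  μ/(2ᵐ − 1) for each nonzero vector. μ is the prior probability that a
  candidate locus is somatic in at least one sample.

The per-sample likelihood under zᵢ = 1 marginalizes fᵢ:

P(bᵢ | zᵢ=1) = ρᵢ · (1/(1−ε)) ∫_ε^1 ∏ⱼ [(1−f)·P(bᵢⱼ|𝒩,qᵢⱼ) + f·P(bᵢⱼ|𝒯,qᵢⱼ)] df,

where ρᵢ is the multinomial coefficient of the (d_n, d_t, d_e) count
partition. ρᵢ depends on 𝒯 through the partition and does **not** cancel
across the sum over candidate tumor alleles in the posterior, so it is
computed per (sample, allele) and included identically in both the z = 0
and z = 1 likelihoods.

The somatic probability is one minus the posterior of **z** = **0**,
summing over the three candidate alleles 𝒯 ≠ 𝒩 in both numerator and
denominator; the tumor allele estimate 𝒯* is the argmax over the three
per-allele joint marginals already computed in the denominator, with
exact ties broken lexicographically (A < C < G < T) for determinism.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mu` | 1e-3 | prior somatic probability per candidate locus |
| `epsilon` | 0.05 | lower truncation of the VAF prior under z = 1 |
| `call_threshold` | 0.5 | posterior needed to emit a novel call |
| `tin_threshold` | 20 | Phred TIN score below which a call is flagged |
| `mapq_min` | 30 | minimum read mapping quality in pileups |
| `baseq_min` | 13 | minimum base Phred quality in pileups |
| `quad_order` | 32 | minimum Gauss–Legendre order for the VAF integral |

The default μ reflects that candidate loci are pre-enriched by a
permissive caller: most candidates are still errors, so a small prior is
appropriate; 10⁻³ also matches the per-locus mutation probability used by
the bundled simulator. μ is fully exposed — cohorts with very different
candidate purity may want other values. The quality thresholds (MAPQ 30,
baseQ 13, both strict "below" semantics) follow common somatic-calling
practice.

# Numerical choices

Everything runs in log space; no likelihood is ever exponentiated before
it is combined.

* **The VAF integral.** The integrand is a polynomial in f of degree at
  most nᵢ, so Gauss–Legendre quadrature on [ε, 1] of order
  max(32, ⌈(nᵢ+1)/2⌉) integrates it *exactly* up to roundoff (order k is
  exact through degree 2k − 1). Nodes are computed by Newton iteration on
  the Legendre recurrence and cached per order. The quadrature sum is
  accumulated with log-sum-exp; unit tests pin it against 10⁵-point
  trapezoid integration (relative error ≤ 10⁻⁸) and the node tables
  against an independent CRAN implementation.
* **The joint marginal.** The 2ᵐ-term sum over indicator vectors is
  evaluated in the algebraically equivalent two-term form
  (1−μ)·∏P0ᵢ + [μ/(2ᵐ−1)]·(∏(P0ᵢ+P1ᵢ) − ∏P0ᵢ). Both terms are
  nonnegative, which avoids the signed cancellation the more obvious
  rearrangement suffers when μ is large; 2ᵐ never appears outside a
  `log1p`, so m is unbounded in practice. Unit tests verify equality with
  explicit enumeration for m ≤ 12 at relative error 10⁻¹⁰.
* **Error probabilities** are clamped to [10⁻¹⁰, 0.75]: Phred 0 and
  q ≥ 3/4 carry no information under the symmetric error channel, and
  q = 0 is degenerate in log space. A pileup in which every read has
  q = 0.75 makes P0 = P1 exactly — the posterior falls back to the prior.
* **Degenerate inputs.** Empty pileups have likelihood 1 under both
  states. Samples whose filtered reads are all 𝒩 (including empty ones)
  are omitted before the posterior — retaining many of them drives the
  joint posterior toward 0 — and a locus where *every* sample is omitted
  produces no record at all rather than a probability-0 record.

# The TIN score and the filters

The tumor-in-normal score treats the normal sample as an (m+1)-th member
of the cohort: the indicator-vector prior is applied verbatim to the
extended (Z₀, z) vector, and the score is −10·log₁₀ P(Z₀ = 1 | data).
The prior over the extended vector is a design choice (the score needs a
joint prior on (Z₀, **z**), and reusing the same uniform-over-nonzero
form is the least-surprising one); the code isolates it so it can be
swapped. A threshold of 20 corresponds to posterior 0.01. Note the score
is sensitive: a single tumor-allele error read in a deep normal pileup
can pull the score below 20. This is intentional — at such loci the
normal genuinely fails to rule out contamination — and it only affects
calls the original caller never accepted (see below).

The empirical filters flag: normal depth < 6; tumor-allele count < 4 in
*all* samples; one strand with zero tumor-allele reads across all
samples (the "either strand empty everywhere" reading); and ≥ 3 called
sites within a 100 bp span (span = max pos − min pos ≤ 100, inclusive,
all members flagged — the window semantics are pinned by tests at spans
99, 100 and 101). Flags always annotate; by default (`filter_mode =
"novel"`) a flagged record is *removed* only when no sample's original
caller accepted the locus, so previously accepted calls are never lost
to a flag. When only one tumor sample has tumor-allele reads the joint
model adds nothing over the original caller, and the call defers to the
original caller's decision.

Two under-specified behaviors are this package's own documented choices:

* **Per-sample support.** A sample is reported as supporting a call iff
  it has at least one quality-filtered tumor-allele read *and* its
  individual posterior with even prior odds exceeds ½ (P1ᵢ > P0ᵢ). The
  read-evidence condition keeps zero-read samples out; the posterior
  condition keeps a lone noisy read from counting as support.
* **Caller acceptance.** A locus counts as "originally called" in a
  sample iff that sample's candidate VCF record has FILTER `PASS`;
  missing FILTER (".") is treated as not accepted.

# The synthetic cohort generator

The generator emulates the structure joint calling is designed for: a
linear phylogeny of tumor clones (each clone inherits its ancestors'
mutations), per-sample clone prevalences, and per-locus truth VAFs
= (prevalence of carrying clones)/2 for heterozygous mutations. The
default design — five bulk samples over four clones, see
`default_mixture()` — gives per-clone VAF profiles spanning 0.5 down to
0.05, with the deepest clone (VAF 0.05–0.10 in every sample) forming the
stratum where single-sample calling degrades but joint calling does not.
Defaults: 1000 candidate loci of which 500 are true SNVs, mean depth 60,
mean error rate 0.01 (Phred qualities drawn from {Q₀−10, Q₀, Q₀+10} with
probabilities 0.1/0.6/0.3 around Q₀ = 20), pseudo-caller false-nomination
rate 0.1, clean normal. These values were fixed as the package's study
conditions before any end-to-end measurement and are not tuned.

Reads are emitted as minimal single-base SAM records with correct flags,
MAPQ and base qualities — enough to exercise the BAM pileup path
bit-exactly (a test asserts the SAM round trip reproduces the
generator's filtered pileups). What the generator does **not** model:
read fragments and mate pairs, alignment and mapping artifacts,
copy-number aberrations, strand bias, error-rate heterogeneity along
reads. Passing end-to-end tests on this generator therefore demonstrates
the statistical machinery (posterior, allele estimation, filters,
plumbing), not robustness to real-data artifacts — the empirical filters
in particular are exercised for correctness of their definitions, not
for their real-world yield.

The permissive pseudo-caller (nominate at ≥ 2 non-reference reads; PASS
at ≥ 4 ALT reads and ALT fraction ≥ 0.1) is an invented stand-in that
makes the defer rule and novel-only filtering exercisable; its
thresholds are not claims about any real caller.

# Problem sizes and observed behavior

The end-to-end test and `scripts/acceptance.R` run the default cohort
(1000 loci × 6 samples × depth 60) — small enough to re-run in about a
minute yet large enough for stable metrics. On it, the pipeline at
threshold 0.5 reaches recall ≈ 0.97 and precision 1.0, and on the
VAF < 0.15 stratum roughly 0.89 recall versus 0.60 for the
pseudo-caller's PASS union — the qualitative gain joint calling exists
for. (Numbers vary by ~1–2 points across seeds; the acceptance script
recomputes them from scratch.)

One boundary behavior worth knowing: at exactly VAF 0.1 and depth 60
with only two samples, a binomial downdraw to ~2 supporting reads
legitimately yields a posterior below 0.99 in a percent or two of loci —
the ε-truncated VAF prior penalizes sub-5 % support. Across the broader
VAF ≥ 0.1 class the >0.99-confidence rate exceeds 99 %.

# Known limitations

* Heterozygous normal loci and multi-allelic tumor sites are rejected by
  assumption, not detected; upstream callers' heterozygous-site handling
  is trusted.
* The realigned-BAM merge replaces reads by (query name, mate) key among
  reads fetched over the candidate loci; a realigned read relocated
  entirely away from every candidate region cannot veto its original.
* Overlapping mate pairs are counted twice by default (`mate_overlap =
  "both"`); switch to `"highest"` to keep only the better base per
  fragment. Which convention real tools use varies.
* The candidate extractor records but ignores the nominating callers'
  ALT alleles; the model re-estimates the tumor allele from the reads.
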