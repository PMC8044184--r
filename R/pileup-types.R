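#' Construct a per-sample pileup at one locus
#'
#' A pileup is the set of quality-filtered read observations one sample
#' contributes at a candidate locus: for each read, the observed base, its
#' sequencing error probability (from the Phred base quality), the strand,
#' and the read's mapping quality. This is the unit the likelihood model
#' consumes; a zero-read pileup is valid and is treated as an all-normal
#' sample by the omission rule.
#'
#' @param base character vector of observed bases, each one of A/C/G/T.
#' @param error_prob numeric vector of sequencing error probabilities in
#'   (0, 1); use [phred_to_error_prob()] to convert Phred scores.
#' @param forward_strand logical vector; `TRUE` for reads on the forward
#'   strand.
#' @param mapping_quality integer vector of Phred-scaled mapping qualities.
#' @param sample_id sample identifier attached as an attribute.
#' @return a `sample_pileup`: a data frame with columns `base`, `error_prob`,
#'   `forward_strand`, `mapping_quality`.
#' @examples
#' sample_pileup(c("A", "G"), c(0.01, 0.001), c(TRUE, FALSE), c(60, 60), "t1")
#' @export
sample_pileup <- function(base = character(), error_prob = numeric(),
                          forward_strand = rep(TRUE, length(base)),
                          mapping_quality = rep(60L, length(base)),
                          sample_id = NA_character_) {
  assert_base(base, "pileup base")
  stopifnot(length(error_prob) == length(base),
            length(forward_strand) == length(base),
            length(mapping_quality) == length(base))
  if (any(error_prob <= 0 | error_prob >= 1)) {
    stop("error_prob must lie strictly in (0, 1); clamp Phred extremes with phred_to_error_prob()",
         call. = FALSE)
  }
  out <- data.frame(base = as.character(base),
                    error_prob = as.numeric(error_prob),
                    forward_strand = as.logical(forward_strand),
                    mapping_quality = as.integer(mapping_quality),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("sample_pileup", "data.frame")
  out
}

pileup_depth <- function(pileup) nrow(pileup)

#' Partition a pileup into normal / tumor / error base counts
#'
#' Counts observations equal to the normal allele (`d_n`), the candidate
#' tumor allele (`d_t`), and neither (`d_e`, "error bases"), plus the
#' strand split of the tumor-allele reads. `d_n + d_t + d_e` equals the
#' pileup depth.
#'
#' @param pileup a [sample_pileup()].
#' @param N,T normal and candidate tumor allele (single bases, `N != T`).
#' @return list with integer fields `d_n`, `d_t`, `d_e`, `fwd_t`, `rev_t`.
#' @export
allele_counts <- function(pileup, N, T) {
  assert_base(c(N, T))
  if (N == T) stop("tumor allele must differ from normal allele", call. = FALSE)
  is_t <- pileup$base == T
  list(d_n = sum(pileup$base == N),
       d_t = sum(is_t),
       d_e = sum(pileup$base != N & !is_t),
       fwd_t = sum(is_t & pileup$forward_strand),
       rev_t = sum(is_t & !pileup$forward_strand))
}

#' Model parameters for joint somatic calling
#'
#' @param mu prior probability that a locus carries a somatic SNV in at
#'   least one sample. Candidate loci are pre-enriched by a permissive
#'   single-sample caller, so the default is deliberately small.
#' @param epsilon lower truncation of the uniform prior on the latent
#'   variant allele frequency under the somatic state (f ~ U\[epsilon, 1\]).
#' @param call_threshold posterior cutoff for emitting a call.
#' @param tin_threshold Phred cutoff for the tumor-in-normal filter; scores
#'   below it flag likely contamination (20 corresponds to posterior 0.01).
#' @param mapq_min minimum read mapping quality retained in pileups.
#' @param baseq_min minimum base Phred quality retained in pileups.
#' @param quad_order minimum Gauss-Legendre order for the frequency
#'   integral; the effective order grows with pileup depth so the
#'   polynomial integrand is integrated exactly.
#' @param count_duplicates keep duplicate-flagged reads in pileups.
#' @param mate_overlap `"both"` counts both mates of an overlapping pair
#'   independently; `"highest"` keeps only the higher-base-quality mate.
#' @param filter_mode `"novel"` removes flagged records only when no
#'   original caller accepted the locus (flags annotate the rest), `"all"`
#'   removes every flagged record, `"off"` annotates only.
#' @return a `model_params` list.
#' @export
model_params <- function(mu = 1e-3, epsilon = 0.05, call_threshold = 0.5,
                         tin_threshold = 20, mapq_min = 30L, baseq_min = 13L,
                         quad_order = 32L, count_duplicates = FALSE,
                         mate_overlap = c("both", "highest"),
                         filter_mode = c("novel", "all", "off")) {
  stopifnot(mu >= 0, mu < 1, epsilon > 0, epsilon < 1)
  p <- list(mu = mu, epsilon = epsilon, call_threshold = call_threshold,
            tin_threshold = tin_threshold, mapq_min = as.integer(mapq_min),
            baseq_min = as.integer(baseq_min), quad_order = as.integer(quad_order),
            count_duplicates = isTRUE(count_duplicates),
            mate_overlap = match.arg(mate_overlap),
            filter_mode = match.arg(filter_mode))
  class(p) <- "model_params"
  p
}
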