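## Synthetic multi-sample cohorts with clonal mixture structure: a linear
## phylogeny of tumor clones, per-sample clone prevalences, per-locus VAFs,
## Phred-scored read observations, SAM/VCF fixture output, a permissive
## pseudo-caller, and a precision-recall benchmark harness. Everything is
## reproducible from the cohort-spec seed.

#' Default clone-prevalence mixture
#'
#' Five bulk tumor samples over a normal clone and four tumor clones on a
#' linear phylogeny (each clone inherits its ancestors' mutations). Rows
#' sum to 1. The cumulative descendant prevalences put every mutation at
#' VAF >= 0.05 in every sample, with the deepest clone forming a
#' low-frequency stratum (VAF 0.05-0.10) that single-sample calling
#' struggles with but joint calling recovers.
#'
#' @return a 5 x 5 matrix (samples x clones, first column the normal clone).
#' @export
default_mixture <- function() {
  m <- rbind(
    c(0.0, 0.4, 0.3, 0.2, 0.1),
    c(0.2, 0.3, 0.3, 0.1, 0.1),
    c(0.1, 0.5, 0.1, 0.1, 0.2),
    c(0.3, 0.1, 0.4, 0.1, 0.1),
    c(0.0, 0.2, 0.4, 0.3, 0.1))
  dimnames(m) <- list(paste0("tumor", 1:5), c("normal", paste0("clone", 1:4)))
  m
}

#' Specification of a synthetic clone-mixture cohort
#'
#' @param n_loci total candidate loci (true SNVs plus non-variant loci).
#' @param n_true number of true somatic SNVs, assigned round-robin to the
#'   clones of a linear phylogeny.
#' @param mixture samples x clones prevalence matrix (first column the
#'   normal clone); rows must sum to 1.
#' @param depth_mean expected per-sample coverage (Poisson).
#' @param error_rate mean sequencing error probability; per-read Phred
#'   qualities are drawn from \{Q0-10, Q0, Q0+10\} with probabilities
#'   (0.1, 0.6, 0.3), where `Q0 = -10 log10(error_rate)`.
#' @param fp_rate probability that a non-variant locus is nominated by the
#'   permissive pseudo-caller despite lacking read support.
#' @param contamination tumor-in-normal contamination: VAF of each true
#'   SNV in the matched normal sample (0 = clean normal).
#' @param region_len length of the simulated contig (`chr1`).
#' @param seed RNG seed; all downstream draws derive from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_loci = 1000L, n_true = 500L,
                        mixture = default_mixture(), depth_mean = 60,
                        error_rate = 0.01, fp_rate = 0.1, contamination = 0,
                        region_len = 1e7, seed = 1L) {
  stopifnot(n_true <= n_loci, depth_mean > 0,
            error_rate > 0, error_rate < 1,
            fp_rate >= 0, fp_rate <= 1,
            contamination >= 0, contamination <= 0.5)
  if (any(abs(rowSums(mixture) - 1) > 1e-8) || any(mixture < 0)) {
    stop("mixture rows must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(n_loci = as.integer(n_loci), n_true = as.integer(n_true),
                 mixture = mixture, depth_mean = depth_mean,
                 error_rate = error_rate, fp_rate = fp_rate,
                 contamination = contamination, region_len = region_len,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Phred quality distribution centered on the requested mean error rate
draw_phred <- function(n, error_rate) {
  q0 <- round(-10 * log10(error_rate))
  sample(c(q0 - 10L, q0, q0 + 10L), n, replace = TRUE,
         prob = c(0.1, 0.6, 0.3))
}

## draw one locus' reads for one sample; returns a data.frame of raw reads
draw_reads <- function(depth, vaf, N, T, error_rate) {
  if (depth == 0L) {
    return(data.frame(base = character(), phred = integer(),
                      strand = logical(), mapq = integer(),
                      stringsAsFactors = FALSE))
  }
  true_base <- ifelse(stats::runif(depth) < vaf, T, N)
  phred <- draw_phred(depth, error_rate)
  q <- 10^(-phred / 10)
  err <- stats::runif(depth) < q
  obs <- true_base
  if (any(err)) {
    obs[err] <- vapply(true_base[err],
                       function(b) sample(setdiff(BASES, b), 1L), character(1))
  }
  data.frame(base = obs, phred = phred,
             strand = stats::runif(depth) < 0.5,
             mapq = ifelse(stats::runif(depth) < 0.97, 60L, 20L),
             stringsAsFactors = FALSE)
}

## quality-filtered sample_pileup from a raw read table
pileup_from_reads <- function(reads, params, sample_id) {
  keep <- reads$mapq >= params$mapq_min & reads$phred >= params$baseq_min
  r <- reads[keep, , drop = FALSE]
  sample_pileup(base = r$base, error_prob = phred_to_error_prob(r$phred),
                forward_strand = r$strand, mapping_quality = r$mapq,
                sample_id = sample_id)
}

#' Simulate a multi-sample tumor/normal cohort
#'
#' Generates candidate loci on one contig, assigns true SNVs to the clones
#' of a linear phylogeny, computes per-sample truth VAFs from the clone
#' prevalences (heterozygous mutations: VAF = prevalence sum / 2), and
#' draws per-read observations: depth ~ Poisson, true base ~
#' Bernoulli(VAF), sequencing errors at the Phred-implied rate landing
#' uniformly on the three other bases, strand ~ Bernoulli(1/2). The
#' matched normal draws from VAF `contamination` at true loci. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param params a [model_params()]; its quality thresholds define the
#'   filtered pileups returned alongside the raw reads.
#' @return a `sim_cohort` list: `truth` (locus table with per-sample truth
#'   VAF columns `vaf.<sample>`), `reads` (raw per-read tables by sample,
#'   then locus), `pileups` (quality-filtered [sample_pileup()]s by
#'   sample, then locus; first sample `"normal"`), and the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), params = model_params()) {
  set.seed(spec$seed)
  n_clones <- ncol(spec$mixture) - 1L
  samples <- rownames(spec$mixture)
  if (is.null(samples)) samples <- paste0("tumor", seq_len(nrow(spec$mixture)))
  pos <- sort(sample.int(spec$region_len, spec$n_loci))
  N <- sample(BASES, spec$n_loci, replace = TRUE)
  T <- vapply(N, function(b) sample(setdiff(BASES, b), 1L), character(1))
  is_snv <- seq_len(spec$n_loci) %in% sample.int(spec$n_loci, spec$n_true)
  clone <- integer(spec$n_loci)
  clone[is_snv] <- rep_len(seq_len(n_clones), spec$n_true)
  ## linear phylogeny: a clone-k mutation is present in clones k..K
  vaf <- matrix(0, spec$n_loci, length(samples),
                dimnames = list(NULL, samples))
  for (s in seq_along(samples)) {
    desc <- rev(cumsum(rev(spec$mixture[s, -1L])))  # descendant prevalence
    vaf[is_snv, s] <- desc[clone[is_snv]] / 2
  }
  truth <- data.frame(chrom = "chr1", pos = pos, normal_allele = N,
                      tumor_allele = T, is_snv = is_snv, clone = clone,
                      stringsAsFactors = FALSE)
  for (s in samples) truth[[paste0("vaf.", s)]] <- vaf[, s]

  all_samples <- c("normal", samples)
  reads <- list()
  pileups <- list()
  for (s in all_samples) {
    sv <- if (s == "normal") ifelse(is_snv, spec$contamination, 0) else vaf[, s]
    depth <- stats::rpois(spec$n_loci, spec$depth_mean)
    rl <- lapply(seq_len(spec$n_loci), function(i)
      draw_reads(depth[i], sv[i], N[i], T[i], spec$error_rate))
    reads[[s]] <- rl
    pileups[[s]] <- lapply(rl, pileup_from_reads, params = params, sample_id = s)
  }
  structure(list(truth = truth, reads = reads, pileups = pileups, spec = spec),
            class = "sim_cohort")
}

#' Emulate a permissive single-sample caller on a simulated cohort
#'
#' A deliberately simple stand-in for running a real single-sample somatic
#' caller under permissive settings (it makes no claims about any specific
#' tool): a tumor sample nominates a locus iff its quality-filtered pileup
#' holds at least 2 non-reference reads, taking the most frequent
#' non-reference base as ALT (ties break lexicographically); additionally,
#' each non-variant locus is nominated with probability `fp_rate` with a
#' random ALT, emulating error-driven false candidates. A nominated record
#' gets FILTER `PASS` iff it has at least 4 ALT reads and ALT fraction
#' >= 0.1; otherwise FILTER `permissive`.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @return named list (one per tumor sample) of data frames with columns
#'   `chrom`, `pos`, `ref`, `alt`, `filter`.
#' @export
emulate_permissive_caller <- function(cohort) {
  spec <- cohort$spec
  set.seed(spec$seed + 777L)   # independent stream, still seed-derived
  truth <- cohort$truth
  samples <- setdiff(names(cohort$pileups), "normal")
  out <- list()
  for (s in samples) {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      p <- cohort$pileups[[s]][[i]]
      nonref <- p$base[p$base != truth$normal_allele[i]]
      if (length(nonref) >= 2L) {
        tab <- table(factor(nonref, levels = BASES))
        alt <- BASES[which.max(tab)]
        nalt <- sum(nonref == alt)
        pass <- nalt >= 4L && nalt / max(nrow(p), 1L) >= 0.1
        return(data.frame(chrom = truth$chrom[i], pos = truth$pos[i],
                          ref = truth$normal_allele[i], alt = alt,
                          filter = if (pass) "PASS" else "permissive",
                          stringsAsFactors = FALSE))
      }
      if (!truth$is_snv[i] && stats::runif(1) < spec$fp_rate) {
        return(data.frame(chrom = truth$chrom[i], pos = truth$pos[i],
                          ref = truth$normal_allele[i],
                          alt = sample(setdiff(BASES, truth$normal_allele[i]), 1L),
                          filter = "permissive", stringsAsFactors = FALSE))
      }
      NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out[[s]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), filter = character(),
                 stringsAsFactors = FALSE)
  }
  out
}

#' Write per-sample candidate VCFs for a pseudo-caller result
#'
#' @param candidates output of [emulate_permissive_caller()].
#' @param dir output directory (created if needed).
#' @param region_len contig length declared in the header.
#' @return named character vector of file paths.
#' @export
write_candidate_vcfs <- function(candidates, dir, region_len = 1e7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in names(candidates)) {
    path <- file.path(dir, paste0(s, ".candidates.vcf"))
    d <- candidates[[s]]
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=chr1,length=%d>", as.integer(region_len)),
             "##FILTER=<ID=permissive,Description=\"Nominated under permissive settings only\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
    body <- if (nrow(d)) sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.",
                                 d$chrom, d$pos, d$ref, d$alt, d$filter)
            else character(0)
    writeLines(c(hdr, body), path)
    paths[s] <- path
  }
  paths
}

#' Write a simulated sample as a coordinate-sorted SAM file
#'
#' Each read observation becomes a minimal single-base alignment record
#' (CIGAR `1M`) with the correct strand flag, MAPQ, and base quality —
#' enough to exercise the BAM pileup path bit-exactly without modeling
#' read fragments.
#'
#' @param cohort a `sim_cohort`.
#' @param sample sample name (`"normal"` or a tumor sample).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sample_sam <- function(cohort, sample, path) {
  truth <- cohort$truth
  rl <- cohort$reads[[sample]]
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:chr1\tLN:%d", as.integer(cohort$spec$region_len)))
  body <- lapply(seq_len(nrow(truth)), function(i) {
    r <- rl[[i]]
    if (nrow(r) == 0L) return(character(0))
    sprintf("%s\t%d\tchr1\t%d\t%d\t1M\t*\t0\t0\t%s\t%s",
            sprintf("%s_L%05d_%03d", sample, i, seq_len(nrow(r))),
            ifelse(r$strand, 0L, 16L), truth$pos[i], r$mapq,
            r$base, intToUtf8(r$phred + 33L, multiple = TRUE))
  })
  writeLines(c(lines, unlist(body)), path)
  invisible(path)
}

#' Precision-recall curve over the somatic-probability threshold
#'
#' Sweeps the call threshold over every observed probability and reports
#' precision, recall and F1 at each. Recall is computed against the full
#' truth set (`n_true`), so true SNVs never nominated as candidates count
#' as false negatives.
#'
#' @param prob numeric vector of per-call somatic probabilities.
#' @param is_true logical vector: is each call a true SNV?
#' @param n_true total number of true SNVs in the truth set.
#' @return data frame with columns `threshold`, `precision`, `recall`,
#'   `f1`, ordered by increasing threshold.
#' @export
pr_curve <- function(prob, is_true, n_true) {
  stopifnot(length(prob) == length(is_true), n_true >= 0)
  if (length(prob) == 0L) {
    return(data.frame(threshold = numeric(), precision = numeric(),
                      recall = numeric(), f1 = numeric()))
  }
  thresholds <- sort(unique(prob))
  rows <- lapply(thresholds, function(t) {
    called <- prob >= t
    tp <- sum(called & is_true)
    fp <- sum(called & !is_true)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 1
    recall <- if (n_true > 0) tp / n_true else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(threshold = t, precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, rows)
}
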