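## End-to-end driver: candidate loci -> pileups -> joint posterior ->
## tumor allele -> defer rule -> support + TIN -> filters -> output VCF.
## call_somatic_pileups() is the pure-computation core; run_call() wraps it
## with BAM/VCF I/O and is what the command-line entry point invokes.

#' Joint somatic calling over pre-built pileups
#'
#' The computational core of the pipeline, independent of file I/O. For
#' each candidate locus: omit all-normal samples, compute the somatic
#' posterior and maximum-likelihood tumor allele, apply the
#' defer-to-single-caller rule, compute the per-sample support vector and
#' the TIN score, then annotate the emitted records with the empirical,
#' cluster and TIN filters and apply the removal policy.
#'
#' @param loci a `candidate_loci` data frame from [extract_candidates()]
#'   (or an equivalent data frame with `chrom`, `pos`, `normal_allele`,
#'   `originally_called_in`).
#' @param normal_pileups list of the normal sample's [sample_pileup()]s,
#'   one per locus row.
#' @param tumor_pileups named list over tumor samples, each a list of
#'   [sample_pileup()]s parallel to `loci`.
#' @param params a [model_params()].
#' @param verbose emit per-locus messages for skipped loci.
#' @return list with `calls` (a `call_set` data frame of emitted records:
#'   coordinates, `tumor_allele`, `somatic_prob`, `tin_score`,
#'   `normal_depth`, `novel`, `filter_flags`, and per-sample list-columns
#'   `tcount`, `dp`, `fwd_t`, `rev_t`, `support`) and `summary` (named
#'   counts of candidates, skips, defers, emissions, and filter flags).
#' @export
call_somatic_pileups <- function(loci, normal_pileups, tumor_pileups,
                                 params = model_params(), verbose = FALSE) {
  samples <- names(tumor_pileups)
  stopifnot(length(samples) >= 1L, length(normal_pileups) == nrow(loci))
  n <- nrow(loci)
  rows <- vector("list", n)
  n_all_normal <- 0L
  n_defer <- 0L
  n_below <- 0L
  for (i in seq_len(n)) {
    N <- loci$normal_allele[i]
    cohort <- lapply(tumor_pileups, `[[`, i)
    res <- somatic_posterior(cohort, N, params)
    if (is.null(res)) {
      n_all_normal <- n_all_normal + 1L
      if (verbose) message(sprintf("%s:%d skipped: all samples all-normal",
                                   loci$chrom[i], loci$pos[i]))
      next
    }
    Tstar <- estimate_tumor_allele(res$log_marginals, N)
    called_in <- if (!is.null(loci$originally_called_in)) loci$originally_called_in[[i]] else character(0)
    orig_any <- length(called_in) > 0L
    if (!(res$somatic_prob >= params$call_threshold || orig_any)) {
      n_below <- n_below + 1L
      next
    }
    n_with_t <- sum(vapply(cohort, function(p) any(p$base == Tstar), logical(1)))
    if (!defer_single_sample(n_with_t, orig_any)) {
      n_defer <- n_defer + 1L
      if (verbose) message(sprintf("%s:%d dropped: single-sample support, deferring to original caller",
                                   loci$chrom[i], loci$pos[i]))
      next
    }
    support <- per_sample_support(cohort, N, Tstar, params)
    tin <- tin_posterior(normal_pileups[[i]], res$retained, N, Tstar, params)
    cnt <- lapply(cohort, allele_counts, N = N, T = Tstar)
    rows[[i]] <- data.frame(
      chrom = loci$chrom[i], pos = loci$pos[i], normal_allele = N,
      tumor_allele = Tstar, somatic_prob = res$somatic_prob,
      tin_score = tin, normal_depth = pileup_depth(normal_pileups[[i]]),
      novel = !orig_any, filter_flags = "",
      tcount = I(list(vapply(cnt, `[[`, integer(1), "d_t"))),
      dp = I(list(vapply(cohort, nrow, integer(1)))),
      fwd_t = I(list(vapply(cnt, `[[`, integer(1), "fwd_t"))),
      rev_t = I(list(vapply(cnt, `[[`, integer(1), "rev_t"))),
      support = I(list(support)),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), pos = integer(),
                        normal_allele = character(), tumor_allele = character(),
                        somatic_prob = numeric(), tin_score = numeric(),
                        normal_depth = integer(), novel = logical(),
                        filter_flags = character(),
                        tcount = I(list()), dp = I(list()), fwd_t = I(list()),
                        rev_t = I(list()), support = I(list()))
  }
  rownames(calls) <- NULL
  class(calls) <- c("call_set", "data.frame")
  calls <- apply_empirical_filters(calls)
  calls <- cluster_filter(calls)
  calls <- tin_filter(calls, params$tin_threshold)
  flag_counts <- vapply(FILTER_NAMES, function(f) sum(has_flag(calls$filter_flags, f)),
                        integer(1))
  keep <- filter_removal_mask(calls, params$filter_mode)
  emitted <- calls[keep, , drop = FALSE]
  rownames(emitted) <- NULL
  class(emitted) <- c("call_set", "data.frame")
  list(calls = emitted,
       summary = c(n_candidates = n, n_all_normal_skipped = n_all_normal,
                   n_below_threshold = n_below, n_deferred = n_defer,
                   n_flag_removed = sum(!keep), n_calls = nrow(emitted),
                   flag_counts))
}

#' Run the full joint calling pipeline from files
#'
#' Reads candidate loci from per-sample VCFs, builds quality-filtered
#' pileups from the matched-normal and tumor BAMs (merging realigned reads
#' over originals when provided), runs the joint model at every candidate
#' locus, and optionally writes the aggregate output VCF. Deterministic:
#' identical inputs and parameters give byte-identical output.
#'
#' @param normal_bam path to the matched normal BAM (sorted, indexed).
#' @param tumor_bams named character vector of tumor BAM paths; names are
#'   the sample ids and must match `candidate_vcfs`.
#' @param candidate_vcfs named character vector of per-sample candidate
#'   VCFs from the upstream single-sample caller.
#' @param params a [model_params()].
#' @param realigned_bams optional named character vector (subset of the
#'   tumor sample names) of realigned BAMs merged over the originals.
#' @param output_vcf optional path; when given, the aggregate VCF is
#'   written there.
#' @param reference optional reference FASTA; used only to declare contig
#'   lengths in the output header.
#' @param verbose per-locus logging.
#' @return as [call_somatic_pileups()], plus `loci` (the candidate set).
#' @export
run_call <- function(normal_bam, tumor_bams, candidate_vcfs,
                     params = model_params(), realigned_bams = NULL,
                     output_vcf = NULL, reference = NULL, verbose = FALSE) {
  if (is.null(names(tumor_bams)) || is.null(names(candidate_vcfs))) {
    stop("tumor_bams and candidate_vcfs must be named by sample id", call. = FALSE)
  }
  if (!setequal(names(tumor_bams), names(candidate_vcfs))) {
    stop("sample names of tumor_bams and candidate_vcfs disagree", call. = FALSE)
  }
  for (f in c(normal_bam, tumor_bams, candidate_vcfs, realigned_bams)) {
    if (!file.exists(f)) stop(sprintf("input file not found: '%s'", f), call. = FALSE)
  }
  loci <- extract_candidates(candidate_vcfs)
  normal_pileups <- load_pileups(normal_bam, loci, params, sample_id = "normal")
  tumor_pileups <- lapply(names(tumor_bams), function(s) {
    load_pileups(tumor_bams[[s]], loci, params,
                 realigned_path = if (!is.null(realigned_bams) && s %in% names(realigned_bams))
                   realigned_bams[[s]] else NULL,
                 sample_id = s)
  })
  names(tumor_pileups) <- names(tumor_bams)
  res <- call_somatic_pileups(loci, normal_pileups, tumor_pileups, params,
                              verbose = verbose)
  res$loci <- loci
  if (!is.null(output_vcf)) {
    contigs <- reference_contigs(reference)
    write_vcf(res$calls, names(tumor_bams), output_vcf, contigs = contigs)
  }
  res
}

## contig name/length pairs from a FASTA, or NULL
reference_contigs <- function(reference) {
  if (is.null(reference)) return(NULL)
  fai <- paste0(reference, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(reference)
  idx <- utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(idx[[2]], idx[[1]])
}

#' Write a call set as an aggregate VCF
#'
#' Emits VCF v4.2 with one record per called locus: REF is the normal
#' allele, ALT the estimated tumor allele, FILTER the accumulated flags
#' (or PASS), INFO fields PROB (somatic probability), TIN (Phred
#' tumor-in-normal score) and NSUP (number of supporting samples), and
#' per-tumor-sample FORMAT fields TCOUNT (tumor-allele count), DP
#' (filtered depth), SB (forward,reverse tumor-allele counts) and ZS
#' (support indicator).
#'
#' @param calls a `call_set`, sorted by (chrom, pos) within chromosome
#'   blocks.
#' @param sample_ids tumor sample names, in column order.
#' @param path output path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_ids, path, contigs = NULL) {
  if (nrow(calls) > 0L) {
    for (chr in unique(calls$chrom)) {
      p <- calls$pos[calls$chrom == chr]
      if (is.unsorted(p)) stop("call set must be position-sorted within chromosomes",
                               call. = FALSE)
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=jointsnv",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                                   as.integer(contigs)),
    "##INFO=<ID=PROB,Number=1,Type=Float,Description=\"Somatic probability: posterior that at least one tumor sample carries the variant\">",
    "##INFO=<ID=TIN,Number=1,Type=Float,Description=\"Phred-scaled posterior against the normal sample carrying the tumor allele\">",
    "##INFO=<ID=NSUP,Number=1,Type=Integer,Description=\"Number of supporting tumor samples\">",
    "##FILTER=<ID=low-normal-depth,Description=\"Quality-filtered normal depth below 6\">",
    "##FILTER=<ID=low-tumor-support,Description=\"Tumor allele count below 4 in all samples\">",
    "##FILTER=<ID=empty-strand,Description=\"No tumor-allele reads on one strand in all samples\">",
    "##FILTER=<ID=cluster,Description=\"At least 3 called SNV sites within 100 bp\">",
    "##FILTER=<ID=TIN,Description=\"Tumor-in-normal score below threshold\">",
    "##FORMAT=<ID=TCOUNT,Number=1,Type=Integer,Description=\"Tumor allele count\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Quality-filtered depth\">",
    "##FORMAT=<ID=SB,Number=2,Type=Integer,Description=\"Tumor allele count on forward,reverse strand\">",
    "##FORMAT=<ID=ZS,Number=1,Type=Integer,Description=\"Sample supports the variant (0/1)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(calls)), function(i) {
    info <- sprintf("PROB=%s;TIN=%s;NSUP=%d",
                    format(calls$somatic_prob[i], digits = 6),
                    format(calls$tin_score[i], digits = 6),
                    sum(calls$support[[i]]))
    fmt <- vapply(seq_along(sample_ids), function(s) {
      sprintf("%d:%d:%d,%d:%d", calls$tcount[[i]][s], calls$dp[[i]][s],
              calls$fwd_t[[i]][s], calls$rev_t[[i]][s], calls$support[[i]][s])
    }, character(1))
    filt <- if (nzchar(calls$filter_flags[i])) calls$filter_flags[i] else "PASS"
    paste(c(calls$chrom[i], calls$pos[i], ".", calls$normal_allele[i],
            calls$tumor_allele[i], ".", filt, info, "TCOUNT:DP:SB:ZS", fmt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
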