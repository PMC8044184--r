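## Candidate-locus construction: the union of per-sample single-sample-caller
## VCF records, kept deliberately permissive (records failing the original
## caller's filters are candidates too — the joint model re-evaluates them).

#' Build the candidate locus set from per-sample VCFs
#'
#' Takes the union of SNV positions across the per-sample call files
#' produced by any single-sample somatic caller run under permissive
#' settings. Records that failed the original caller's filters are
#' included; only biallelic-position bookkeeping is needed because the
#' joint model re-estimates the tumor allele itself. Non-SNV records
#' (REF length != 1, symbolic or non-ACGT REF) are skipped and counted.
#' Positions where two inputs disagree on REF are dropped with a warning:
#' a wrong normal allele would corrupt the model at that locus.
#'
#' @param vcf_inputs named character vector: `sample_id = path` to a VCF
#'   (plain or gzipped).
#' @return a data frame of class `candidate_loci`, sorted by chromosome
#'   (order of first appearance across the inputs) then position, with
#'   columns `chrom`, `pos`, `normal_allele` and list-columns
#'   `source_samples`, `originally_called_in`, `alt_alleles`. The number
#'   of skipped non-SNV records is attached as attribute `n_skipped`.
#' @export
extract_candidates <- function(vcf_inputs) {
  stopifnot(length(vcf_inputs) >= 1L, !is.null(names(vcf_inputs)))
  recs <- list()
  n_skipped <- 0L
  for (sid in names(vcf_inputs)) {
    v <- vcfR::read.vcfR(vcf_inputs[[sid]], verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0L) next
    ref <- fix[, "REF"]
    snv <- !is.na(ref) & nchar(ref) == 1L & ref %in% BASES
    n_skipped <- n_skipped + sum(!snv)
    if (!any(snv)) next
    recs[[sid]] <- data.frame(
      sample = sid,
      chrom = fix[snv, "CHROM"],
      pos = as.integer(fix[snv, "POS"]),
      ref = ref[snv],
      alt = fix[snv, "ALT"],
      pass = !is.na(fix[snv, "FILTER"]) & fix[snv, "FILTER"] == "PASS",
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, recs)
  if (is.null(all) || nrow(all) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      normal_allele = character(),
                      source_samples = I(list()),
                      originally_called_in = I(list()),
                      alt_alleles = I(list()))
    class(out) <- c("candidate_loci", "data.frame")
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  chrom_order <- unique(all$chrom)
  key <- paste(all$chrom, all$pos)
  grp <- split(all, factor(key, levels = unique(key)))
  rows <- lapply(grp, function(g) {
    if (length(unique(g$ref)) > 1L) {
      warning(sprintf("REF disagreement at %s:%d (%s); locus skipped",
                      g$chrom[1], g$pos[1],
                      paste(unique(g$ref), collapse = "/")), call. = FALSE)
      return(NULL)
    }
    data.frame(chrom = g$chrom[1], pos = g$pos[1], normal_allele = g$ref[1],
               source_samples = I(list(unique(g$sample))),
               originally_called_in = I(list(unique(g$sample[g$pass]))),
               alt_alleles = I(list(unique(unlist(strsplit(g$alt[!is.na(g$alt)], ","))))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      normal_allele = character(),
                      source_samples = I(list()),
                      originally_called_in = I(list()),
                      alt_alleles = I(list()))
    class(out) <- c("candidate_loci", "data.frame")
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  ord <- order(match(out$chrom, chrom_order), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_loci", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Was a candidate locus accepted by the original caller in a sample?
#'
#' `TRUE` iff the sample's input VCF has a record at the locus whose FILTER
#' is `PASS`. Records with named filters, and loci absent from the
#' sample's VCF, return `FALSE`.
#'
#' @param loci a `candidate_loci` data frame from [extract_candidates()].
#' @param chrom,pos locus coordinates (1-based, VCF convention).
#' @param sample sample id.
#' @return logical scalar.
#' @export
originally_called <- function(loci, chrom, pos, sample) {
  i <- which(loci$chrom == chrom & loci$pos == pos)
  if (length(i) == 0L) return(FALSE)
  sample %in% loci$originally_called_in[[i[1]]]
}
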