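## Pileup construction from coordinate-sorted, indexed BAM files: fetch the
## reads covering the candidate loci, optionally merge in realigned reads,
## apply read- and base-level quality filters, and emit one sample_pileup
## per locus.

FLAG_REVERSE <- 16L
FLAG_FIRST_MATE <- 64L
FLAG_SECONDARY <- 256L
FLAG_DUP <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

## Fetch reads over a set of ranges as a plain read table. One row per
## alignment record: qname, flag, chrom, pos (leftmost, 1-based), mapq,
## cigar, seq, qual (ASCII-33 string).
scan_read_table <- function(bam_path, which) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop(sprintf("BAM index not found for '%s'; sort and index the file first",
                 bam_path), call. = FALSE)
  }
  bf <- Rsamtools::BamFile(bam_path)
  known <- GenomeInfoDb::seqnames(Rsamtools::seqinfo(bf))
  miss <- setdiff(as.character(GenomeInfoDb::seqnames(which)), known)
  if (length(miss) > 0L) {
    warning(sprintf("contig(s) %s absent from '%s'; returning no reads there",
                    paste(miss, collapse = ", "), bam_path), call. = FALSE)
    which <- which[as.character(GenomeInfoDb::seqnames(which)) %in% known]
  }
  if (length(which) == 0L) {
    return(data.frame(qname = character(), flag = integer(), chrom = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bf, param = param)
  tabs <- lapply(res, function(r) {
    data.frame(qname = r$qname, flag = r$flag, chrom = as.character(r$rname),
               pos = r$pos, mapq = r$mapq, cigar = r$cigar,
               seq = as.character(r$seq), qual = as.character(r$qual),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  # ranges may overlap; drop records fetched twice
  out[!duplicated(paste(out$qname, out$flag, out$chrom, out$pos, out$cigar)), ,
      drop = FALSE]
}

#' Merge realigned reads over the original read set
#'
#' Local realignment (e.g. by an assembly-based single-sample caller)
#' produces an updated version of some reads. The merged set contains
#' every original read unless a realigned read with the same key — (query
#' name, first-of-pair flag) — exists, in which case the realigned version
#' replaces it; realigned-only reads are added. Duplicate keys within one
#' source keep the first occurrence with a warning.
#'
#' @param original,realigned read tables (data frames with at least
#'   `qname` and `flag` columns), as produced by the internal BAM scanner.
#' @return the merged read table.
#' @export
merge_realigned <- function(original, realigned) {
  key <- function(tab) paste(tab$qname, bitwAnd(tab$flag, FLAG_FIRST_MATE) > 0L)
  dedup <- function(tab, label) {
    k <- key(tab)
    if (anyDuplicated(k)) {
      warning(sprintf("duplicate read keys in %s set; keeping first occurrence",
                      label), call. = FALSE)
      tab <- tab[!duplicated(k), , drop = FALSE]
    }
    tab
  }
  original <- dedup(original, "original")
  realigned <- dedup(realigned, "realigned")
  if (nrow(realigned) == 0L) return(original)
  keep <- !(key(original) %in% key(realigned))
  out <- rbind(original[keep, , drop = FALSE], realigned)
  rownames(out) <- NULL
  out
}

## For each (read, locus) pair, locate the base aligned to the locus.
## Returns a data.frame(locus_idx, base, phred, flag, mapq) with one row
## per read that has an aligned match/mismatch base at the position; reads
## with a deletion, skip or clip there contribute nothing.
extract_base_at <- function(reads, loci_chrom, loci_pos) {
  empty <- data.frame(locus_idx = integer(), base = character(),
                      phred = integer(), flag = integer(), mapq = integer(),
                      qname = character(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L || length(loci_pos) == 0L) return(empty)
  ops <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = ops)
  qq <- GenomicAlignments::cigarRangesAlongQuerySpace(reads$cigar, ops = ops)
  nblock <- S4Vectors::elementNROWS(rr)
  blocks <- data.frame(read_idx = rep(seq_len(nrow(reads)), nblock),
                       rstart = unlist(IRanges::start(rr), use.names = FALSE),
                       rend = unlist(IRanges::end(rr), use.names = FALSE),
                       qstart = unlist(IRanges::start(qq), use.names = FALSE))
  # candidate pairs: read block x locus on the same chromosome
  gr_blocks <- GenomicRanges::GRanges(reads$chrom[blocks$read_idx],
                                      IRanges::IRanges(blocks$rstart, blocks$rend))
  gr_loci <- GenomicRanges::GRanges(loci_chrom, IRanges::IRanges(loci_pos, loci_pos))
  hits <- GenomicRanges::findOverlaps(gr_loci, gr_blocks)
  if (length(hits) == 0L) return(empty)
  li <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ri <- blocks$read_idx[bi]
  qpos <- blocks$qstart[bi] + (loci_pos[li] - blocks$rstart[bi])
  base <- substr(reads$seq[ri], qpos, qpos)
  qchar <- substr(reads$qual[ri], qpos, qpos)
  phred <- utf8ToInt(paste(qchar, collapse = "")) - 33L
  data.frame(locus_idx = li, base = base, phred = phred,
             flag = reads$flag[ri], mapq = reads$mapq[ri],
             qname = reads$qname[ri], stringsAsFactors = FALSE)
}

#' Load quality-filtered pileups for one sample at many loci
#'
#' Fetches the reads covering the candidate loci from an indexed BAM (or
#' converted SAM), optionally replaces originals with their realigned
#' versions, and builds one [sample_pileup()] per locus. Reads below the
#' mapping-quality threshold, bases below the base-quality threshold,
#' duplicate-flagged (unless `count_duplicates`), secondary and
#' supplementary alignments, and non-ACGT base calls are excluded. With
#' `mate_overlap = "highest"` the lower-quality mate of an overlapping
#' pair is dropped at each locus.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param loci a `candidate_loci` data frame (or any data frame with
#'   `chrom` and `pos`).
#' @param params a [model_params()].
#' @param realigned_path optional realigned BAM merged over the original.
#' @param sample_id id attached to each pileup.
#' @return list of [sample_pileup()], one per locus row.
#' @export
load_pileups <- function(bam_path, loci, params = model_params(),
                         realigned_path = NULL, sample_id = NA_character_) {
  which <- GenomicRanges::reduce(GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$pos, loci$pos)))
  reads <- scan_read_table(bam_path, which)
  if (!is.null(realigned_path)) {
    reads <- merge_realigned(reads, scan_read_table(realigned_path, which))
  }
  drop_mask <- bitwAnd(reads$flag, FLAG_SECONDARY + FLAG_SUPPLEMENTARY) > 0L
  if (!params$count_duplicates) {
    drop_mask <- drop_mask | bitwAnd(reads$flag, FLAG_DUP) > 0L
  }
  reads <- reads[!drop_mask & reads$mapq >= params$mapq_min, , drop = FALSE]
  obs <- extract_base_at(reads, loci$chrom, loci$pos)
  obs <- obs[obs$phred >= params$baseq_min & obs$base %in% BASES, , drop = FALSE]
  if (params$mate_overlap == "highest" && nrow(obs) > 0L) {
    # overlapping mates share qname at the same locus; keep the better base
    ord <- order(obs$locus_idx, obs$qname, -obs$phred,
                 bitwAnd(obs$flag, FLAG_FIRST_MATE) == 0L)
    obs <- obs[ord, , drop = FALSE]
    obs <- obs[!duplicated(paste(obs$locus_idx, obs$qname)), , drop = FALSE]
  }
  out <- vector("list", nrow(loci))
  split_obs <- split(obs, factor(obs$locus_idx, levels = seq_len(nrow(loci))))
  for (i in seq_len(nrow(loci))) {
    o <- split_obs[[i]]
    out[[i]] <- sample_pileup(
      base = o$base,
      error_prob = phred_to_error_prob(o$phred),
      forward_strand = bitwAnd(o$flag, FLAG_REVERSE) == 0L,
      mapping_quality = o$mapq,
      sample_id = sample_id)
  }
  out
}

#' Load the pileup for one sample at a single locus
#'
#' Convenience wrapper around [load_pileups()] for one candidate locus.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param chrom,pos locus coordinates (1-based).
#' @param params a [model_params()].
#' @param realigned_path optional realigned BAM.
#' @param sample_id id attached to the pileup.
#' @return a [sample_pileup()].
#' @export
load_pileup <- function(bam_path, chrom, pos, params = model_params(),
                        realigned_path = NULL, sample_id = NA_character_) {
  load_pileups(bam_path, data.frame(chrom = chrom, pos = pos), params,
               realigned_path, sample_id)[[1]]
}
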