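# Programmatic fixtures: tiny SAM/VCF files built in code at test time.

sam_header <- function(contig = "chr1", len = 100000L) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, len))
}

# one alignment line; qual given as Phred integers
sam_read <- function(qname, pos, seq, phred, flag = 0L, mapq = 60L,
                     cigar = paste0(nchar(seq), "M"), contig = "chr1") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, contig, pos, mapq, cigar, seq,
          intToUtf8(phred + 33L, multiple = FALSE))
}

# write SAM lines, convert to sorted+indexed BAM, return BAM path
make_bam <- function(lines, name = "reads") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(lines, sam)
  suppressMessages(Rsamtools::asBam(sam, file.path(dir, name),
                                    overwrite = TRUE, indexDestination = TRUE))
}

# minimal candidate VCF
make_vcf <- function(rows, name = "cands", contig = "chr1", len = 100000L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  path <- file.path(dir, paste0(name, ".vcf"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, len),
           "##FILTER=<ID=LowEVS,Description=\"x\">",
           "##FILTER=<ID=permissive,Description=\"x\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, filter = "PASS") {
  sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", chrom, pos, ref, alt, filter)
}

# a minimal call_set row for filter tests
call_row <- function(chrom = "chr1", pos = 100L, prob = 0.99, tin = 30,
                     normal_depth = 30L, novel = TRUE, tcount = c(5L, 5L),
                     fwd = c(3L, 2L), rev = c(2L, 3L), flags = "") {
  structure(data.frame(chrom = chrom, pos = pos, normal_allele = "A",
                       tumor_allele = "G", somatic_prob = prob,
                       tin_score = tin, normal_depth = normal_depth,
                       novel = novel, filter_flags = flags,
                       tcount = I(list(tcount)), dp = I(list(tcount + 20L)),
                       fwd_t = I(list(fwd)), rev_t = I(list(rev)),
                       support = I(list(as.integer(tcount > 0))),
                       stringsAsFactors = FALSE),
            class = c("call_set", "data.frame"))
}

bind_calls <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("call_set", "data.frame")
  out
}
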