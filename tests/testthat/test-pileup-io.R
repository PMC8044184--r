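# BAM pileup construction: quality filtering, CIGAR handling, duplicate and
# secondary exclusion, realigned-read merging.

test_that("pileup applies mapping- and base-quality thresholds strictly", {
  bam <- make_bam(c(
    sam_header(),
    sam_read("r1", 1000, "G", 40, mapq = 30),   # kept
    sam_read("r2", 1000, "G", 40, mapq = 29),   # MAPQ below 30
    sam_read("r3", 1000, "G", 13, mapq = 60),   # baseQ 13 kept (strict below)
    sam_read("r4", 1000, "G", 12, mapq = 60),   # baseQ 12 excluded
    sam_read("r5", 1000, "A", 40, mapq = 60, flag = 16L)))
  p <- load_pileup(bam, "chr1", 1000)
  expect_identical(nrow(p), 3L)
  expect_identical(sort(p$base), c("A", "G", "G"))
  expect_identical(sum(!p$forward_strand), 1L)
  expect_true(all(p$mapping_quality >= 30))
})

test_that("reads with a deletion or soft clip at the locus contribute nothing", {
  bam <- make_bam(c(
    sam_header(),
    sam_read("del", 995, "ACGTAACGTA", rep(40, 10), cigar = "5M3D5M"),  # deletion spans 1000-1002
    sam_read("clip", 999, "ACG", rep(40, 3), cigar = "1M2S"),           # clipped at 1000
    sam_read("span", 996, "ACGTAACGTA", rep(40, 10))))                  # covers 1000
  p <- load_pileup(bam, "chr1", 1000)
  expect_identical(nrow(p), 1L)
  expect_identical(p$base, "A")  # 5th base of "span" starting at 996
})

test_that("multi-block CIGARs map the correct query base to the locus", {
  # 3M2D4M starting at 100: ref 100-102 from query 1-3, ref 105-108 from query 4-7
  bam <- make_bam(c(sam_header(),
                    sam_read("r", 100, "ACGTTTT", rep(40, 7), cigar = "3M2D4M")))
  expect_identical(load_pileup(bam, "chr1", 102)$base, "G")
  expect_identical(nrow(load_pileup(bam, "chr1", 104)), 0L)
  expect_identical(load_pileup(bam, "chr1", 106)$base, "T")
})

test_that("duplicate, secondary and supplementary alignments are excluded by default", {
  bam <- make_bam(c(
    sam_header(),
    sam_read("ok", 2000, "C", 40),
    sam_read("dup", 2000, "C", 40, flag = 1024L),
    sam_read("sec", 2000, "C", 40, flag = 256L),
    sam_read("sup", 2000, "C", 40, flag = 2048L)))
  expect_identical(nrow(load_pileup(bam, "chr1", 2000)), 1L)
  p_dup <- load_pileup(bam, "chr1", 2000, model_params(count_duplicates = TRUE))
  expect_identical(nrow(p_dup), 2L)
})

test_that("re-loading a locus is deterministic and depth never exceeds raw depth", {
  set.seed(3)
  lines <- c(sam_header(),
             vapply(1:25, function(i)
               sam_read(paste0("r", i), 5000, sample(c("A", "G"), 1),
                        sample(c(10, 20, 40), 1), mapq = sample(c(20, 60), 1)),
               character(1)))
  bam <- make_bam(lines)
  p1 <- load_pileup(bam, "chr1", 5000)
  p2 <- load_pileup(bam, "chr1", 5000)
  expect_identical(p1, p2)
  expect_lte(nrow(p1), 25L)
})

test_that("unknown contigs yield an empty pileup with a warning", {
  bam <- make_bam(c(sam_header(), sam_read("r1", 100, "A", 40)))
  expect_warning(p <- load_pileup(bam, "chrUn", 100), "absent")
  expect_identical(nrow(p), 0L)
})

test_that("a missing BAM index is an explicit error", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  writeLines(c(sam_header(), sam_read("r1", 100, "A", 40)), sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, file.path(dir, "x"),
                                           overwrite = TRUE,
                                           indexDestination = FALSE))
  file.remove(Sys.glob(file.path(dir, "*.bai")))
  expect_error(load_pileup(bam, "chr1", 100), "index")
})

test_that("realigned reads replace originals by (qname, mate) key", {
  orig <- data.frame(qname = c("r1", "r2"), flag = c(0L, 0L), chrom = "chr1",
                     pos = c(100L, 100L), mapq = 60L, cigar = "1M",
                     seq = c("A", "A"), qual = c("I", "I"),
                     stringsAsFactors = FALSE)
  realn <- data.frame(qname = "r2", flag = 0L, chrom = "chr1", pos = 100L,
                      mapq = 60L, cigar = "1M", seq = "G", qual = "I",
                      stringsAsFactors = FALSE)
  merged <- merge_realigned(orig, realn)
  expect_identical(nrow(merged), 2L)
  expect_identical(sort(merged$seq), c("A", "G"))
  # empty realigned set: originals unchanged
  expect_identical(merge_realigned(orig, realn[0, ]), orig)
  # realigned-only reads are added
  r3 <- data.frame(qname = "r3", flag = 0L, chrom = "chr1", pos = 100L,
                   mapq = 60L, cigar = "1M", seq = "T", qual = "I",
                   stringsAsFactors = FALSE)
  expect_identical(nrow(merge_realigned(orig, r3)), 3L)
  # mates are distinct keys: first-of-pair flag 64 vs second
  mate <- data.frame(qname = "r1", flag = 64L, chrom = "chr1", pos = 100L,
                     mapq = 60L, cigar = "1M", seq = "C", qual = "I",
                     stringsAsFactors = FALSE)
  expect_identical(nrow(merge_realigned(orig, mate)), 3L)
  # duplicate keys within one source: keep first, warn
  expect_warning(m <- merge_realigned(rbind(orig, orig[1, ]), realn),
                 "duplicate")
  expect_identical(nrow(m), 2L)
})

test_that("the realigned BAM path feeds the pileup", {
  orig_bam <- make_bam(c(sam_header(),
                         sam_read("r1", 3000, "A", 40),
                         sam_read("r2", 3000, "A", 40)), "orig")
  realn_bam <- make_bam(c(sam_header(),
                          sam_read("r2", 3000, "G", 40)), "realn")
  p <- load_pileup(orig_bam, "chr1", 3000, realigned_path = realn_bam)
  expect_identical(sort(p$base), c("A", "G"))
})

test_that("overlapping mates can be collapsed to the higher-quality base", {
  bam <- make_bam(c(sam_header(),
                    sam_read("frag", 4000, "A", 20, flag = 64L),
                    sam_read("frag", 4000, "G", 40, flag = 128L)))
  both <- load_pileup(bam, "chr1", 4000, model_params(mate_overlap = "both"))
  expect_identical(nrow(both), 2L)
  best <- load_pileup(bam, "chr1", 4000, model_params(mate_overlap = "highest"))
  expect_identical(best$base, "G")
})
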