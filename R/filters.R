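## Post-call filters: empirical artifact filters (normal depth, tumor
## support, strand, SNV clusters), the Phred-scaled tumor-in-normal filter,
## and the defer-to-single-caller rule. Filters annotate; removal policy is
## decided at emission time (by default only calls the original caller
## never accepted are removed when flagged).

FILTER_NAMES <- c("low-normal-depth", "low-tumor-support", "empty-strand",
                  "cluster", "TIN")

set_flag <- function(flags, name, on) {
  cur <- strsplit(flags, ";", fixed = TRUE)
  mapply(function(f, o) {
    f <- setdiff(f, c(name, ""))
    if (o) f <- c(f, name)
    paste(f, collapse = ";")
  }, cur, on, USE.NAMES = FALSE)
}

has_flag <- function(flags, name) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(f) name %in% f, logical(1))
}

#' Apply the empirical artifact filters to a call set
#'
#' Flags each record with any of: `low-normal-depth` (quality-filtered
#' normal depth below 6), `low-tumor-support` (tumor-allele count below 4
#' in every sample), `empty-strand` (no tumor-allele reads on the forward
#' strand in any sample, or none on the reverse strand in any sample).
#' Flags are recomputed from the counts, so the operation is idempotent.
#'
#' @param calls a `call_set` data frame (see [call_somatic()]): needs
#'   `normal_depth`, list-columns `tcount`, `fwd_t`, `rev_t`, and a
#'   `filter_flags` character column.
#' @return the call set with updated `filter_flags`.
#' @export
apply_empirical_filters <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  low_nd <- calls$normal_depth < 6
  low_ts <- vapply(calls$tcount, function(tc) all(tc < 4), logical(1))
  empty_strand <- mapply(function(f, r) all(f == 0) || all(r == 0),
                         calls$fwd_t, calls$rev_t)
  calls$filter_flags <- set_flag(calls$filter_flags, "low-normal-depth", low_nd)
  calls$filter_flags <- set_flag(calls$filter_flags, "low-tumor-support", low_ts)
  calls$filter_flags <- set_flag(calls$filter_flags, "empty-strand", empty_strand)
  calls
}

#' Flag clustered SNV sites
#'
#' Runs of nearby calls are characteristic of undetected duplicate reads
#' and alignment artifacts. A record is flagged `cluster` iff some window
#' of span at most 100 bp (max position minus min position, inclusive) on
#' its chromosome contains it together with at least two other called
#' records. The flag depends only on the full sorted call set, so
#' streaming and whole-chromosome application agree.
#'
#' @param calls a `call_set` sorted by (chrom, pos).
#' @param window_bp cluster window span in base pairs.
#' @param min_sites minimum number of sites in the window.
#' @return the call set with updated `filter_flags`.
#' @export
cluster_filter <- function(calls, window_bp = 100L, min_sites = 3L) {
  if (nrow(calls) == 0L) return(calls)
  flag <- logical(nrow(calls))
  for (chr in unique(calls$chrom)) {
    idx <- which(calls$chrom == chr)
    pos <- calls$pos[idx]
    o <- order(pos)
    sp <- pos[o]
    in_cluster <- logical(length(sp))
    j <- 1L
    for (i in seq_along(sp)) {
      if (j < i) j <- i
      # largest j with sp[j] - sp[i] <= window_bp
      while (j < length(sp) && sp[j + 1L] - sp[i] <= window_bp) j <- j + 1L
      if (j >= i + min_sites - 1L) in_cluster[i:j] <- TRUE
    }
    flag[idx[o]] <- in_cluster
  }
  calls$filter_flags <- set_flag(calls$filter_flags, "cluster", flag)
  calls
}

#' Flag calls with tumor-in-normal contamination
#'
#' Flags records whose Phred-scaled TIN score (posterior that the normal
#' sample carries the tumor allele, see [tin_posterior()]) falls strictly
#' below the threshold.
#'
#' @param calls a `call_set` with a `tin_score` column.
#' @param threshold Phred threshold (default 20, i.e. posterior 0.01).
#' @return the call set with updated `filter_flags`.
#' @export
tin_filter <- function(calls, threshold = 20) {
  if (nrow(calls) == 0L) return(calls)
  calls$filter_flags <- set_flag(calls$filter_flags, "TIN",
                                 calls$tin_score < threshold)
  calls
}

#' Defer-to-single-caller decision
#'
#' When only one tumor sample has any read carrying the tumor allele, the
#' joint model adds nothing over a single-sample caller; the call is kept
#' only if the original caller accepted the locus in some sample.
#'
#' @param n_samples_with_t number of samples with >= 1 quality-filtered
#'   tumor-allele read.
#' @param originally_called_any was the locus accepted by the original
#'   caller in any sample?
#' @return `TRUE` to keep the call, `FALSE` to drop it.
#' @export
defer_single_sample <- function(n_samples_with_t, originally_called_any) {
  !(n_samples_with_t == 1L && !originally_called_any)
}

#' Decide which flagged records to remove at emission
#'
#' In `"novel"` mode (the default) flags only remove records the original
#' caller never accepted anywhere — previously accepted calls are
#' annotated but kept. `"all"` removes every flagged record; `"off"`
#' removes none.
#'
#' @param calls a `call_set` with `filter_flags` and `novel` columns.
#' @param mode one of `"novel"`, `"all"`, `"off"`.
#' @return logical vector: `TRUE` for records to keep.
#' @export
filter_removal_mask <- function(calls, mode = c("novel", "all", "off")) {
  mode <- match.arg(mode)
  flagged <- nzchar(calls$filter_flags)
  switch(mode,
         novel = !(flagged & calls$novel),
         all = !flagged,
         off = rep(TRUE, nrow(calls)))
}
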