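#' Overlap length between genomic intervals
#'
#' Computes the number of base pairs shared by two intervals in the
#' package-wide 0-based half-open convention. Intervals on different
#' chromosomes overlap by 0 bp; strand never enters the computation
#' (promoter windows are symmetric around the TSS).
#'
#' @param a,b Data frames (or single-row tibbles) with columns `chrom`,
#'   `start`, `end`. Rows are matched positionally and recycled if one
#'   side has a single row.
#' @return Integer vector of overlap lengths in bp (>= 0).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 300)
#' b <- tibble::tibble(chrom = "chr1", start = 200, end = 400)
#' interval_overlap(a, b)  # 100
#' @export
interval_overlap <- function(a, b) {
  check_columns(a, c("chrom", "start", "end"), "`a`")
  check_columns(b, c("chrom", "start", "end"), "`b`")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1L && nrow(b) != 1L) {
    tfm_abort("`a` and `b` must have the same number of rows (or one row)",
              "length_error")
  }
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0L,
             pmin(a$end[idx_a], b$end[idx_b]) -
               pmax(a$start[idx_a], b$start[idx_b]))
  as.integer(ov * (a$chrom[idx_a] == b$chrom[idx_b]))
}

# internal: convert a 0-based half-open interval tibble to GRanges (1-based
# closed). Strand is deliberately dropped: no overlap decision is stranded.
# A shared seqlevels universe avoids seqinfo-merge chatter downstream.
as_granges0 <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# internal: all overlapping pairs between two 0-based interval tibbles,
# with overlap width in bp. Returns tibble(query, subject, overlap).
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble(query = integer(), subject = integer(), overlap = integer()))
  }
  lev <- union(unique(query$chrom), unique(subject$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges0(query, lev),
                                      as_granges0(subject, lev),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  tibble(query = qi, subject = si, overlap = as.integer(ov))
}

#' Validate a peak or interval table
#'
#' Checks the structural invariants of an interval table: non-empty
#' chromosome names, `0 <= start < end`, and (for peak tables)
#' `neg_log10_p >= 0` and summit offsets inside the peak.
#'
#' @param x Interval/peak tibble.
#' @return `x` invisibly; aborts with a validation error otherwise.
#' @export
validate_intervals <- function(x) {
  check_columns(x, c("chrom", "start", "end"), "interval table")
  if (any(is.na(x$chrom) | x$chrom == "")) {
    tfm_abort("chromosome names must be non-empty", "validation_error")
  }
  if (any(x$start < 0)) {
    tfm_abort("negative start coordinate", "validation_error")
  }
  if (any(x$start >= x$end)) {
    tfm_abort("intervals must satisfy start < end", "validation_error")
  }
  if ("neg_log10_p" %in% names(x) && any(x$neg_log10_p < 0, na.rm = TRUE)) {
    tfm_abort("neg_log10_p must be >= 0", "validation_error")
  }
  if ("summit_offset" %in% names(x)) {
    bad <- !is.na(x$summit_offset) &
      (x$summit_offset < 0 | x$summit_offset >= x$end - x$start)
    if (any(bad)) {
      tfm_abort("summit_offset must lie in [0, end - start)", "validation_error")
    }
  }
  invisible(x)
}
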