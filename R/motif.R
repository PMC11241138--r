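#' Convert a position frequency matrix to a log2-odds weight matrix
#'
#' Each entry is
#' `log2( (count(b,j) + pseudocount * bg(b)) / (colsum(j) + pseudocount) / bg(b) )`,
#' i.e. the pseudocount is distributed across bases proportionally to
#' the background before normalising each column.
#'
#' @param pfm `pfm_matrix` object (see [pfm_matrix()], [read_pfm()]);
#'   its `pseudocount` must be > 0.
#' @return 4 x L numeric matrix of log2-odds scores (rows A, C, G, T).
#' @export
pwm_log_odds <- function(pfm) {
  stopifnot(inherits(pfm, "pfm_matrix"))
  if (pfm$pseudocount <= 0) {
    tfm_abort("pseudocount must be > 0", "validation_error")
  }
  counts <- pfm$counts
  bg <- pfm$background
  p <- sweep(counts + pfm$pseudocount * bg, 2,
             colSums(counts) + pfm$pseudocount, "/")
  log2(sweep(p, 1, bg, "/"))
}

#' Scan a promoter sequence for motif hits
#'
#' Slides the weight matrix over both strands of the sequence (the
#' reverse strand is scored against the reverse complement), scoring
#' each window as the sum of per-position log2-odds entries. A window is
#' a hit iff its relative score reaches `rel_threshold`. The relative
#' score rescales the raw score between the minimum and maximum
#' attainable matrix scores, so it lies in [0, 1] and the consensus
#' sequence scores exactly 1. Windows containing `N` are skipped.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pwm Log2-odds matrix from [pwm_log_odds()].
#' @param rel_threshold Minimum relative score in (0, 1] (default 0.80,
#'   a common PWM-scan convention).
#' @return Tibble of hits: `position` (0-based offset of the window
#'   start on the forward sequence), `strand`, `score` (log2-odds bits),
#'   `rel_score`. Sequences shorter than the motif yield zero rows.
#' @export
scan_promoter <- function(sequence, pwm, rel_threshold = 0.80) {
  if (rel_threshold <= 0 || rel_threshold > 1) {
    tfm_abort("rel_threshold must be in (0, 1]", "validation_error")
  }
  sequence <- toupper(sequence)
  L <- ncol(pwm)
  n <- nchar(sequence)
  empty <- tibble(position = integer(), strand = character(),
                  score = numeric(), rel_score = numeric())
  if (n < L) return(empty)

  max_score <- sum(apply(pwm, 2, max))
  min_score <- sum(apply(pwm, 2, min))
  span <- max_score - min_score

  score_strand <- function(seq_chars) {
    idx <- match(seq_chars, c("A", "C", "G", "T"))  # N -> NA
    nw <- n - L + 1L
    s <- numeric(nw)
    for (j in seq_len(L)) {
      col <- pwm[, j]
      s <- s + col[idx[j:(j + nw - 1L)]]  # NA propagates for N windows
    }
    unname(s)
  }

  fwd_chars <- strsplit(sequence, "")[[1]]
  rev_chars <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence))
  ), "")[[1]]

  fwd <- score_strand(fwd_chars)
  rev <- score_strand(rev_chars)
  nw <- n - L + 1L
  # a window at forward offset i (0-based) corresponds, on the reverse
  # complement, to the window starting at offset n - L - i
  hits <- bind_rows(
    tibble(position = 0:(nw - 1L), strand = "+", score = fwd),
    tibble(position = (nw - 1L):0, strand = "-", score = rev)
  ) |>
    filter(!is.na(.data$score)) |>
    mutate(rel_score = if (span > 0) (.data$score - min_score) / span else 1) |>
    filter(.data$rel_score >= rel_threshold) |>
    arrange(.data$position, .data$strand)
  hits
}

#' Best motif hit per promoter sequence
#'
#' Convenience wrapper: scans every sequence and reports whether it
#' carries a hit and the best relative score observed (over both
#' strands, threshold-free).
#'
#' @param seqs Named character vector of promoter sequences.
#' @param pfm `pfm_matrix` object.
#' @param rel_threshold Hit threshold passed to [scan_promoter()].
#' @return Tibble: `parent_id`, `motif_hit`, `motif_best_rel_score`,
#'   `n_motif_hits`.
#' @export
scan_promoter_set <- function(seqs, pfm, rel_threshold = 0.80) {
  pwm <- pwm_log_odds(pfm)
  res <- purrr::map(seqs, function(s) {
    all_windows <- scan_promoter(s, pwm, rel_threshold = 1e-9)
    hits <- all_windows[all_windows$rel_score >= rel_threshold, ]
    tibble(
      motif_hit = nrow(hits) > 0,
      motif_best_rel_score = if (nrow(all_windows) > 0)
        max(all_windows$rel_score) else NA_real_,
      n_motif_hits = nrow(hits)
    )
  })
  bind_rows(res, .id = "parent_id")
}
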