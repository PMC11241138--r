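#' Assign ChIP-seq peaks to promoter windows
#'
#' A peak counts for a promoter iff its score exceeds `min_neglog10p`
#' AND its overlap with the promoter window exceeds `min_overlap` — both
#' inequalities strict, so a peak at exactly -log10(p) = 3 or exactly
#' 100 bp of overlap is excluded under the defaults. The per-peak filter
#' is applied before any merging. At `level = "gene"` all transcript
#' promoters of a gene are merged: the gene is bound if any of its
#' promoters collects a passing peak, and passing hits are pooled across
#' its promoters.
#'
#' @param peaks Peak tibble (see [read_narrowpeak()]).
#' @param promoters Promoter tibble from [build_promoters()].
#' @param min_neglog10p Strict lower bound on the peak -log10 p-value
#'   (default 3).
#' @param min_overlap Strict lower bound on the peak/promoter overlap in
#'   bp (default 100).
#' @param level `"gene"` (merge transcript promoters by `gene_id`;
#'   the default) or `"promoter"` (one row per promoter, keyed by
#'   `parent_id`).
#' @return Annotation tibble with columns `id`, `bound`,
#'   `n_passing_peaks`, `total_overlap`, `best_peak_name`,
#'   `best_peak_score`, `best_peak_overlap`. The best peak is the
#'   passing hit with the highest score, ties broken by larger overlap
#'   then leftmost start.
#' @export
assign_peaks <- function(peaks, promoters, min_neglog10p = 3,
                         min_overlap = 100, level = c("gene", "promoter")) {
  level <- match.arg(level)
  if (min_neglog10p < 0 || min_overlap < 0) {
    tfm_abort("thresholds must be >= 0", "validation_error")
  }
  check_columns(promoters, c("parent_id", "gene_id", "chrom", "start", "end"),
                "promoter table")
  key <- if (level == "gene") promoters$gene_id else promoters$parent_id
  ids <- unique(key)

  hits <- overlap_pairs(promoters, peaks)
  if (nrow(hits) > 0) {
    hits <- hits |>
      mutate(
        id = key[.data$query],
        peak_name = peaks$name[.data$subject],
        peak_score = peaks$neg_log10_p[.data$subject],
        peak_start = peaks$start[.data$subject]
      ) |>
      filter(.data$peak_score > min_neglog10p, .data$overlap > min_overlap)
  } else {
    hits <- mutate(hits, id = character(), peak_name = character(),
                   peak_score = numeric(), peak_start = integer())
  }

  ann <- hits |>
    group_by(.data$id) |>
    arrange(dplyr::desc(.data$peak_score), dplyr::desc(.data$overlap),
            .data$peak_start, .by_group = TRUE) |>
    summarise(
      n_passing_peaks = dplyr::n(),
      total_overlap = sum(.data$overlap),
      best_peak_name = first(.data$peak_name),
      best_peak_score = first(.data$peak_score),
      best_peak_overlap = first(.data$overlap),
      .groups = "drop"
    )

  tibble(id = ids) |>
    left_join(ann, by = "id") |>
    mutate(
      n_passing_peaks = if_else(is.na(.data$n_passing_peaks), 0L,
                                as.integer(.data$n_passing_peaks)),
      total_overlap = if_else(is.na(.data$total_overlap), 0L,
                              as.integer(.data$total_overlap)),
      bound = .data$n_passing_peaks >= 1L,
      .after = "id"
    )
}

#' Annotate promoters with histone-mark presence
#'
#' A mark is called present on a promoter iff at least `min_overlap` bp
#' of the window overlap any peak of that mark (default: any overlap,
#' i.e. >= 1 bp).
#'
#' @param promoters Promoter tibble.
#' @param h3k27ac_peaks,h3k4me3_peaks Peak or interval tibbles for the
#'   two marks.
#' @param min_overlap Minimum overlap in bp for a mark call (>=, default 1).
#' @return `promoters` with logical columns `h3k27ac` and `h3k4me3`
#'   appended.
#' @export
annotate_marks <- function(promoters, h3k27ac_peaks, h3k4me3_peaks,
                           min_overlap = 1) {
  flag_for <- function(marks) {
    hit <- overlap_pairs(promoters, marks) |>
      filter(.data$overlap >= min_overlap)
    seq_len(nrow(promoters)) %in% hit$query
  }
  promoters |>
    mutate(h3k27ac = flag_for(h3k27ac_peaks),
           h3k4me3 = flag_for(h3k4me3_peaks))
}

#' Collapse promoter-level binding or mark flags to mature miRNAs
#'
#' A mature miRNA is bound (or marked) iff any promoter of any of its
#' precursors is, mirroring the gene-level merge over transcript
#' promoters.
#'
#' @param mature_promoters Output of [map_mature_to_promoters()], with
#'   any per-promoter logical columns added.
#' @param flags Character vector of logical column names to OR over.
#' @return Tibble with one row per `mature_id` and the OR-ed flags;
#'   unmapped matures get `FALSE`.
#' @export
collapse_mature_flags <- function(mature_promoters, flags) {
  mature_promoters |>
    group_by(.data$mature_id) |>
    summarise(across(all_of(flags), ~ any(.x, na.rm = TRUE)),
              .groups = "drop")
}
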