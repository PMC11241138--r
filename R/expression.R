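# Expression-level filters and transforms. Matrices travel as wide
# tibbles: a `feature_id` column plus one numeric column per sample.

# internal: split a wide matrix tibble into ids + numeric matrix
mat_parts <- function(x) {
  check_columns(x, "feature_id", "expression matrix")
  vals <- as.matrix(x[, setdiff(names(x), "feature_id"), drop = FALSE])
  rownames(vals) <- x$feature_id
  vals
}

#' Compute transcripts per million
#'
#' Per column: `rate_i = count_i / length_i`, then
#' `tpm_i = 1e6 * rate_i / sum(rates)`. Columns with zero total rate
#' come back all-zero rather than NaN.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param lengths Tibble (`feature_id`, `length`) of effective feature
#'   lengths in bp, all > 0; every counted feature must have one.
#' @return Wide TPM tibble with the same shape; non-degenerate columns
#'   sum to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  check_columns(lengths, c("feature_id", "length"), "`lengths`")
  vals <- mat_parts(counts)
  len <- lengths$length[match(counts$feature_id, lengths$feature_id)]
  if (anyNA(len)) {
    bad <- counts$feature_id[which(is.na(len))[1]]
    tfm_abort(sprintf("missing length for feature %s", bad), "validation_error")
  }
  if (any(len <= 0)) tfm_abort("feature lengths must be > 0", "validation_error")
  rates <- vals / len
  totals <- colSums(rates)
  tpm <- sweep(rates, 2, ifelse(totals > 0, totals, 1), "/") * 1e6
  out <- counts
  out[, colnames(vals)] <- as_tibble(tpm)
  out
}

# internal: features whose value strictly exceeds `min_value` in >= 1 sample
filter_expressed <- function(x, min_value) {
  vals <- mat_parts(x)
  x$feature_id[apply(vals > min_value, 1, any)]
}

#' Expressed-gene filter
#'
#' Keeps genes with TPM strictly greater than `min_tpm` in at least one
#' replicate; a gene at exactly the threshold in every sample is
#' dropped.
#'
#' @param tpm Wide TPM tibble from [compute_tpm()].
#' @param min_tpm Strict lower bound (default 1).
#' @return Character vector of expressed feature ids.
#' @export
filter_expressed_genes <- function(tpm, min_tpm = 1) {
  filter_expressed(tpm, min_tpm)
}

#' Expressed-miRNA filter
#'
#' Keeps mature miRNAs with a normalized count strictly greater than
#' `min_count` in at least one sample.
#'
#' @param norm Wide normalized-count tibble keyed by mature id.
#' @param min_count Strict lower bound (default 1).
#' @return Character vector of expressed mature ids.
#' @export
filter_expressed_mirnas <- function(norm, min_count = 1) {
  filter_expressed(norm, min_count)
}

#' Aggregate precursor-arm miRNA expression to mature miRNAs
#'
#' A mature miRNA quantified from several precursors gets, per sample,
#' the arithmetic mean of its per-precursor values.
#'
#' @param arm_counts Tibble with columns `precursor_id`, `mature_id`
#'   plus one numeric column per sample; each (precursor, mature) pair
#'   appears once.
#' @param expected_matures Optional character vector; aborts if any of
#'   these matures has zero precursor rows in `arm_counts`.
#' @return Wide tibble keyed by `feature_id` (= mature id), mature ids
#'   in first-appearance order.
#' @export
aggregate_mature_mirna <- function(arm_counts, expected_matures = NULL) {
  if (!is.null(expected_matures)) {
    absent <- setdiff(expected_matures, arm_counts$mature_id)
    if (length(absent) > 0) {
      tfm_abort(sprintf("mature miRNA(s) with zero precursor rows: %s",
                        paste(head(absent, 5), collapse = ", ")),
                "validation_error")
    }
  }
  check_columns(arm_counts, c("precursor_id", "mature_id"), "arm counts")
  samples <- setdiff(names(arm_counts), c("precursor_id", "mature_id"))
  if (length(samples) == 0L) {
    tfm_abort("arm counts need at least one sample column", "validation_error")
  }
  if (anyDuplicated(arm_counts[, c("precursor_id", "mature_id")]) > 0) {
    tfm_abort("duplicate (precursor, mature) rows in arm counts",
              "validation_error")
  }
  order_ids <- unique(arm_counts$mature_id)
  arm_counts |>
    group_by(.data$mature_id) |>
    summarise(across(all_of(samples), mean), .groups = "drop") |>
    arrange(match(.data$mature_id, order_ids)) |>
    rename(feature_id = "mature_id")
}
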