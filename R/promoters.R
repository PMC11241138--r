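#' Build putative promoter windows around TSSs
#'
#' Defines one promoter per TSS record as the symmetric window
#' `[tss - halfwidth, tss + halfwidth)` (0-based half-open, length
#' `2 * halfwidth` when unclipped), clipped to chromosome bounds. The
#' window is strand-independent; input order is preserved and identical
#' windows are not deduplicated.
#'
#' @param tss TSS catalog tibble (`feature_id`, `gene_id`, `chrom`,
#'   `tss`, `strand`, `biotype`), 0-based positions.
#' @param halfwidth Window half-width in bp (default 2500, giving the
#'   -2500..+2500 promoter definition).
#' @param chrom_sizes Named integer vector of chromosome lengths; every
#'   TSS chromosome must be present.
#' @return Promoter tibble: `parent_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, `halfwidth`.
#' @examples
#' tss <- tibble::tibble(feature_id = "tx1", gene_id = "g1", chrom = "chr1",
#'                       tss = 10000L, strand = "+", biotype = "protein_coding")
#' build_promoters(tss, chrom_sizes = c(chr1 = 50000L))
#' @export
build_promoters <- function(tss, halfwidth = 2500, chrom_sizes) {
  check_columns(tss, c("feature_id", "gene_id", "chrom", "tss", "strand",
                       "biotype"), "TSS catalog")
  if (halfwidth <= 0) tfm_abort("halfwidth must be > 0", "validation_error")
  missing_chrom <- setdiff(unique(tss$chrom), names(chrom_sizes))
  if (length(missing_chrom) > 0) {
    tfm_abort(sprintf("chromosome(s) absent from chrom_sizes: %s",
                      paste(missing_chrom, collapse = ", ")),
              "validation_error")
  }
  len <- unname(chrom_sizes[tss$chrom])
  if (any(tss$tss >= len)) {
    bad <- tss$feature_id[which(tss$tss >= len)[1]]
    tfm_abort(sprintf("TSS beyond chromosome length for feature %s", bad),
              "validation_error")
  }
  tibble(
    parent_id = tss$feature_id,
    gene_id = tss$gene_id,
    chrom = tss$chrom,
    start = pmax(0L, as.integer(tss$tss - halfwidth)),
    end = pmin(as.integer(len), as.integer(tss$tss + halfwidth)),
    strand = tss$strand,
    biotype = tss$biotype,
    halfwidth = as.integer(halfwidth)
  )
}

#' Map mature miRNAs to the promoters of their precursors
#'
#' A mature miRNA inherits the union of the promoters of all its
#' precursor (pri-miRNA) transcripts; binding and histone-mark calls at
#' the mature level are then ORs over this promoter set. Matures whose
#' precursors are absent from the promoter catalog map to zero
#' promoters and are flagged.
#'
#' @param matures Precursor-to-mature map tibble (`precursor_id`,
#'   `mature_id`, `arm`).
#' @param promoters Promoter tibble from [build_promoters()];
#'   pri-miRNA promoters are keyed by `parent_id == precursor_id`.
#' @return Tibble with one row per (mature, promoter) pair plus the
#'   promoter columns; matures with no promoter appear once with `NA`
#'   promoter fields and `unmapped = TRUE`.
#' @export
map_mature_to_promoters <- function(matures, promoters) {
  check_columns(matures, c("precursor_id", "mature_id"), "mature map")
  pri <- filter(promoters, .data$biotype == "pri_mirna")
  joined <- matures |>
    distinct(.data$mature_id, .data$precursor_id) |>
    left_join(pri, by = c(precursor_id = "parent_id"),
              relationship = "many-to-many") |>
    mutate(unmapped = is.na(.data$chrom))
  # a mature maps to the union over precursors: drop the NA rows of
  # matures that found at least one promoter through another precursor
  mapped_ids <- unique(joined$mature_id[!joined$unmapped])
  joined |>
    filter(!.data$unmapped | !(.data$mature_id %in% mapped_ids)) |>
    distinct(.data$mature_id, .data$precursor_id, .data$chrom, .data$start,
             .data$end, .keep_all = TRUE)
}
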