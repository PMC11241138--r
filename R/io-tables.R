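# TSV readers/writers for the tabular formats the pipeline touches:
# TSS catalogs, chromosome sizes, count matrices, DE tables, precursor-to-
# mature maps and miRNA target maps. All writers emit tab-separated,
# LF-terminated, UTF-8 files with a header row.

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) {
    tfm_abort(sprintf("%s file not found: %s", what, path), "io_error")
  }
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE))
}

write_tsv_plain <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSS catalog
#'
#' Expects columns `feature_id`, `gene_id`, `chrom`, `tss`, `strand`,
#' `biotype`. The catalog declares its coordinate base (`0` or `1`);
#' 1-based positions are converted so that all internal coordinates are
#' 0-based half-open.
#'
#' @param path TSV path.
#' @param coordinate_base 0 or 1; overridden by a `coordinate_base`
#'   column if the file carries one.
#' @param chrom_map Optional chromosome rename map (see
#'   [normalize_chrom()]).
#' @return Tibble with 0-based `tss` positions.
#' @export
read_tss_table <- function(path, coordinate_base = 0, chrom_map = NULL) {
  x <- read_tsv_strict(path, "TSS catalog")
  check_columns(x, c("feature_id", "gene_id", "chrom", "tss", "strand",
                     "biotype"), "TSS catalog")
  base <- if ("coordinate_base" %in% names(x)) x$coordinate_base else coordinate_base
  if (!all(base %in% c(0, 1))) {
    tfm_abort("coordinate_base must be 0 or 1", "validation_error")
  }
  x$tss <- as.integer(x$tss - as.integer(base))
  x$coordinate_base <- NULL
  if (any(x$tss < 0)) {
    tfm_abort("TSS positions must be >= 0 after base normalisation",
              "validation_error")
  }
  bad <- setdiff(unique(x$biotype), c("protein_coding", "ncRNA", "pri_mirna"))
  if (length(bad) > 0) {
    tfm_abort(sprintf("unknown biotype(s): %s", paste(bad, collapse = ", ")),
              "validation_error")
  }
  if (!is.null(chrom_map)) x$chrom <- normalize_chrom(x$chrom, chrom_map)
  x
}

#' Write a TSS catalog
#'
#' Positions are written 0-based with an explicit `coordinate_base`
#' column so the file round-trips through [read_tss_table()].
#'
#' @param tss TSS tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  out <- tss
  out$coordinate_base <- 0L
  write_tsv_plain(out, path)
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV (`chrom`, `length`), with or without header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- read_tsv_strict(path, "chrom sizes")
  if (!all(c("chrom", "length") %in% names(x))) {
    # headerless two-column file
    x <- as_tibble(read.delim(path, sep = "\t", header = FALSE,
                              col.names = c("chrom", "length"),
                              stringsAsFactors = FALSE))
  }
  setNames(as.integer(x$length), x$chrom)
}

#' Write chromosome sizes
#' @param sizes Named integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write_tsv_plain(tibble(chrom = names(sizes), length = unname(sizes)), path)
}

#' Read a count or abundance matrix
#'
#' First column is the feature id, remaining columns are samples.
#'
#' @param path TSV path.
#' @return Wide tibble: `feature_id` plus one numeric column per sample.
#' @export
read_count_matrix <- function(path) {
  x <- read_tsv_strict(path, "count matrix")
  if (names(x)[1] != "feature_id") names(x)[1] <- "feature_id"
  if (ncol(x) < 2L) {
    tfm_abort("count matrix needs at least one sample column", "parse_error")
  }
  vals <- as.matrix(x[, -1])
  if (any(is.na(vals))) {
    tfm_abort("count matrix contains non-numeric or missing values",
              "parse_error")
  }
  if (any(vals < 0)) {
    tfm_abort("count matrix contains negative values", "validation_error")
  }
  x
}

#' Write a count or abundance matrix
#' @param x Wide tibble (`feature_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) write_tsv_plain(x, path)

#' Read a differential-expression table
#'
#' Accepts tables produced by this package or by external tools
#' (e.g. DESeq2 exports reshaped to these columns): `feature_id`,
#' `log2fc`, `pvalue`, `fdr`, optionally `status`. Status is normally
#' recomputed from thresholds via [classify_de()].
#'
#' @param path TSV path.
#' @return DE tibble.
#' @export
read_de_table <- function(path) {
  x <- read_tsv_strict(path, "DE table")
  check_columns(x, c("feature_id", "log2fc", "pvalue", "fdr"), "DE table")
  ok <- is.na(x$fdr) | (x$fdr >= 0 & x$fdr <= 1)
  if (!all(ok)) tfm_abort("fdr values must lie in [0, 1]", "validation_error")
  x
}

#' Write a differential-expression table
#' @param de DE tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) write_tsv_plain(de, path)

#' Read a precursor-to-mature miRNA map
#'
#' @param path TSV with columns `precursor_id`, `mature_id`, `arm`.
#' @return Tibble, one row per (precursor, mature) pair.
#' @export
read_mature_map <- function(path) {
  x <- read_tsv_strict(path, "mature map")
  check_columns(x, c("precursor_id", "mature_id", "arm"), "mature map")
  bad <- setdiff(unique(x$arm), c("5p", "3p"))
  if (length(bad) > 0) {
    tfm_abort(sprintf("arm must be 5p or 3p, got: %s",
                      paste(bad, collapse = ", ")), "validation_error")
  }
  x
}

#' Write a precursor-to-mature miRNA map
#' @param x Mature-map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mature_map <- function(x, path) write_tsv_plain(x, path)

#' Read a miRNA target map
#'
#' TargetScan-style summary table keyed by mature miRNA name. Only the
#' `mature_id`/`gene_id` pair columns are required; a per-pair `score`
#' column is kept if present. Duplicate pairs are collapsed.
#'
#' @param path TSV path.
#' @return Tibble of unique (mature_id, gene_id) pairs.
#' @export
read_target_map <- function(path) {
  x <- read_tsv_strict(path, "target map")
  check_columns(x, c("mature_id", "gene_id"), "target map")
  distinct(x, .data$mature_id, .data$gene_id, .keep_all = TRUE)
}

#' Write a miRNA target map
#' @param x Target-map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(x, path) write_tsv_plain(x, path)
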