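#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak format into a peak tibble. Coordinates
#' are kept 0-based half-open exactly as in the file. Column 8
#' (-log10 p-value) becomes `neg_log10_p`; column 10 (summit offset from
#' `start`) becomes `summit_offset`, with the conventional `-1` sentinel
#' mapped to `NA`.
#'
#' @param path Path to a narrowPeak file.
#' @param chrom_map Optional named character vector used to normalise
#'   chromosome names at load time (e.g. `c("1" = "chr1")`), guarding
#'   against Ensembl/UCSC naming clashes.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `fold_enrichment`, `neg_log10_p`, `neg_log10_q`,
#'   `summit_offset`.
#' @export
read_narrowpeak <- function(path, chrom_map = NULL) {
  if (!file.exists(path)) {
    tfm_abort(sprintf("file not found: %s", path), "io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    bad <- which(nf < 10L)[1]
    tfm_abort(
      sprintf("narrowPeak parse error at line %d: expected >= 10 tab-separated fields, got %d",
              bad, nf[bad]),
      "parse_error"
    )
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  peaks <- tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = m[, 4],
    score = as.numeric(m[, 5]),
    strand = m[, 6],
    fold_enrichment = as.numeric(m[, 7]),
    neg_log10_p = as.numeric(m[, 8]),
    neg_log10_q = as.numeric(m[, 9]),
    summit_offset = as.integer(m[, 10])
  )
  if (anyNA(peaks$start) || anyNA(peaks$end)) {
    tfm_abort("narrowPeak parse error: non-numeric coordinates", "parse_error")
  }
  peaks$summit_offset[peaks$summit_offset < 0L] <- NA_integer_
  if (!is.null(chrom_map)) {
    peaks$chrom <- normalize_chrom(peaks$chrom, chrom_map)
  }
  validate_intervals(peaks)
  peaks
}

#' Write peaks as ENCODE narrowPeak
#'
#' Inverse of [read_narrowpeak()]: emits the 10-column tab-separated,
#' LF-terminated format, with `NA` summit offsets written as `-1`.
#'
#' @param peaks Peak tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks)
  summit <- peaks$summit_offset %||% rep(NA_integer_, nrow(peaks))
  summit <- ifelse(is.na(summit), -1L, summit)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
    peaks$chrom, peaks$start, peaks$end,
    peaks$name %||% ".",
    format_num(peaks$score %||% 0),
    peaks$strand %||% ".",
    format_num(peaks$fold_enrichment %||% 0),
    format_num(peaks$neg_log10_p),
    format_num(peaks$neg_log10_q %||% -1),
    summit
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# internal: full-precision, non-scientific numeric formatting for writers
format_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

empty_peaks <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    fold_enrichment = numeric(), neg_log10_p = numeric(),
    neg_log10_q = numeric(), summit_offset = integer()
  )
}

#' Write intervals as BED6
#'
#' @param x Interval tibble with at least `chrom`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  validate_intervals(x)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s",
    x$chrom, x$start, x$end,
    x$name %||% ".",
    format_num(x$score %||% 0),
    x$strand %||% "."
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a BED6 file
#'
#' @inheritParams read_narrowpeak
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path, chrom_map = NULL) {
  if (!file.exists(path)) {
    tfm_abort(sprintf("file not found: %s", path), "io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1]
    tfm_abort(sprintf("BED6 parse error at line %d: expected >= 6 fields", bad),
              "parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  x <- tibble(
    chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    name = m[, 4], score = as.numeric(m[, 5]), strand = m[, 6]
  )
  if (!is.null(chrom_map)) x$chrom <- normalize_chrom(x$chrom, chrom_map)
  validate_intervals(x)
  x
}

#' Normalise chromosome names
#'
#' Applies an explicit rename map at the reader boundary so that all
#' downstream matching can use exact string equality.
#'
#' @param chrom Character vector of chromosome names.
#' @param chrom_map Named character vector, `c(old = "new")`.
#' @return Renamed character vector.
#' @export
normalize_chrom <- function(chrom, chrom_map) {
  hit <- chrom %in% names(chrom_map)
  chrom[hit] <- unname(chrom_map[chrom[hit]])
  chrom
}
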