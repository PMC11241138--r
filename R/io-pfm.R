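#' Construct a position frequency matrix object
#'
#' @param counts 4 x L numeric matrix of non-negative base counts with
#'   rows A, C, G, T.
#' @param matrix_id Matrix label (e.g. a JASPAR accession-style id).
#' @param background Base frequencies (A, C, G, T) summing to 1;
#'   defaults to uniform.
#' @param pseudocount Additive constant distributed by background when
#'   converting to log-odds (see [pwm_log_odds()]).
#' @return Object of class `pfm_matrix`.
#' @export
pfm_matrix <- function(counts, matrix_id = "PFM",
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) tfm_abort("PFM must have 4 rows (A, C, G, T)", "format_error")
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) tfm_abort("PFM counts must be >= 0", "format_error")
  if (any(colSums(counts) <= 0)) {
    tfm_abort("every PFM column must have a positive total", "format_error")
  }
  background <- unname(background)
  if (abs(sum(background) - 1) > 1e-9) {
    tfm_abort("background frequencies must sum to 1", "format_error")
  }
  structure(
    list(matrix_id = matrix_id, counts = counts,
         background = setNames(background, c("A", "C", "G", "T")),
         pseudocount = pseudocount),
    class = "pfm_matrix"
  )
}

#' @export
print.pfm_matrix <- function(x, ...) {
  cat(sprintf("<pfm_matrix %s: %d positions, pseudocount %g>\n",
              x$matrix_id, ncol(x$counts), x$pseudocount))
  print(x$counts)
  invisible(x)
}

#' Read a JASPAR-format PFM file
#'
#' Parses the JASPAR 2016+ text format: a `>ID name` header line
#' followed by four rows `A [ ... ]`, `C [ ... ]`, `G [ ... ]`,
#' `T [ ... ]`. Background defaults to uniform 0.25.
#'
#' @param path Path to a JASPAR PFM file.
#' @inheritParams pfm_matrix
#' @return `pfm_matrix` object.
#' @export
read_pfm <- function(path, pseudocount = 0.8) {
  if (!file.exists(path)) {
    tfm_abort(sprintf("file not found: %s", path), "io_error")
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 5L || !startsWith(lines[1], ">")) {
    tfm_abort("not a JASPAR PFM: expected '>ID name' header plus 4 base rows",
              "format_error")
  }
  header <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[2:5], function(l) {
    base <- sub("^([ACGT]).*", "\\1", l)
    rest <- sub("^[ACGT]", "", l)
    nums <- regmatches(rest, gregexpr("[0-9.eE+-]+", rest))[[1]]
    list(base = base, counts = as.numeric(nums))
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!identical(bases, c("A", "C", "G", "T"))) {
    tfm_abort("JASPAR PFM rows must appear in A, C, G, T order", "format_error")
  }
  lens <- vapply(rows, function(r) length(r$counts), integer(1))
  if (length(unique(lens)) != 1L || lens[1] == 0L) {
    tfm_abort("JASPAR PFM rows have unequal (or zero) length", "format_error")
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  pfm_matrix(counts, matrix_id = header[1], pseudocount = pseudocount)
}

#' Write a PFM in JASPAR text format
#'
#' @param pfm `pfm_matrix` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pfm_matrix"))
  rows <- vapply(c("A", "C", "G", "T"), function(b) {
    sprintf("%s  [ %s ]", b,
            paste(format_num(pfm$counts[b, ]), collapse = " "))
  }, character(1))
  writeLines(c(paste0(">", pfm$matrix_id), rows), path, sep = "\n")
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Thin wrapper over Biostrings FASTA input returning a plain named
#' character vector keyed by the promoter's parent feature id.
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_promoter_fasta <- function(path) {
  if (!file.exists(path)) {
    tfm_abort(sprintf("file not found: %s", path), "io_error")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write promoter sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, format = "fasta"
  )
  invisible(path)
}
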