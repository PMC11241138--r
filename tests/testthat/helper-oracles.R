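# Independent brute-force oracles. These deliberately avoid the package's
# code paths: per-base enumeration, nested loops, direct formulas.

# overlap by counting covered bases one at a time
bf_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  bases_a <- seq(a$start, a$end - 1L)
  bases_b <- seq(b$start, b$end - 1L)
  length(intersect(bases_a, bases_b))
}

# all-pairs peak-to-promoter assignment by explicit loops
bf_assign <- function(peaks, promoters, min_p, min_ov, key) {
  res <- list()
  for (k in unique(key)) res[[k]] <- 0L
  for (i in seq_len(nrow(promoters))) {
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != promoters$chrom[i]) next
      ov <- min(peaks$end[j], promoters$end[i]) -
        max(peaks$start[j], promoters$start[i])
      if (ov > min_ov && peaks$neg_log10_p[j] > min_p) {
        res[[key[i]]] <- res[[key[i]]] + 1L
      }
    }
  }
  res
}

# histone-mark flag by explicit pairwise check
bf_mark_flags <- function(promoters, marks, min_ov = 1) {
  out <- logical(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    for (j in seq_len(nrow(marks))) {
      if (marks$chrom[j] != promoters$chrom[i]) next
      ov <- min(marks$end[j], promoters$end[i]) -
        max(marks$start[j], promoters$start[i])
      if (ov >= min_ov) { out[i] <- TRUE; break }
    }
  }
  out
}

bf_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# exhaustive window scan, scoring each window directly from the matrix
bf_scan <- function(sequence, pwm, rel_threshold) {
  L <- ncol(pwm)
  n <- nchar(sequence)
  maxs <- sum(apply(pwm, 2, max))
  mins <- sum(apply(pwm, 2, min))
  hits <- list()
  if (n < L) return(data.frame(position = integer(), strand = character(),
                               score = double(), rel_score = double()))
  for (i in 0:(n - L)) {
    win <- substr(sequence, i + 1, i + L)
    for (st in c("+", "-")) {
      w <- if (st == "+") win else bf_revcomp(win)
      chars <- strsplit(w, "")[[1]]
      if (any(!chars %in% c("A", "C", "G", "T"))) next
      sc <- 0
      for (j in 1:L) sc <- sc + pwm[chars[j], j]
      rel <- if (maxs > mins) (sc - mins) / (maxs - mins) else 1
      if (rel >= rel_threshold) {
        hits[[length(hits) + 1]] <-
          data.frame(position = i, strand = st, score = sc, rel_score = rel)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(position = integer(), strand = character(),
                               score = double(), rel_score = double())
  else out[order(out$position, out$strand), ]
}

# literal step-up definition of Benjamini-Hochberg
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    ks <- i:m
    adj[o[i]] <- min(1, min(p[o[ks]] * m / ks))
  }
  adj
}

# double loop over the target map applying the sign-opposition rule
bf_anticorr <- function(dems, degs, targets) {
  out <- list()
  for (r in seq_len(nrow(targets))) {
    m <- targets$mature_id[r]; g <- targets$gene_id[r]
    im <- match(m, dems$feature_id); ig <- match(g, degs$feature_id)
    if (is.na(im) || is.na(ig)) next
    fm <- dems$log2fc[im]; fg <- degs$log2fc[ig]
    if ((fm > 0 && fg < 0) || (fm < 0 && fg > 0)) {
      out[[length(out) + 1]] <- data.frame(mature_id = m, gene_id = g)
    }
  }
  if (length(out) == 0) data.frame(mature_id = character(),
                                   gene_id = character())
  else do.call(rbind, out)
}

# --- random-instance generators -------------------------------------

rand_peaks <- function(n, chroms = c("c1", "c2"), max_pos = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(300, n, replace = TRUE),
    name = paste0("pk", seq_len(n)),
    score = 0,
    strand = ".",
    fold_enrichment = round(stats::runif(n, 1, 20), 3),
    neg_log10_p = round(stats::runif(n, 0, 10), 3),
    neg_log10_q = round(stats::runif(n, 0, 8), 3),
    summit_offset = NA_integer_
  )
}

rand_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(100, n, replace = TRUE)
  )
}

rand_promoters <- function(n, chroms = c("c1", "c2"), max_pos = 2000) {
  x <- rand_intervals(n, chroms, max_pos)
  x$end <- x$start + sample.int(400, n, replace = TRUE)
  x$parent_id <- paste0("tx", seq_len(n))
  x$gene_id <- paste0("g", sample.int(max(1, n %/% 2), n, replace = TRUE))
  x$strand <- "+"
  x$biotype <- "protein_coding"
  x$halfwidth <- 200L
  x
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small, fast simulated study for pipeline-level tests
small_config <- function(seed = 7, ...) {
  simulation_config(n_genes = 300, n_mirnas = 40, seed = seed, ...)
}
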