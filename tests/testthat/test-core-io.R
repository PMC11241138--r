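test_that("narrowPeak fields map onto the peak record", {
  path <- withr::local_tempfile()
  writeLines("chr1\t100\t300\tpk1\t0\t.\t5.0\t7.2\t6.1\t50", path)
  pk <- read_narrowpeak(path)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$chrom, "chr1")
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 300L)
  expect_equal(pk$neg_log10_p, 7.2)
  expect_equal(pk$summit_offset, 50L)
  expect_equal(pk$fold_enrichment, 5.0)
})

test_that("empty and malformed narrowPeak inputs behave per contract", {
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_equal(nrow(read_narrowpeak(empty)), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t100\t300\tpk1\t0\t.\t5.0\t7.2\t6.1\t50",
               "chr1\t100\t300"), bad)
  expect_error(read_narrowpeak(bad), "line 2", class = "tfmirnet_parse_error")

  neg <- withr::local_tempfile()
  writeLines("chr1\t-5\t300\tpk1\t0\t.\t5.0\t7.2\t6.1\t50", neg)
  expect_error(read_narrowpeak(neg), class = "tfmirnet_validation_error")
})

test_that("narrowPeak writer round-trips random peaks", {
  set.seed(11)
  peaks <- rand_peaks(100)
  peaks$summit_offset[1:50] <- 5L
  path <- withr::local_tempfile()
  write_narrowpeak(peaks, path)
  expect_equal(as.data.frame(read_narrowpeak(path)), as.data.frame(peaks))
})

test_that("BED6 writer round-trips and chrom maps rename at the boundary", {
  set.seed(12)
  x <- rand_intervals(30, chroms = c("1", "chr2"))
  x$name <- paste0("n", seq_len(30))
  x$score <- round(runif(30), 3)
  x$strand <- sample(c("+", "-", "."), 30, replace = TRUE)
  path <- withr::local_tempfile()
  write_bed6(x, path)
  y <- read_bed6(path, chrom_map = c("1" = "chr1"))
  expect_setequal(unique(y$chrom), intersect(c("chr1", "chr2"), unique(y$chrom)))
  y2 <- read_bed6(path)
  expect_equal(as.data.frame(y2), as.data.frame(x))
})

test_that("interval_overlap matches examples and the per-base oracle", {
  a <- tibble::tibble(chrom = "c1", start = 100L, end = 300L)
  b <- tibble::tibble(chrom = "c1", start = 200L, end = 400L)
  expect_equal(interval_overlap(a, b), 100L)
  # half-open abutment
  expect_equal(interval_overlap(
    tibble::tibble(chrom = "c1", start = 100L, end = 200L),
    tibble::tibble(chrom = "c1", start = 200L, end = 300L)), 0L)
  # different chromosome
  expect_equal(interval_overlap(
    a, tibble::tibble(chrom = "c2", start = 100L, end = 300L)), 0L)

  set.seed(21)
  x <- rand_intervals(200)
  y <- rand_intervals(200)
  got <- interval_overlap(x, y)
  expect_equal(interval_overlap(y, x), got)  # symmetry
  for (i in seq_len(200)) {
    expect_equal(got[i], bf_overlap(x[i, ], y[i, ]))
  }
  expect_equal(interval_overlap(x, x), x$end - x$start)  # self-overlap
})

test_that("JASPAR PFM parsing, errors, and round-trip", {
  one <- withr::local_tempfile()
  writeLines(c(">M1 test", "A [4]", "C [0]", "G [0]", "T [0]"), one)
  pfm <- read_pfm(one)
  expect_equal(dim(pfm$counts), c(4L, 1L))
  expect_equal(unname(pfm$counts["A", 1]), 4)
  expect_equal(unname(pfm$background), rep(0.25, 4))

  hdr <- withr::local_tempfile()
  writeLines(">M1 test", hdr)
  expect_error(read_pfm(hdr), class = "tfmirnet_format_error")

  uneven <- withr::local_tempfile()
  writeLines(c(">M1", "A [1 2]", "C [1]", "G [1 2]", "T [1 2]"), uneven)
  expect_error(read_pfm(uneven), class = "tfmirnet_format_error")

  set.seed(31)
  rnd <- pfm_matrix(matrix(sample(0:50, 32, replace = TRUE) + 1, nrow = 4),
                    matrix_id = "RND1")
  path <- withr::local_tempfile()
  write_pfm(rnd, path)
  back <- read_pfm(path)
  expect_equal(back$matrix_id, "RND1")
  expect_equal(unname(back$counts), unname(rnd$counts))
})

test_that("TSS tables normalise their coordinate base on load", {
  tss <- tibble::tibble(
    feature_id = c("t1", "t2"), gene_id = c("g1", "g2"),
    chrom = "chr1", tss = c(1000L, 2000L), strand = "+",
    biotype = "protein_coding"
  )
  p0 <- withr::local_tempfile()
  write_tss_table(tss, p0)
  expect_equal(read_tss_table(p0)$tss, c(1000L, 2000L))

  # a 1-based export shifts down by one on load
  p1 <- withr::local_tempfile()
  one_based <- tss
  one_based$tss <- one_based$tss + 1L
  one_based$coordinate_base <- 1L
  write.table(one_based, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_tss_table(p1)$tss, c(1000L, 2000L))

  bad <- tss
  bad$biotype <- "weird"
  pb <- withr::local_tempfile()
  write_tss_table(bad, pb)
  expect_error(read_tss_table(pb), class = "tfmirnet_validation_error")
})

test_that("count matrices and DE tables enforce their contracts", {
  cm <- tibble::tibble(feature_id = c("a", "b"), s1 = c(1, 2), s2 = c(0, 5))
  p <- withr::local_tempfile()
  write_count_matrix(cm, p)
  expect_equal(as.data.frame(read_count_matrix(p)), as.data.frame(cm))

  neg <- cm; neg$s1[1] <- -1
  pn <- withr::local_tempfile()
  write_count_matrix(neg, pn)
  expect_error(read_count_matrix(pn), class = "tfmirnet_validation_error")

  de <- tibble::tibble(feature_id = "a", log2fc = 1.5, pvalue = 0.01,
                       fdr = 1.2)
  pd <- withr::local_tempfile()
  write_de_table(de, pd)
  expect_error(read_de_table(pd), class = "tfmirnet_validation_error")
})
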