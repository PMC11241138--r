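#' Collected analysis thresholds
#'
#' One configuration object holding every cut-off the pipeline applies:
#' the promoter half-width, the peak score/overlap bounds, the
#' gene-level (|log2FC| > 1, FDR < 0.05) and miRNA-level
#' (|log2FC| > 0.5, FDR < 0.1) significance thresholds, the expressed
#' filters (TPM > 1; normalized count > 1) and the PWM relative-score
#' threshold.
#'
#' @param halfwidth Promoter half-width (bp).
#' @param min_neglog10p Strict peak -log10(p) bound.
#' @param min_overlap Strict peak/promoter overlap bound (bp).
#' @param gene_lfc,gene_fdr DEG thresholds (strict |log2FC| >, FDR <).
#' @param mirna_lfc,mirna_fdr DEM thresholds.
#' @param min_tpm Expressed-gene TPM bound (strict >).
#' @param min_mirna_count Expressed-miRNA normalized-count bound.
#' @param pwm_rel_threshold Motif-hit relative score (>=).
#' @return List of class `tfmirnet_thresholds`.
#' @export
default_thresholds <- function(halfwidth = 2500, min_neglog10p = 3,
                               min_overlap = 100, gene_lfc = 1,
                               gene_fdr = 0.05, mirna_lfc = 0.5,
                               mirna_fdr = 0.1, min_tpm = 1,
                               min_mirna_count = 1,
                               pwm_rel_threshold = 0.80) {
  th <- list(halfwidth = halfwidth, min_neglog10p = min_neglog10p,
             min_overlap = min_overlap, gene_lfc = gene_lfc,
             gene_fdr = gene_fdr, mirna_lfc = mirna_lfc,
             mirna_fdr = mirna_fdr, min_tpm = min_tpm,
             min_mirna_count = min_mirna_count,
             pwm_rel_threshold = pwm_rel_threshold)
  if (any(unlist(th) <= 0)) {
    tfm_abort("all thresholds must be positive", "validation_error")
  }
  if (gene_fdr >= 1 || mirna_fdr >= 1) {
    tfm_abort("FDR thresholds must lie in (0, 1)", "validation_error")
  }
  structure(th, class = "tfmirnet_thresholds")
}

#' Median-of-ratios library size factors
#'
#' Per sample, the median over features of the ratio between the
#' sample's count and the feature's geometric mean across samples;
#' features with a zero in any sample are excluded from the median
#' (their geometric mean is zero).
#'
#' @param counts Wide raw-count tibble (`feature_id` + sample columns).
#' @return Tibble (`sample_id`, `size_factor`).
#' @export
size_factors <- function(counts) {
  vals <- mat_parts(counts)
  keep <- rowSums(vals == 0) == 0
  if (!any(keep)) {
    tfm_abort(paste0(
      "no feature has nonzero counts in every sample; ",
      "median-of-ratios needs at least one — consider a pseudo-reference ",
      "(e.g. counts + 1) upstream"
    ), "validation_error")
  }
  loggeo <- rowMeans(log(vals[keep, , drop = FALSE]))
  sf <- apply(vals[keep, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - loggeo))
  })
  tibble(sample_id = colnames(vals), size_factor = unname(sf))
}

# internal: size-factor-normalized count matrix
normalize_counts <- function(counts, sf = size_factors(counts)) {
  vals <- mat_parts(counts)
  vals <- sweep(vals, 2, sf$size_factor[match(colnames(vals), sf$sample_id)], "/")
  out <- counts
  out[, colnames(vals)] <- as_tibble(vals)
  out
}

#' Two-condition differential-expression stand-in test
#'
#' A deliberately simple, documented stand-in for a dedicated
#' count-model DE tool, for the synthetic path (externally produced DE
#' tables are accepted anywhere this package consumes DE results). After
#' median-of-ratios normalization, the log2 fold change is
#' `log2((mean_silenced + c0) / (mean_control + c0))` on normalized
#' counts — positive when expression rises upon silencing. P-values come
#' from, per feature:
#'
#' * `"lognormal_t"`: a pooled two-sample t-test on
#'   `log2(normalized + c0)`;
#' * `"lognormal_limma"`: the limma moderated t on the same transformed
#'   matrix, which shares variance information across features and is
#'   the sensible choice at 2 replicates per condition.
#'
#' With fewer than 2 replicates in either condition only the fold change
#' is computed and p is `NA`. Features with zero variance in both groups
#' get p = 1 when the group means coincide and `NA` otherwise
#' (no within-group evidence to test against).
#'
#' @param counts Wide raw-count tibble.
#' @param condition Tibble (`sample_id`, `condition`) with conditions
#'   `control` and `silenced`.
#' @param method `"lognormal_t"` (default) or `"lognormal_limma"`.
#' @param c0 Pseudo-count for the log transform (default 0.5).
#' @return Tibble (`feature_id`, `log2fc`, `pvalue`), one row per
#'   feature, input order; deterministic given its inputs.
#' @export
de_test <- function(counts, condition, method = "lognormal_t", c0 = 0.5) {
  methods <- c("lognormal_t", "lognormal_limma")
  if (!method %in% methods) {
    tfm_abort(sprintf("unknown method '%s'; available: %s", method,
                      paste(methods, collapse = ", ")), "validation_error")
  }
  check_columns(condition, c("sample_id", "condition"), "`condition`")
  if (!all(condition$condition %in% c("control", "silenced"))) {
    tfm_abort("conditions must be 'control' or 'silenced'", "validation_error")
  }
  norm <- normalize_counts(counts)
  vals <- mat_parts(norm)
  cond <- condition$condition[match(colnames(vals), condition$sample_id)]
  if (anyNA(cond)) {
    tfm_abort("every sample column needs a condition label", "validation_error")
  }
  ctl <- vals[, cond == "control", drop = FALSE]
  sil <- vals[, cond == "silenced", drop = FALSE]
  log2fc <- log2((rowMeans(sil) + c0) / (rowMeans(ctl) + c0))

  n1 <- ncol(ctl); n2 <- ncol(sil)
  if (n1 < 2L || n2 < 2L) {
    return(tibble(feature_id = counts$feature_id, log2fc = log2fc,
                  pvalue = NA_real_))
  }
  lctl <- log2(ctl + c0)
  lsil <- log2(sil + c0)

  if (method == "lognormal_limma") {
    design <- cbind(intercept = 1, silenced = c(rep(0, n1), rep(1, n2)))
    fit <- limma::lmFit(cbind(lctl, lsil), design)
    fit <- limma::eBayes(fit)
    pvalue <- fit$p.value[, "silenced"]
  } else {
    m1 <- rowMeans(lctl); m2 <- rowMeans(lsil)
    v1 <- apply(lctl, 1, stats::var); v2 <- apply(lsil, 1, stats::var)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m2 - m1) / se
    pvalue <- 2 * pt(-abs(tstat), df)
    zero_var <- sp2 == 0
    pvalue[zero_var & m1 == m2] <- 1
    pvalue[zero_var & m1 != m2] <- NA_real_
  }
  tibble(feature_id = counts$feature_id, log2fc = unname(log2fc),
         pvalue = unname(pvalue))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wrapping the stock BH implementation):
#' sorted ascending, `adj(i) = min over k >= i of p(k) * m / k`, clipped
#' at 1, with the original order restored. `NA` values pass through.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of adjusted values in [0, 1].
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) {
    tfm_abort("p-values must lie in [0, 1]", "validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Classify differential-expression status
#'
#' `up` iff `log2fc > lfc_thresh` and `fdr < fdr_thresh`; `down` iff
#' `log2fc < -lfc_thresh` and `fdr < fdr_thresh`; otherwise `ns`. All
#' inequalities strict, so a feature at exactly the fold-change or FDR
#' threshold is not significant. Missing `fdr` columns are computed from
#' `pvalue` via [bh_adjust()]; `NA` statistics classify as `ns`.
#'
#' @param results DE tibble (`feature_id`, `log2fc`, and `fdr` or
#'   `pvalue`).
#' @param lfc_thresh Absolute log2 fold-change threshold (strict >).
#' @param fdr_thresh FDR threshold (strict <).
#' @return `results` with `fdr` and `status` columns.
#' @export
classify_de <- function(results, lfc_thresh, fdr_thresh) {
  if (lfc_thresh <= 0 || fdr_thresh <= 0) {
    tfm_abort("thresholds must be positive", "validation_error")
  }
  check_columns(results, c("feature_id", "log2fc"), "DE results")
  if (!"fdr" %in% names(results)) {
    check_columns(results, "pvalue", "DE results")
    results$fdr <- bh_adjust(results$pvalue)
  }
  results |>
    mutate(status = dplyr::case_when(
      is.na(.data$log2fc) | is.na(.data$fdr) ~ "ns",
      .data$log2fc > lfc_thresh & .data$fdr < fdr_thresh ~ "up",
      .data$log2fc < -lfc_thresh & .data$fdr < fdr_thresh ~ "down",
      TRUE ~ "ns"
    ))
}
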