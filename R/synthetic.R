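#' Synthetic study configuration
#'
#' Parameters of the planted-truth generator. Defaults emulate the study
#' design this pipeline targets: a two-condition knockdown contrast with
#' 2 mRNA-seq and 3 miRNA-seq replicates per condition, negative
#' binomial counts (variance `mu + dispersion * mu^2`) over log-normal
#' baseline means, roughly half of gene promoters and 45% of pri-miRNA
#' promoters TF-bound, ~4% of genes and ~5% of matures differentially
#' expressed, and miRNA-mediated repression coupling that makes planted
#' miRNA/target pairs sign-opposed in expectation.
#'
#' @param n_genes,n_mirnas Number of protein-coding genes and pri-miRNAs.
#' @param n_mrna_reps,n_mirna_reps Replicates per condition.
#' @param nb_dispersion NB dispersion alpha (> 0).
#' @param mean_log_mu,mean_log_sd Log-normal law (natural-log scale) for
#'   baseline means.
#' @param frac_de_genes,frac_de_mirnas Planted DE fractions.
#' @param effect_min,effect_max Planted |log2FC| effect range (uniform).
#' @param frac_bound_genes,frac_bound_mirnas TF-bound promoter fractions.
#' @param frac_two_tx Fraction of genes given a second transcript
#'   promoter (overlapping window, exercising gene-level merging).
#' @param frac_multi_precursor Fraction of mature miRNAs fed by two
#'   precursors (exercising mature-level averaging).
#' @param targets_per_dem Planted repression targets per bound DEM.
#' @param repression_lfc Magnitude of the repression-induced log2FC on
#'   target genes (sign opposes the miRNA's effect).
#' @param decoy_peak_rate Decoy peaks per true peak; decoys violate at
#'   least one of the score/overlap thresholds or fall outside
#'   promoters.
#' @param decoy_targets_per_mirna Random decoy pairs per mature in the
#'   target map.
#' @param frac_silent_genes Fraction of genes given a near-zero baseline
#'   (fail the expressed filter).
#' @param halfwidth Promoter half-width (bp).
#' @param peak_width True TF peak width (bp), centred on the TSS.
#' @param min_de_mean Minimum baseline mean for a feature to be eligible
#'   for a planted effect.
#' @param library_size_sd Log-sd of per-sample library-size factors.
#' @param seed Integer seed; one global seed drives named substreams so
#'   each generator is independently reproducible.
#' @return List of class `tfmirnet_sim_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_mirnas = 100,
                              n_mrna_reps = 2, n_mirna_reps = 3,
                              nb_dispersion = 0.1,
                              mean_log_mu = log(300), mean_log_sd = 1.2,
                              frac_de_genes = 0.04, frac_de_mirnas = 0.05,
                              effect_min = 1.2, effect_max = 3,
                              frac_bound_genes = 0.5,
                              frac_bound_mirnas = 0.45,
                              frac_two_tx = 0.3,
                              frac_multi_precursor = 0.05,
                              targets_per_dem = 5, repression_lfc = 1.5,
                              decoy_peak_rate = 0.5,
                              decoy_targets_per_mirna = 20,
                              frac_silent_genes = 0.1,
                              halfwidth = 2500, peak_width = 400,
                              min_de_mean = 20, library_size_sd = 0.1,
                              seed = 1) {
  cfg <- as.list(environment())
  if (n_genes < 0 || n_mirnas < 0 || n_mrna_reps < 1 || n_mirna_reps < 1) {
    tfm_abort("feature and replicate counts must be positive",
              "validation_error")
  }
  if (nb_dispersion <= 0) tfm_abort("dispersion must be > 0", "validation_error")
  structure(cfg, class = "tfmirnet_sim_config")
}

# internal: derive a reproducible substream seed from the global seed.
# Kept below 2^31 via modular arithmetic.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Generate the synthetic annotation bundle
#'
#' Places genes (with 1-2 transcript promoters each) and pri-miRNAs on
#' two synthetic chromosomes with spacing wide enough that promoter
#' windows never collide, and builds a precursor-to-mature map in which
#' every precursor feeds a -5p/-3p pair and a configurable fraction of
#' matures is fed by two precursors.
#'
#' @param cfg `tfmirnet_sim_config`.
#' @return List: `tss` (TSS catalog tibble), `chrom_sizes` (named
#'   vector), `mature_map` (precursor/mature/arm tibble).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "tfmirnet_sim_config"))
  set.seed(substream_seed(cfg$seed, "annotation"))
  spacing <- as.integer(4 * cfg$halfwidth)
  gap <- as.integer(2 * cfg$halfwidth)

  place <- function(n, chrom) {
    if (n == 0) return(tibble(chrom = character(), tss = integer()))
    pos <- gap + spacing * (seq_len(n) - 1L) +
      sample.int(cfg$halfwidth, n, replace = TRUE)
    tibble(chrom = chrom, tss = as.integer(pos))
  }

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  gpos <- place(cfg$n_genes, "chrS1")
  two_tx <- runif(cfg$n_genes) < cfg$frac_two_tx
  tss_gene <- bind_rows(
    tibble(feature_id = paste0(gene_ids, ".t1"), gene_id = gene_ids,
           chrom = gpos$chrom, tss = gpos$tss,
           strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
           biotype = "protein_coding"),
    tibble(feature_id = paste0(gene_ids[two_tx], ".t2"),
           gene_id = gene_ids[two_tx],
           chrom = gpos$chrom[two_tx],
           tss = gpos$tss[two_tx] + 1000L,
           strand = "+", biotype = "protein_coding")
  )

  pri_ids <- sprintf("pri-M%03d", seq_len(cfg$n_mirnas))
  mpos <- place(cfg$n_mirnas, "chrS2")
  tss_mir <- tibble(feature_id = pri_ids, gene_id = pri_ids,
                    chrom = mpos$chrom, tss = mpos$tss,
                    strand = sample(c("+", "-"), cfg$n_mirnas, replace = TRUE),
                    biotype = "pri_mirna")

  # every precursor feeds a 5p/3p mature pair; a fraction of matures is
  # additionally fed by a second precursor (averaging path)
  mature_map <- bind_rows(
    tibble(precursor_id = pri_ids,
           mature_id = sprintf("miR-%03d-5p", seq_len(cfg$n_mirnas)),
           arm = "5p"),
    tibble(precursor_id = pri_ids,
           mature_id = sprintf("miR-%03d-3p", seq_len(cfg$n_mirnas)),
           arm = "3p")
  )
  if (cfg$n_mirnas >= 2) {
    n_multi <- max(0L, round(cfg$frac_multi_precursor * cfg$n_mirnas))
    if (n_multi > 0) {
      pick <- sample(seq_len(cfg$n_mirnas), n_multi)
      donor <- vapply(pick, function(i) {
        sample(setdiff(seq_len(cfg$n_mirnas), i), 1)
      }, integer(1))
      mature_map <- bind_rows(
        mature_map,
        tibble(precursor_id = pri_ids[donor],
               mature_id = sprintf("miR-%03d-5p", pick), arm = "5p")
      )
    }
  }

  # chrS3 carries no annotated feature; intergenic decoy peaks live there
  chrom_sizes <- c(
    chrS1 = gap + spacing * max(1L, cfg$n_genes) + gap,
    chrS2 = gap + spacing * max(1L, cfg$n_mirnas) + gap,
    chrS3 = 1000000L
  )
  list(tss = bind_rows(tss_gene, tss_mir) |> arrange(.data$chrom, .data$tss),
       chrom_sizes = chrom_sizes, mature_map = mature_map)
}

# internal: sample the planted truth (bound sets, DE labels, repression
# edges) from the annotation
generate_truth <- function(cfg, annotation, baseline_gene, baseline_mature) {
  set.seed(substream_seed(cfg$seed, "truth"))
  gene_ids <- unique(annotation$tss$gene_id[
    annotation$tss$biotype == "protein_coding"])
  pri_ids <- annotation$tss$feature_id[annotation$tss$biotype == "pri_mirna"]
  mature_ids <- unique(annotation$mature_map$mature_id)

  bound_genes <- sort(sample(gene_ids,
                             round(cfg$frac_bound_genes * length(gene_ids))))
  bound_pri <- sort(sample(pri_ids,
                           round(cfg$frac_bound_mirnas * length(pri_ids))))
  # matures inherit binding from any precursor
  bound_matures <- sort(unique(annotation$mature_map$mature_id[
    annotation$mature_map$precursor_id %in% bound_pri]))

  draw_effects <- function(ids, frac, eligible) {
    n <- round(frac * length(ids))
    pool <- intersect(ids, eligible)
    chosen <- sample(pool, min(n, length(pool)))
    setNames(sample(c(-1, 1), length(chosen), replace = TRUE) *
               runif(length(chosen), cfg$effect_min, cfg$effect_max),
             chosen)
  }
  eligible_genes <- names(baseline_gene)[baseline_gene >= cfg$min_de_mean]
  eligible_matures <- names(baseline_mature)[baseline_mature >= cfg$min_de_mean]
  planted_degs <- draw_effects(gene_ids, cfg$frac_de_genes, eligible_genes)
  planted_dems <- draw_effects(mature_ids, cfg$frac_de_mirnas, eligible_matures)

  # repression edges attach to TF-bound DEMs; targets are TF-bound,
  # expression-eligible genes not already carrying a planted effect
  dems_bound <- intersect(names(planted_dems), bound_matures)
  target_pool <- setdiff(intersect(bound_genes, eligible_genes),
                         names(planted_degs))
  repression <- tibble(mature_id = character(), gene_id = character())
  for (m in dems_bound) {
    k <- min(cfg$targets_per_dem, length(target_pool))
    if (k == 0) break
    tg <- sample(target_pool, k)
    target_pool <- setdiff(target_pool, tg)
    repression <- bind_rows(repression, tibble(mature_id = m, gene_id = tg))
  }

  list(
    bound_gene_promoters = bound_genes,
    bound_mirna_promoters = bound_pri,
    bound_matures = bound_matures,
    planted_degs = planted_degs,
    planted_dems = planted_dems,
    repression_edges = repression,
    motif_carriers = bound_pri
  )
}

#' Generate synthetic ChIP-seq peak sets
#'
#' Every TF-bound promoter receives one peak centred on its TSS with
#' `-log10(p) > 3` and guaranteed window overlap well above 100 bp.
#' Decoy peaks each violate at least one assignment rule: sub-threshold
#' score on a promoter, passing score but <= 100 bp of overlap, or a
#' passing peak in intergenic space. Histone-mark peaks (H3K27ac,
#' H3K4me3) are placed on active promoters: all bound ones plus a
#' sample of unbound ones.
#'
#' @param cfg `tfmirnet_sim_config`.
#' @param annotation Output of [generate_annotation()].
#' @param truth Planted truth (see [simulate_study()]).
#' @return List of peak tibbles: `tf_peaks`, `h3k27ac_peaks`,
#'   `h3k4me3_peaks`.
#' @export
generate_chip <- function(cfg, annotation, truth) {
  set.seed(substream_seed(cfg$seed, "chip"))
  tss <- annotation$tss
  promoters <- build_promoters(tss, cfg$halfwidth, annotation$chrom_sizes)

  bound_parent <- promoters$gene_id %in% truth$bound_gene_promoters |
    promoters$parent_id %in% truth$bound_mirna_promoters
  # one true peak per bound gene/pri (at its first promoter)
  first_prom <- promoters[bound_parent, ] |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup()

  w <- as.integer(cfg$peak_width)
  centre <- as.integer((first_prom$start + first_prom$end) / 2)
  true_peaks <- tibble(
    chrom = first_prom$chrom,
    start = pmax(0L, centre - w %/% 2L),
    end = centre + w %/% 2L,
    name = sprintf("truepk%04d", seq_len(nrow(first_prom))),
    score = 0, strand = ".",
    fold_enrichment = runif(nrow(first_prom), 3, 30),
    neg_log10_p = runif(nrow(first_prom), 6, 60),
    neg_log10_q = runif(nrow(first_prom), 4, 40),
    summit_offset = w %/% 2L
  )

  n_decoy <- round(cfg$decoy_peak_rate * nrow(true_peaks))
  decoys <- empty_peaks()
  if (n_decoy > 0 && nrow(promoters) > 0) {
    kind <- sample(c("lowscore", "shortoverlap", "intergenic"), n_decoy,
                   replace = TRUE)
    # short-overlap decoys hang off the LEFT edge of a gene's leftmost
    # window, so they cannot reach a sibling transcript window
    leftmost <- promoters |>
      group_by(.data$gene_id) |>
      arrange(.data$start, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    host <- promoters[sample.int(nrow(promoters), n_decoy, replace = TRUE), ]
    lhost <- leftmost[sample.int(nrow(leftmost), n_decoy, replace = TRUE), ]
    chrom <- host$chrom
    start <- integer(n_decoy); end <- integer(n_decoy)
    p <- numeric(n_decoy)
    for (i in seq_len(n_decoy)) {
      if (kind[i] == "lowscore") {
        c0 <- as.integer((host$start[i] + host$end[i]) / 2)
        start[i] <- max(0L, c0 - w %/% 2L); end[i] <- c0 + w %/% 2L
        p[i] <- runif(1, 0.3, 3)  # fails the strict > 3 rule
      } else if (kind[i] == "shortoverlap") {
        # passing score, but at most 100 bp inside the window
        ov <- sample(10:100, 1)
        chrom[i] <- lhost$chrom[i]
        start[i] <- max(0L, lhost$start[i] - (w - ov))
        end[i] <- start[i] + w
        p[i] <- runif(1, 6, 60)
      } else {
        # promoter-free chromosome: passing score, zero promoter overlap
        chrom[i] <- "chrS3"
        start[i] <- sample.int(900000L, 1)
        end[i] <- start[i] + w
        p[i] <- runif(1, 6, 60)
      }
    }
    decoys <- tibble(
      chrom = chrom, start = start, end = end,
      name = sprintf("decoypk%04d", seq_len(n_decoy)),
      score = 0, strand = ".",
      fold_enrichment = runif(n_decoy, 1, 5),
      neg_log10_p = p,
      neg_log10_q = p / 2,
      summit_offset = w %/% 2L
    )
  }
  tf_peaks <- bind_rows(true_peaks, decoys) |>
    mutate(score = pmin(1000, round(10 * .data$neg_log10_p))) |>
    arrange(.data$chrom, .data$start)

  # marks on active promoters: every bound one plus 20% of the rest
  active <- promoters[bound_parent |
                        runif(nrow(promoters)) < 0.2, ]
  mark_peaks <- function(tag) {
    mw <- 1000L
    c0 <- as.integer((active$start + active$end) / 2)
    tibble(
      chrom = active$chrom,
      start = pmax(0L, c0 - mw %/% 2L), end = c0 + mw %/% 2L,
      name = sprintf("%s%04d", tag, seq_len(nrow(active))),
      score = 500, strand = ".",
      fold_enrichment = runif(nrow(active), 2, 20),
      neg_log10_p = runif(nrow(active), 5, 50),
      neg_log10_q = runif(nrow(active), 3, 30),
      summit_offset = mw %/% 2L
    )
  }
  list(tf_peaks = tf_peaks,
       h3k27ac_peaks = mark_peaks("k27ac"),
       h3k4me3_peaks = mark_peaks("k4me3"))
}

# internal: NB counts for one feature set under the knockdown contrast
nb_matrix <- function(mu, effects, n_reps, dispersion, lib_factors, prefix) {
  ids <- names(mu)
  lfc <- setNames(rep(0, length(ids)), ids)
  common <- intersect(names(effects), ids)
  lfc[common] <- effects[common]
  mu_sil <- mu * 2^lfc
  samples <- c(paste0(prefix, "_ctl_", seq_len(n_reps)),
               paste0(prefix, "_sil_", seq_len(n_reps)))
  cols <- lapply(seq_len(2 * n_reps), function(j) {
    m <- if (j <= n_reps) mu else mu_sil
    rnbinom(length(ids), mu = m * lib_factors[j], size = 1 / dispersion)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- samples
  bind_cols(tibble(feature_id = ids), as_tibble(mat))
}

#' Generate synthetic two-condition count matrices
#'
#' Negative binomial counts (variance `mu + alpha * mu^2`) around
#' log-normal baseline means, with per-sample library-size factors.
#' Planted features have their silenced-condition mean scaled by
#' `2^effect`; genes targeted by a planted DEM receive an additional
#' multiplicative repression whose sign opposes the miRNA's effect, so
#' sign opposition holds in expectation. miRNA counts are emitted per
#' (precursor, mature) arm row; mRNA counts per gene, with gene lengths
#' for TPM.
#'
#' @inheritParams generate_chip
#' @param baselines Baseline means as produced inside [simulate_study()]
#'   (list with `gene` and `mature` named vectors).
#' @return List: `mrna_counts`, `mirna_arm_counts`, `gene_lengths`,
#'   `condition_mrna`, `condition_mirna`.
#' @export
generate_counts <- function(cfg, annotation, truth, baselines) {
  set.seed(substream_seed(cfg$seed, "counts"))
  gene_mu <- baselines$gene
  mature_mu <- baselines$mature

  # total planted gene effect: own effect plus repression coupling
  gene_eff <- truth$planted_degs
  if (nrow(truth$repression_edges) > 0) {
    rep_eff <- truth$repression_edges |>
      mutate(eff = -sign(truth$planted_dems[.data$mature_id]) *
               cfg$repression_lfc) |>
      group_by(.data$gene_id) |>
      summarise(eff = sum(.data$eff), .groups = "drop")
    add <- setNames(rep_eff$eff, rep_eff$gene_id)
    gene_eff <- c(gene_eff, add[setdiff(names(add), names(gene_eff))])
    both <- intersect(names(add), names(gene_eff))
    gene_eff[both] <- gene_eff[both] + add[both]
  }

  lib_mrna <- exp(rnorm(2 * cfg$n_mrna_reps, 0, cfg$library_size_sd))
  lib_mirna <- exp(rnorm(2 * cfg$n_mirna_reps, 0, cfg$library_size_sd))

  mrna_counts <- nb_matrix(gene_mu, gene_eff, cfg$n_mrna_reps,
                           cfg$nb_dispersion, lib_mrna, "rna")

  # per-precursor arm rows; each row's mean is the mature baseline so the
  # across-precursor average recovers it
  mm <- annotation$mature_map
  arm_mu <- setNames(mature_mu[mm$mature_id], NULL)
  arm_eff <- setNames(rep(0, nrow(mm)), NULL)
  common <- mm$mature_id %in% names(truth$planted_dems)
  arm_eff[common] <- truth$planted_dems[mm$mature_id[common]]
  arm_ids <- paste(mm$precursor_id, mm$mature_id, sep = "|")
  arm_tbl <- nb_matrix(setNames(arm_mu, arm_ids),
                       setNames(arm_eff, arm_ids),
                       cfg$n_mirna_reps, cfg$nb_dispersion, lib_mirna, "mir")
  mirna_arm_counts <- bind_cols(
    tibble(precursor_id = mm$precursor_id, mature_id = mm$mature_id),
    arm_tbl[, -1]
  )

  gene_lengths <- tibble(
    feature_id = names(gene_mu),
    length = sample(500:5000, length(gene_mu), replace = TRUE)
  )
  cond <- function(prefix, n) {
    tibble(sample_id = c(paste0(prefix, "_ctl_", seq_len(n)),
                         paste0(prefix, "_sil_", seq_len(n))),
           condition = rep(c("control", "silenced"), each = n))
  }
  list(mrna_counts = mrna_counts, mirna_arm_counts = mirna_arm_counts,
       gene_lengths = gene_lengths,
       condition_mrna = cond("rna", cfg$n_mrna_reps),
       condition_mirna = cond("mir", cfg$n_mirna_reps))
}

#' Generate a synthetic miRNA target map
#'
#' Contains every planted repression edge plus random decoy pairs at the
#' configured per-mature rate (decoys never duplicate truth edges).
#'
#' @inheritParams generate_chip
#' @return Tibble of unique (`mature_id`, `gene_id`) pairs.
#' @export
generate_target_map <- function(cfg, annotation, truth) {
  set.seed(substream_seed(cfg$seed, "targets"))
  matures <- unique(annotation$mature_map$mature_id)
  genes <- unique(annotation$tss$gene_id[
    annotation$tss$biotype == "protein_coding"])
  map <- truth$repression_edges
  if (cfg$decoy_targets_per_mirna > 0 && length(genes) > 0) {
    decoys <- tidyr::expand_grid(mature_id = matures, idx = seq_len(
      min(cfg$decoy_targets_per_mirna, length(genes)))) |>
      mutate(gene_id = sample(genes, dplyr::n(), replace = TRUE)) |>
      select("mature_id", "gene_id")
    map <- bind_rows(map, decoys)
  }
  map |>
    distinct(.data$mature_id, .data$gene_id) |>
    anti_join(truth$repression_edges,
              by = c("mature_id", "gene_id")) |>
    bind_rows(truth$repression_edges) |>
    arrange(.data$mature_id, .data$gene_id)
}

#' Generate pri-miRNA promoter sequences with embedded motifs
#'
#' Random uniform-composition sequences the size of the promoter window;
#' every motif carrier (TF-bound pri-miRNA) gets the PFM consensus
#' embedded at a random offset, on a random strand.
#'
#' @inheritParams generate_chip
#' @param pfm `pfm_matrix` whose consensus is embedded.
#' @return Named character vector keyed by pri-miRNA id.
#' @export
generate_promoter_seqs <- function(cfg, annotation, truth, pfm) {
  set.seed(substream_seed(cfg$seed, "sequences"))
  pri_ids <- annotation$tss$feature_id[annotation$tss$biotype == "pri_mirna"]
  len <- 2L * as.integer(cfg$halfwidth)
  consensus <- paste(c("A", "C", "G", "T")[apply(pfm$counts, 2, which.max)],
                     collapse = "")
  L <- nchar(consensus)
  seqs <- vapply(pri_ids, function(id) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (id %in% truth$motif_carriers) {
      at <- sample.int(len - L + 1L, 1)
      ins <- if (runif(1) < 0.5) consensus else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(consensus)))
      substr(s, at, at + L - 1L) <- ins
    }
    s
  }, character(1))
  setNames(seqs, pri_ids)
}

#' Built-in CLEAR-like synthetic PFM
#'
#' A synthetic stand-in position frequency matrix over the palindromic
#' E-box-type consensus GTCACGTGAC, used by the simulator and examples.
#' It is not derived from any database matrix.
#'
#' @param strength Consensus count per column out of 100.
#' @return `pfm_matrix` object.
#' @export
synthetic_clear_pfm <- function(strength = 85) {
  consensus <- c("G", "T", "C", "A", "C", "G", "T", "G", "A", "C")
  counts <- matrix((100 - strength) / 3, nrow = 4, ncol = length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- strength
  pfm_matrix(counts, matrix_id = "SYNTH.CLEAR.1")
}

#' Simulate a complete synthetic study
#'
#' Runs every generator under one global seed and returns the full input
#' bundle plus the planted truth: annotation, chromosome sizes,
#' precursor-to-mature map, TF and histone peak sets, count matrices
#' with condition labels, gene lengths, target map, pri-miRNA promoter
#' sequences with embedded motifs, and the PFM.
#'
#' @param cfg `tfmirnet_sim_config` (see [simulation_config()]).
#' @return List of class `tfmirnet_study`; the `truth` element holds the
#'   planted bound sets, DE effects and repression edges.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  annotation <- generate_annotation(cfg)

  set.seed(substream_seed(cfg$seed, "baselines"))
  gene_ids <- unique(annotation$tss$gene_id[
    annotation$tss$biotype == "protein_coding"])
  gene_mu <- setNames(
    exp(rnorm(length(gene_ids), cfg$mean_log_mu, cfg$mean_log_sd)), gene_ids)
  silent <- sample(gene_ids, round(cfg$frac_silent_genes * length(gene_ids)))
  gene_mu[silent] <- runif(length(silent), 0.01, 0.2)
  mature_ids <- unique(annotation$mature_map$mature_id)
  mature_mu <- setNames(
    exp(rnorm(length(mature_ids), log(200), 1.5)), mature_ids)
  baselines <- list(gene = gene_mu, mature = mature_mu)

  truth <- generate_truth(cfg, annotation, gene_mu, mature_mu)
  chip <- generate_chip(cfg, annotation, truth)
  counts <- generate_counts(cfg, annotation, truth, baselines)
  target_map <- generate_target_map(cfg, annotation, truth)
  pfm <- synthetic_clear_pfm()
  seqs <- generate_promoter_seqs(cfg, annotation, truth, pfm)

  structure(
    c(annotation, chip, counts,
      list(target_map = target_map, promoter_seqs = seqs, pfm = pfm,
           truth = truth, config = cfg)),
    class = "tfmirnet_study"
  )
}

#' Write a synthetic study bundle to disk
#'
#' Emits the complete file bundle (TSS TSV, chrom sizes, three
#' narrowPeak files, counts TSVs, gene lengths, mature map, target map,
#' promoter FASTA, JASPAR PFM, truth JSON) so the file-based readers and
#' [validate_config()]/[run_pipeline()] can consume it.
#'
#' @param study `tfmirnet_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "tfmirnet_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tss_table(study$tss, p("tss.tsv"))
  write_chrom_sizes(study$chrom_sizes, p("chrom_sizes.tsv"))
  write_narrowpeak(study$tf_peaks, p("tf_peaks.narrowPeak"))
  write_narrowpeak(study$h3k27ac_peaks, p("h3k27ac.narrowPeak"))
  write_narrowpeak(study$h3k4me3_peaks, p("h3k4me3.narrowPeak"))
  write_count_matrix(study$mrna_counts, p("mrna_counts.tsv"))
  write_tsv_plain(study$mirna_arm_counts, p("mirna_arm_counts.tsv"))
  write_tsv_plain(study$gene_lengths, p("gene_lengths.tsv"))
  write_mature_map(study$mature_map, p("mature_map.tsv"))
  write_target_map(study$target_map, p("target_map.tsv"))
  write_tsv_plain(study$condition_mrna, p("condition_mrna.tsv"))
  write_tsv_plain(study$condition_mirna, p("condition_mirna.tsv"))
  write_promoter_fasta(study$promoter_seqs, p("mirna_promoters.fa"))
  write_pfm(study$pfm, p("motif.pfm"))
  truth <- study$truth
  jsonlite::write_json(
    list(
      bound_gene_promoters = truth$bound_gene_promoters,
      bound_mirna_promoters = truth$bound_mirna_promoters,
      bound_matures = truth$bound_matures,
      planted_degs = as.list(truth$planted_degs),
      planted_dems = as.list(truth$planted_dems),
      repression_edges = truth$repression_edges,
      motif_carriers = truth$motif_carriers
    ),
    p("truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(setNames(
    as.list(p(c("tss.tsv", "chrom_sizes.tsv", "tf_peaks.narrowPeak",
                "h3k27ac.narrowPeak", "h3k4me3.narrowPeak",
                "mrna_counts.tsv", "mirna_arm_counts.tsv", "gene_lengths.tsv",
                "mature_map.tsv", "target_map.tsv", "condition_mrna.tsv",
                "condition_mirna.tsv", "mirna_promoters.fa", "motif.pfm",
                "truth.json"))),
    c("tss", "chrom_sizes", "tf_peaks", "h3k27ac", "h3k4me3", "mrna_counts",
      "mirna_arm_counts", "gene_lengths", "mature_map", "target_map",
      "condition_mrna", "condition_mirna", "promoter_fasta", "pfm", "truth")
  ))
}

#' Score recovery of the planted network
#'
#' Set-based precision/recall per edge type between an inferred network
#' and the planted truth. Truth edge sets: `tf_binds_mirna` = TF to each
#' planted DEM with a bound promoter; `mirna_represses_gene` = planted
#' repression edges; `tf_binds_gene` = TF to each bound repression
#' target. An empty inferred edge set has undefined precision (`NA`) and
#' recall 0.
#'
#' @param inferred `tfmirnet_network`.
#' @param truth Planted truth list from [simulate_study()].
#' @return Tibble: `edge_type`, `n_truth`, `n_inferred`, `tp`,
#'   `precision`, `recall`.
#' @export
score_recovery <- function(inferred, truth) {
  stopifnot(inherits(inferred, "tfmirnet_network"))
  dems_bound <- intersect(names(truth$planted_dems), truth$bound_matures)
  truth_edges <- list(
    tf_binds_mirna = paste(inferred$tf, dems_bound, sep = "->"),
    mirna_represses_gene = paste(truth$repression_edges$mature_id,
                                 truth$repression_edges$gene_id, sep = "->"),
    tf_binds_gene = paste(inferred$tf,
                          intersect(truth$repression_edges$gene_id,
                                    truth$bound_gene_promoters), sep = "->")
  )
  purrr::map(names(truth_edges), function(tp) {
    inf <- inferred$edges |> filter(.data$type == tp)
    inf_keys <- paste(inf$from, inf$to, sep = "->")
    tru_keys <- truth_edges[[tp]]
    ntp <- length(intersect(inf_keys, tru_keys))
    tibble(
      edge_type = tp,
      n_truth = length(tru_keys),
      n_inferred = length(inf_keys),
      tp = ntp,
      precision = if (length(inf_keys) == 0) NA_real_ else ntp / length(inf_keys),
      recall = if (length(tru_keys) == 0) NA_real_ else ntp / length(tru_keys)
    )
  }) |>
    bind_rows()
}
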