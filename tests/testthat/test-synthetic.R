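test_that("annotation generation is deterministic and within bounds", {
  cfg <- small_config()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  proms <- build_promoters(a1$tss, cfg$halfwidth, a1$chrom_sizes)
  expect_true(all(proms$start >= 0))
  expect_true(all(proms$end <= a1$chrom_sizes[proms$chrom]))
  expect_equal(nrow(proms), nrow(a1$tss))

  none <- simulation_config(n_genes = 0, n_mirnas = 3, seed = 1)
  a0 <- generate_annotation(none)
  expect_equal(sum(a0$tss$biotype == "protein_coding"), 0L)
  expect_equal(sum(a0$tss$biotype == "pri_mirna"), 3L)
})

test_that("generated peaks recover exactly the planted bound sets", {
  cfg <- small_config()
  study <- simulate_study(cfg)
  th <- default_thresholds()
  proms <- build_promoters(study$tss, cfg$halfwidth, study$chrom_sizes)

  gene_bind <- assign_peaks(study$tf_peaks,
                            dplyr::filter(proms, biotype != "pri_mirna"),
                            th$min_neglog10p, th$min_overlap, level = "gene")
  expect_setequal(gene_bind$id[gene_bind$bound],
                  study$truth$bound_gene_promoters)

  pri_bind <- assign_peaks(study$tf_peaks,
                           dplyr::filter(proms, biotype == "pri_mirna"),
                           th$min_neglog10p, th$min_overlap,
                           level = "promoter")
  expect_setequal(pri_bind$id[pri_bind$bound],
                  study$truth$bound_mirna_promoters)
})

test_that("a decoy-only peak file yields zero bound promoters", {
  cfg2 <- small_config(seed = 8)
  study <- simulate_study(cfg2)
  decoys <- dplyr::filter(study$tf_peaks, grepl("^decoypk", name))
  proms <- build_promoters(study$tss, cfg2$halfwidth, study$chrom_sizes)
  bind <- assign_peaks(decoys, proms, level = "promoter")
  expect_equal(sum(bind$bound), 0L)
})

test_that("the study bundle round-trips through the file readers", {
  cfg <- simulation_config(n_genes = 40, n_mirnas = 10, seed = 9)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)

  expect_equal(as.data.frame(read_narrowpeak(paths$tf_peaks)),
               as.data.frame(study$tf_peaks))
  expect_equal(as.data.frame(read_tss_table(paths$tss)),
               as.data.frame(study$tss))
  expect_equal(read_chrom_sizes(paths$chrom_sizes), study$chrom_sizes)
  expect_equal(as.data.frame(read_count_matrix(paths$mrna_counts)),
               as.data.frame(study$mrna_counts))
  expect_equal(as.data.frame(read_target_map(paths$target_map)),
               as.data.frame(study$target_map))
  seqs <- read_promoter_fasta(paths$promoter_fasta)
  expect_equal(seqs[names(study$promoter_seqs)], study$promoter_seqs)
  pfm <- read_pfm(paths$pfm)
  expect_equal(unname(pfm$counts), unname(study$pfm$counts))
})

test_that("the target map contains the truth and respects the decoy knob", {
  cfg <- small_config()
  study <- simulate_study(cfg)
  truth_keys <- paste(study$truth$repression_edges$mature_id,
                      study$truth$repression_edges$gene_id)
  map_keys <- paste(study$target_map$mature_id, study$target_map$gene_id)
  expect_true(all(truth_keys %in% map_keys))
  expect_equal(anyDuplicated(map_keys), 0L)

  bare <- simulate_study(small_config(decoy_targets_per_mirna = 0))
  expect_setequal(
    paste(bare$target_map$mature_id, bare$target_map$gene_id),
    paste(bare$truth$repression_edges$mature_id,
          bare$truth$repression_edges$gene_id))
})

test_that("planted effects are recoverable from the counts", {
  cfg <- simulation_config(n_genes = 500, n_mirnas = 20, seed = 10,
                           n_mrna_reps = 3, effect_min = 2, effect_max = 2,
                           nb_dispersion = 0.005, frac_de_genes = 0.05,
                           min_de_mean = 300, targets_per_dem = 0,
                           library_size_sd = 0)
  study <- simulate_study(cfg)
  de <- de_test(study$mrna_counts, study$condition_mrna)
  planted <- study$truth$planted_degs
  est <- de$log2fc[match(names(planted), de$feature_id)]
  # high-mean, low-dispersion features recover the planted effect closely
  expect_lt(median(abs(est - planted)), 0.15)
  expect_true(mean(abs(est - planted) < 0.3) >= 0.9)

  # null features show no systematic shift
  null_ids <- setdiff(study$truth$bound_gene_promoters, names(planted))
  nul <- de$log2fc[match(null_ids, de$feature_id)]
  expect_lt(abs(mean(nul, na.rm = TRUE)), 3 * sd(nul, na.rm = TRUE) /
              sqrt(sum(!is.na(nul))))
})

test_that("count generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$mrna_counts, s2$mrna_counts)
  expect_identical(s1$mirna_arm_counts, s2$mirna_arm_counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("recovery scoring does plain set arithmetic", {
  truth <- list(
    planted_dems = c(m1 = 2, m2 = -2),
    bound_matures = c("m1", "m2"),
    bound_gene_promoters = c("g1", "g3"),
    repression_edges = tibble::tibble(mature_id = c("m1", "m2"),
                                      gene_id = c("g1", "g2"))
  )
  nodes <- tibble::tibble(id = c("TF", "m1", "m2", "g1"),
                          type = c("tf", "mirna", "mirna", "gene"),
                          status = NA_character_,
                          tf_bound = c(NA, TRUE, TRUE, TRUE))
  edges <- tibble::tibble(
    from = c("TF", "TF", "m1", "TF"),
    to = c("m1", "m2", "g1", "g1"),
    type = c("tf_binds_mirna", "tf_binds_mirna",
             "mirna_represses_gene", "tf_binds_gene"))
  net <- structure(list(tf = "TF", nodes = nodes, edges = edges),
                   class = "tfmirnet_network")
  sc <- score_recovery(net, truth)
  expect_equal(sc$precision[sc$edge_type == "tf_binds_mirna"], 1)
  expect_equal(sc$recall[sc$edge_type == "tf_binds_mirna"], 1)
  expect_equal(sc$precision[sc$edge_type == "mirna_represses_gene"], 1)
  expect_equal(sc$recall[sc$edge_type == "mirna_represses_gene"], 0.5)

  # identical network scores (1, 1); empty scores (NA, 0)
  empty <- structure(list(tf = "TF", nodes = nodes[1, ],
                          edges = edges[0, ]), class = "tfmirnet_network")
  sc0 <- score_recovery(empty, truth)
  expect_true(all(is.na(sc0$precision)))
  expect_true(all(sc0$recall[sc0$n_truth > 0] == 0))
})
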