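#' Validate a file-based pipeline configuration
#'
#' Checks that a configuration list names every required input file,
#' that the files exist, and that the thresholds object is well formed.
#' Returns the problems rather than aborting, so callers can report them
#' all at once.
#'
#' @param config Named list with file paths (`tss`, `chrom_sizes`,
#'   `tf_peaks`, `h3k27ac`, `h3k4me3`, `mrna_counts`, `mirna_arm_counts`,
#'   `gene_lengths`, `mature_map`, `target_map`, `condition_mrna`,
#'   `condition_mirna`; optional `promoter_fasta`, `pfm`, `gene_de`,
#'   `mirna_de`) plus optional `thresholds` and `tf_label` entries.
#' @return Character vector of problems; empty iff the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  required <- c("tss", "chrom_sizes", "tf_peaks", "h3k27ac", "h3k4me3",
                "mrna_counts", "mirna_arm_counts", "gene_lengths",
                "mature_map", "target_map", "condition_mrna",
                "condition_mirna")
  for (key in required) {
    if (is.null(config[[key]])) {
      problems <- c(problems, sprintf("missing required input key '%s'", key))
    } else if (!file.exists(config[[key]])) {
      problems <- c(problems,
                    sprintf("input '%s' not found: %s", key, config[[key]]))
    }
  }
  for (key in c("promoter_fasta", "pfm", "gene_de", "mirna_de")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      problems <- c(problems,
                    sprintf("input '%s' not found: %s", key, config[[key]]))
    }
  }
  th <- config$thresholds
  if (!is.null(th)) {
    res <- tryCatch({ do.call(default_thresholds, unclass(th)); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) problems <- c(problems, paste0("thresholds: ", res))
  }
  problems
}

#' Load a file-based study bundle
#'
#' Reads every input named in a validated configuration into the
#' in-memory form [run_pipeline()] consumes (the same shape
#' [simulate_study()] produces, without the truth element).
#'
#' @param config Configuration list (see [validate_config()]).
#' @param chrom_map Optional chromosome rename map applied to every
#'   coordinate-bearing input.
#' @param coordinate_base Coordinate base of the TSS table (default 0).
#' @return List of class `tfmirnet_study`.
#' @export
read_study <- function(config, chrom_map = NULL, coordinate_base = 0) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    tfm_abort(paste0("invalid configuration:\n  ",
                     paste(problems, collapse = "\n  ")), "config_error")
  }
  study <- list(
    tss = read_tss_table(config$tss, coordinate_base, chrom_map),
    chrom_sizes = read_chrom_sizes(config$chrom_sizes),
    mature_map = read_mature_map(config$mature_map),
    tf_peaks = read_narrowpeak(config$tf_peaks, chrom_map),
    h3k27ac_peaks = read_narrowpeak(config$h3k27ac, chrom_map),
    h3k4me3_peaks = read_narrowpeak(config$h3k4me3, chrom_map),
    mrna_counts = read_count_matrix(config$mrna_counts),
    mirna_arm_counts = read_tsv_strict(config$mirna_arm_counts, "arm counts"),
    gene_lengths = read_tsv_strict(config$gene_lengths, "gene lengths"),
    target_map = read_target_map(config$target_map),
    condition_mrna = read_tsv_strict(config$condition_mrna, "conditions"),
    condition_mirna = read_tsv_strict(config$condition_mirna, "conditions")
  )
  if (!is.null(config$promoter_fasta)) {
    study$promoter_seqs <- read_promoter_fasta(config$promoter_fasta)
  }
  if (!is.null(config$pfm)) study$pfm <- read_pfm(config$pfm)
  if (!is.null(config$gene_de)) study$gene_de <- read_de_table(config$gene_de)
  if (!is.null(config$mirna_de)) study$mirna_de <- read_de_table(config$mirna_de)
  structure(study, class = "tfmirnet_study")
}

#' Run the integrative TF-miRNA-target pipeline
#'
#' Executes the full analysis in fixed stage order: promoter catalog,
#' expressed-gene filter (TPM), gene DE, mature-miRNA aggregation and
#' expressed filter (normalized counts), miRNA DE, TF peak assignment at
#' gene and mature level, histone-mark and motif annotation of miRNA
#' promoters, anti-correlated target selection, and assembly of the two
#' TF-rooted networks. Externally produced DE tables in the study bundle
#' (`gene_de`, `mirna_de` elements) replace the built-in stand-in test.
#' Output is deterministic given the inputs.
#'
#' @param study Study bundle from [simulate_study()] or [read_study()].
#' @param thresholds `tfmirnet_thresholds` (see [default_thresholds()]).
#' @param tf_label TF node name (default "TFEB").
#' @param gene_de_method,mirna_de_method Methods passed to [de_test()].
#'   Both default to the variance-moderated test: with 2-3 replicates
#'   per condition a per-feature t-test has almost no power, and
#'   information sharing across features is what dedicated count-model
#'   DE tools do.
#' @param out_dir Optional directory; when given, every intermediate
#'   table, the networks (SIF/GraphML/TSV) and the JSON run report are
#'   written there.
#' @return Object of class `tfmirnet_run`: a list with the intermediate
#'   tables (`gene_de`, `mirna_de`, `gene_binding`, `mirna_binding`,
#'   `edges`, ...), the two networks, and `report` (named list of stage
#'   counts satisfying the Venn identities checked by
#'   [validate_report()]).
#' @export
run_pipeline <- function(study, thresholds = default_thresholds(),
                         tf_label = "TFEB",
                         gene_de_method = "lognormal_limma",
                         mirna_de_method = "lognormal_limma",
                         out_dir = NULL) {
  stopifnot(inherits(study, "tfmirnet_study") || is.list(study))
  th <- thresholds

  # --- promoters -----------------------------------------------------
  promoters <- build_promoters(study$tss, th$halfwidth, study$chrom_sizes)
  gene_promoters <- filter(promoters, .data$biotype != "pri_mirna")
  mature_promoters <- map_mature_to_promoters(study$mature_map, promoters)

  # --- expression: genes ----------------------------------------------
  tpm <- compute_tpm(study$mrna_counts, study$gene_lengths)
  expressed_genes <- filter_expressed_genes(tpm, th$min_tpm)
  gene_counts_expr <- filter(study$mrna_counts,
                             .data$feature_id %in% expressed_genes)
  gene_de <- study$gene_de %||%
    de_test(gene_counts_expr, study$condition_mrna, method = gene_de_method)
  gene_de <- classify_de(gene_de, th$gene_lfc, th$gene_fdr)

  # --- expression: miRNAs ---------------------------------------------
  mature_raw <- aggregate_mature_mirna(study$mirna_arm_counts)
  sf <- size_factors(mature_raw)
  mature_norm <- normalize_counts(mature_raw, sf)
  expressed_mirnas <- filter_expressed_mirnas(mature_norm, th$min_mirna_count)
  mature_raw_expr <- mature_raw |>
    filter(.data$feature_id %in% expressed_mirnas) |>
    mutate(across(-"feature_id", round))
  mirna_de <- study$mirna_de %||%
    de_test(mature_raw_expr, study$condition_mirna, method = mirna_de_method)
  mirna_de <- classify_de(mirna_de, th$mirna_lfc, th$mirna_fdr)

  # --- binding ---------------------------------------------------------
  gene_binding <- assign_peaks(study$tf_peaks, gene_promoters,
                               th$min_neglog10p, th$min_overlap,
                               level = "gene")
  pri_promoters <- filter(promoters, .data$biotype == "pri_mirna")
  pri_binding <- assign_peaks(study$tf_peaks, pri_promoters,
                              th$min_neglog10p, th$min_overlap,
                              level = "promoter")
  pri_marks <- annotate_marks(pri_promoters, study$h3k27ac_peaks,
                              study$h3k4me3_peaks)
  pri_flags <- pri_binding |>
    select("id", "bound") |>
    left_join(select(pri_marks, id = "parent_id", "h3k27ac", "h3k4me3"),
              by = "id")
  mature_flags <- mature_promoters |>
    left_join(pri_flags, by = c(precursor_id = "id")) |>
    collapse_mature_flags(c("bound", "h3k27ac", "h3k4me3"))

  if (!is.null(study$promoter_seqs) && !is.null(study$pfm)) {
    motif <- scan_promoter_set(study$promoter_seqs, study$pfm,
                               th$pwm_rel_threshold)
    mature_flags <- mature_promoters |>
      left_join(select(motif, precursor_id = "parent_id", "motif_hit"),
                by = "precursor_id") |>
      collapse_mature_flags("motif_hit") |>
      left_join(x = mature_flags, y = _, by = "mature_id")
  }

  # --- strata ----------------------------------------------------------
  degs <- filter(gene_de, .data$status != "ns")
  dems <- filter(mirna_de, .data$status != "ns")
  bound_matures <- mature_flags$mature_id[mature_flags$bound]
  dems_bound <- dems |>
    filter(.data$feature_id %in% bound_matures) |>
    mutate(bound = TRUE)
  degs_bound <- degs |>
    semi_join(filter(gene_binding, .data$bound), by = c(feature_id = "id"))

  anticorr_targets <- anticorrelated_target_set(dems_bound, gene_de,
                                                study$target_map)
  anticorr_degs <- intersect(anticorr_targets, degs$feature_id)
  bound_gene_ids <- gene_binding$id[gene_binding$bound]
  anticorr_degs_bound <- intersect(anticorr_degs, bound_gene_ids)

  edges <- select_anticorrelated(dems_bound, degs, study$target_map)
  networks <- build_networks(tf_label, dems_bound, edges, gene_binding,
                             gene_status = gene_de)

  report <- list(
    n_promoters = nrow(promoters),
    n_promoters_unique = nrow(distinct(promoters, .data$chrom, .data$start,
                                       .data$end)),
    n_genes = length(unique(gene_promoters$gene_id)),
    n_expressed_genes = length(expressed_genes),
    n_degs = nrow(degs),
    n_deg_up = sum(degs$status == "up"),
    n_deg_down = sum(degs$status == "down"),
    n_genes_bound = sum(gene_binding$bound),
    n_degs_bound = nrow(degs_bound),
    n_degs_unbound = nrow(degs) - nrow(degs_bound),
    n_matures = nrow(mature_flags),
    n_expressed_mirnas = length(expressed_mirnas),
    n_dems = nrow(dems),
    n_dem_up = sum(dems$status == "up"),
    n_dem_down = sum(dems$status == "down"),
    n_matures_bound = length(bound_matures),
    n_dems_bound = nrow(dems_bound),
    n_dems_unbound = nrow(dems) - nrow(dems_bound),
    n_dems_marked = sum(mature_flags$h3k27ac & mature_flags$h3k4me3 &
                          mature_flags$mature_id %in% dems$feature_id),
    n_anticorr_targets = length(anticorr_targets),
    n_anticorr_degs = length(anticorr_degs),
    n_anticorr_degs_bound = length(anticorr_degs_bound),
    n_network_all_nodes = nrow(networks$network_all$nodes),
    n_network_all_edges = nrow(networks$network_all$edges),
    n_network_bound_nodes = nrow(networks$network_bound$nodes),
    n_network_bound_edges = nrow(networks$network_bound$edges)
  )

  run <- structure(
    list(promoters = promoters, tpm = tpm,
         expressed_genes = expressed_genes,
         expressed_mirnas = expressed_mirnas,
         gene_de = gene_de, mirna_de = mirna_de,
         gene_binding = gene_binding, mature_flags = mature_flags,
         edges = edges, networks = networks, report = report,
         thresholds = th, tf_label = tf_label),
    class = "tfmirnet_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# internal: write every intermediate table + networks + report
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_bed6(mutate(run$promoters, name = .data$parent_id, score = 0),
             p("promoters.bed"))
  write_de_table(run$gene_de, p("gene_de.tsv"))
  write_de_table(run$mirna_de, p("mirna_de.tsv"))
  write_tsv_plain(run$gene_binding, p("gene_binding.tsv"))
  write_tsv_plain(run$mature_flags, p("mirna_annotation.tsv"))
  write_tsv_plain(run$edges, p("anticorrelated_edges.tsv"))
  export_network(run$networks$network_all, p("network_all"))
  export_network(run$networks$network_bound, p("network_bound"))
  jsonlite::write_json(run$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Check the Venn identities of a run report
#'
#' Verifies the additive bookkeeping of the report: up + down = total
#' for DEGs and DEMs, bound + unbound = total, and the stratum
#' containments (bound target DEGs within target DEGs within the
#' anti-correlated set).
#'
#' @param report Report list from a `tfmirnet_run`.
#' @return Character vector of violated identities; empty iff all hold.
#' @export
validate_report <- function(report) {
  bad <- character()
  chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)
  chk(report$n_degs == report$n_deg_up + report$n_deg_down,
      "DEG up + down != total")
  chk(report$n_dems == report$n_dem_up + report$n_dem_down,
      "DEM up + down != total")
  chk(report$n_degs == report$n_degs_bound + report$n_degs_unbound,
      "DEG bound + unbound != total")
  chk(report$n_dems == report$n_dems_bound + report$n_dems_unbound,
      "DEM bound + unbound != total")
  chk(report$n_anticorr_degs_bound <= report$n_anticorr_degs,
      "bound target DEGs exceed target DEGs")
  chk(report$n_anticorr_degs <= report$n_anticorr_targets,
      "target DEGs exceed anti-correlated set")
  chk(report$n_degs_bound <= report$n_genes_bound,
      "bound DEGs exceed bound genes")
  chk(report$n_dems_bound <= report$n_matures_bound,
      "bound DEMs exceed bound matures")
  chk(report$n_expressed_genes >= report$n_degs,
      "DEGs exceed expressed genes")
  bad
}

#' @export
print.tfmirnet_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<tfmirnet_run>\n",
           "  expressed genes: %d | DEGs: %d (up %d / down %d), bound %d\n",
           "  expressed miRNAs: %d | DEMs: %d (up %d / down %d), bound %d\n",
           "  anti-correlated targets: %d | of which DEGs: %d | bound: %d\n",
           "  network_all: %d nodes / %d edges; network_bound: %d / %d\n"),
    r$n_expressed_genes, r$n_degs, r$n_deg_up, r$n_deg_down, r$n_degs_bound,
    r$n_expressed_mirnas, r$n_dems, r$n_dem_up, r$n_dem_down, r$n_dems_bound,
    r$n_anticorr_targets, r$n_anticorr_degs, r$n_anticorr_degs_bound,
    r$n_network_all_nodes, r$n_network_all_edges,
    r$n_network_bound_nodes, r$n_network_bound_edges))
  invisible(x)
}
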