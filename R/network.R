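#' Select miRNA-target edges by sign opposition
#'
#' The anti-correlation rule: a candidate pair (miRNA m, gene g) from
#' the target map becomes a repression edge iff
#' `log2FC(m) > 0 & log2FC(g) < 0` or `log2FC(m) < 0 & log2FC(g) > 0`.
#' A fold change of exactly 0 on either side never forms an edge.
#' Status filtering (e.g. restricting to classified DEMs/DEGs) is the
#' caller's choice of input tables.
#'
#' @param dems DE tibble for the miRNAs to consider (`feature_id`,
#'   `log2fc`).
#' @param degs DE tibble for the genes to consider.
#' @param targets Target-map tibble (`mature_id`, `gene_id`).
#' @return Edge tibble: `mature_id`, `gene_id`, `mirna_log2fc`,
#'   `gene_log2fc`.
#' @export
select_anticorrelated <- function(dems, degs, targets) {
  check_columns(targets, c("mature_id", "gene_id"), "target map")
  check_columns(dems, c("feature_id", "log2fc"), "`dems`")
  check_columns(degs, c("feature_id", "log2fc"), "`degs`")
  targets |>
    inner_join(select(dems, mature_id = "feature_id",
                      mirna_log2fc = "log2fc"), by = "mature_id") |>
    inner_join(select(degs, gene_id = "feature_id",
                      gene_log2fc = "log2fc"), by = "gene_id") |>
    filter((.data$mirna_log2fc > 0 & .data$gene_log2fc < 0) |
             (.data$mirna_log2fc < 0 & .data$gene_log2fc > 0)) |>
    select("mature_id", "gene_id", "mirna_log2fc", "gene_log2fc")
}

#' Anti-correlated target set of a DEM panel
#'
#' The union, over the given miRNAs, of their mapped target genes whose
#' log2 fold change opposes the miRNA's sign — computed against the full
#' expressed-gene DE table, regardless of DEG status. Intersecting the
#' result with classified DEGs gives the differentially expressed
#' stratum.
#'
#' @param dems DE tibble of the miRNAs (typically the TF-bound DEMs).
#' @param gene_de DE tibble covering all expressed genes.
#' @param targets Target-map tibble.
#' @return Character vector of gene ids (sorted, unique).
#' @export
anticorrelated_target_set <- function(dems, gene_de, targets) {
  sort(unique(select_anticorrelated(dems, gene_de, targets)$gene_id))
}

#' Assemble the TF-rooted regulatory networks
#'
#' Builds the two networks the analysis reports: `network_all` connects
#' the TF to each bound DEM and each DEM to its selected anti-correlated
#' target genes regardless of TF binding at the gene; `network_bound`
#' keeps only target genes whose own promoter is TF-bound and adds the
#' corresponding direct TF-to-gene binding edges.
#'
#' @param tf_label Name of the TF node (e.g. `"TFEB"`).
#' @param dems_bound DE tibble of the TF-bound DEMs (`feature_id`,
#'   `log2fc`, `status`); every row must be flagged bound via a `bound`
#'   column or the `gene_binding`-style annotation passed separately.
#' @param edges Edge tibble from [select_anticorrelated()].
#' @param gene_binding Binding annotation tibble (`id`, `bound`) at gene
#'   level, covering the target genes.
#' @param gene_status Optional DE tibble (`feature_id`, `status`) used
#'   to annotate gene nodes.
#' @return List of two `tfmirnet_network` objects: `network_all` and
#'   `network_bound`. Each holds `nodes` (`id`, `type`, `status`,
#'   `tf_bound`) and `edges` (`from`, `to`, `type`), lexicographically
#'   ordered.
#' @export
build_networks <- function(tf_label, dems_bound, edges, gene_binding,
                           gene_status = NULL) {
  check_columns(dems_bound, c("feature_id", "log2fc"), "`dems_bound`")
  check_columns(gene_binding, c("id", "bound"), "`gene_binding`")
  if ("bound" %in% names(dems_bound) && !all(dems_bound$bound)) {
    tfm_abort("every DEM in `dems_bound` must have bound = TRUE",
              "validation_error")
  }
  edges <- filter(edges, .data$mature_id %in% dems_bound$feature_id)

  genes <- sort(unique(edges$gene_id))
  missing_ann <- setdiff(genes, gene_binding$id)
  if (length(missing_ann) > 0) {
    tfm_abort(sprintf("gene(s) without binding annotation: %s",
                      paste(head(missing_ann, 5), collapse = ", ")),
              "validation_error")
  }
  bound_genes <- gene_binding$id[gene_binding$bound]
  status_of <- function(ids, table) {
    if (is.null(table) || !"status" %in% names(table)) {
      return(rep(NA_character_, length(ids)))
    }
    table$status[match(ids, table$feature_id)]
  }

  make_network <- function(keep_genes, with_tf_gene_edges) {
    e <- filter(edges, .data$gene_id %in% keep_genes)
    g <- sort(unique(e$gene_id))
    m <- sort(unique(dems_bound$feature_id))
    nodes <- bind_rows(
      tibble(id = tf_label, type = "tf", status = NA_character_,
             tf_bound = NA),
      tibble(id = m, type = "mirna", status = status_of(m, dems_bound),
             tf_bound = TRUE),
      tibble(id = g, type = "gene", status = status_of(g, gene_status),
             tf_bound = g %in% bound_genes)
    )
    edge_tbl <- bind_rows(
      tibble(from = tf_label, to = m, type = "tf_binds_mirna"),
      tibble(from = e$mature_id, to = e$gene_id,
             type = "mirna_represses_gene"),
      if (with_tf_gene_edges && length(g) > 0) {
        tibble(from = tf_label, to = g, type = "tf_binds_gene")
      }
    ) |>
      distinct() |>
      arrange(.data$type, .data$from, .data$to)
    structure(list(tf = tf_label, nodes = nodes, edges = edge_tbl),
              class = "tfmirnet_network")
  }

  list(
    network_all = make_network(genes, with_tf_gene_edges = FALSE),
    network_bound = make_network(intersect(genes, bound_genes),
                                 with_tf_gene_edges = TRUE)
  )
}

#' @export
print.tfmirnet_network <- function(x, ...) {
  cat(sprintf("<tfmirnet_network rooted at %s: %d nodes, %d edges>\n",
              x$tf, nrow(x$nodes), nrow(x$edges)))
  print(dplyr::count(x$edges, .data$type))
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes the network in one or more of three formats: SIF
#' (`source<TAB>relation<TAB>target`, one line per edge), GraphML (with
#' node `type`/`status`/`tf_bound` attributes, via igraph), and TSV node
#' and edge tables. Ordering is deterministic (lexicographic by edge
#' type, source, target).
#'
#' @param network `tfmirnet_network` object.
#' @param prefix Output path prefix; files are written as
#'   `<prefix>.sif`, `<prefix>.graphml`, `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`.
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(network, prefix,
                           formats = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(network, "tfmirnet_network"))
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad) > 0) {
    tfm_abort(sprintf("unknown format(s): %s (use sif, graphml, tsv)",
                      paste(bad, collapse = ", ")), "validation_error")
  }
  edges <- arrange(network$edges, .data$type, .data$from, .data$to)
  nodes <- arrange(network$nodes, .data$id)
  written <- character()
  if ("sif" %in% formats) {
    path <- paste0(prefix, ".sif")
    writeLines(sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to),
               path, sep = "\n")
    written <- c(written, path)
  }
  if ("graphml" %in% formats) {
    path <- paste0(prefix, ".graphml")
    g <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = mutate(nodes,
                        status = if_else(is.na(.data$status), "", .data$status),
                        tf_bound = as.character(.data$tf_bound))
    )
    igraph::write_graph(g, path, format = "graphml")
    written <- c(written, path)
  }
  if ("tsv" %in% formats) {
    np <- paste0(prefix, "_nodes.tsv")
    ep <- paste0(prefix, "_edges.tsv")
    write_tsv_plain(nodes, np)
    write_tsv_plain(edges, ep)
    written <- c(written, np, ep)
  }
  invisible(written)
}

#' Read a network back from GraphML
#'
#' Inverse of the GraphML branch of [export_network()], used for
#' round-trip checks and to re-load exported networks.
#'
#' @param path GraphML path.
#' @return `tfmirnet_network` object.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(
    id = igraph::vertex_attr(g, "name"),
    type = igraph::vertex_attr(g, "type"),
    status = igraph::vertex_attr(g, "status"),
    tf_bound = igraph::vertex_attr(g, "tf_bound")
  ) |>
    mutate(
      status = if_else(.data$status == "", NA_character_, .data$status),
      tf_bound = dplyr::case_when(.data$tf_bound == "TRUE" ~ TRUE,
                                  .data$tf_bound == "FALSE" ~ FALSE,
                                  TRUE ~ NA)
    ) |>
    arrange(.data$id)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- as_tibble(el[, c("from", "to", "type")]) |>
    arrange(.data$type, .data$from, .data$to)
  tf <- nodes$id[nodes$type == "tf"][1]
  structure(list(tf = tf, nodes = nodes, edges = edges),
            class = "tfmirnet_network")
}
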