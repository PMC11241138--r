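# broom-style accessors and ggplot2 methods for the result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a regulatory network
#'
#' @param x `tfmirnet_network`.
#' @param what `"edges"` (default) or `"nodes"`.
#' @param ... Unused.
#' @return Tibble of edges (`from`, `to`, `type`) or nodes.
#' @export
tidy.tfmirnet_network <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  if (what == "edges") x$edges else x$nodes
}

#' One-row summary of a regulatory network
#'
#' @param x `tfmirnet_network`.
#' @param ... Unused.
#' @return One-row tibble with node/edge counts by type.
#' @export
glance.tfmirnet_network <- function(x, ...) {
  tibble(
    tf = x$tf,
    n_nodes = nrow(x$nodes),
    n_mirnas = sum(x$nodes$type == "mirna"),
    n_genes = sum(x$nodes$type == "gene"),
    n_edges = nrow(x$edges),
    n_tf_mirna_edges = sum(x$edges$type == "tf_binds_mirna"),
    n_repression_edges = sum(x$edges$type == "mirna_represses_gene"),
    n_tf_gene_edges = sum(x$edges$type == "tf_binds_gene")
  )
}

#' Tidy a pipeline run
#'
#' @param x `tfmirnet_run`.
#' @param ... Unused.
#' @return Long tibble of report strata (`stratum`, `count`).
#' @export
tidy.tfmirnet_run <- function(x, ...) {
  tibble(stratum = names(x$report),
         count = unlist(x$report, use.names = FALSE))
}

#' One-row summary of a pipeline run
#'
#' @param x `tfmirnet_run`.
#' @param ... Unused.
#' @return One-row tibble of the headline strata.
#' @export
glance.tfmirnet_run <- function(x, ...) {
  r <- x$report
  tibble(
    n_expressed_genes = r$n_expressed_genes, n_degs = r$n_degs,
    n_degs_bound = r$n_degs_bound,
    n_expressed_mirnas = r$n_expressed_mirnas, n_dems = r$n_dems,
    n_dems_bound = r$n_dems_bound,
    n_anticorr_targets = r$n_anticorr_targets,
    n_anticorr_degs = r$n_anticorr_degs,
    n_anticorr_degs_bound = r$n_anticorr_degs_bound
  )
}

#' Plot a regulatory network
#'
#' Simple deterministic ggplot2 rendering: the TF at the centre, miRNAs
#' on an inner ring, genes on an outer ring, edges drawn as segments.
#'
#' @param object `tfmirnet_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfmirnet_network <- function(object, ...) {
  nodes <- object$nodes
  ring <- function(ids, r) {
    k <- length(ids)
    if (k == 0) return(tibble(id = character(), x = numeric(), y = numeric()))
    theta <- 2 * pi * (seq_len(k) - 1) / k
    tibble(id = ids, x = r * cos(theta), y = r * sin(theta))
  }
  layout <- bind_rows(
    tibble(id = object$tf, x = 0, y = 0),
    ring(sort(nodes$id[nodes$type == "mirna"]), 1),
    ring(sort(nodes$id[nodes$type == "gene"]), 2)
  )
  nodes <- left_join(nodes, layout, by = "id")
  edges <- object$edges |>
    left_join(layout, by = c(from = "id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(layout, by = c(to = "id"))
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = edges,
                 aes(x = .data$x0, y = .data$y0,
                     xend = .data$x, yend = .data$y,
                     colour = .data$type),
                 linewidth = 0.3, alpha = 0.6) +
    geom_point(aes(shape = .data$type, colour = .data$type), size = 3) +
    theme_void() +
    labs(colour = NULL, shape = NULL)
}

#' Volcano-style plot of a DE table
#'
#' Diagnostic scatter of log2 fold change against -log10 FDR with the
#' classification status coloured.
#'
#' @param de Classified DE tibble (from [classify_de()]).
#' @return A ggplot object.
#' @export
plot_de <- function(de) {
  check_columns(de, c("log2fc", "fdr", "status"), "DE table")
  ggplot(de, aes(x = .data$log2fc, y = -log10(.data$fdr),
                 colour = .data$status)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_colour_manual(values = c(up = "#c23b22", down = "#2e7d32",
                                   ns = "grey70")) +
    theme_minimal() +
    labs(x = "log2 fold change (silenced vs control)", y = "-log10 FDR",
         colour = NULL)
}
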