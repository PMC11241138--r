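de_tbl <- function(ids, lfc) {
  tibble::tibble(feature_id = ids, log2fc = lfc,
                 pvalue = 0.001, fdr = 0.001,
                 status = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "ns")))
}

test_that("the sign-opposition rule selects exactly the (+,-) and (-,+) cells", {
  targets <- tibble::tibble(mature_id = "m", gene_id = "g")
  for (sm in c(-1, 0, 1)) {
    for (sg in c(-1, 0, 1)) {
      dems <- de_tbl("m", sm * 0.8)
      degs <- de_tbl("g", sg * 1.3)
      n <- nrow(select_anticorrelated(dems, degs, targets))
      expect_equal(n, as.integer((sm > 0 && sg < 0) || (sm < 0 && sg > 0)),
                   info = sprintf("signs (%d, %d)", sm, sg))
    }
  }
  # pair not in the map never forms an edge
  e <- select_anticorrelated(de_tbl("m", 1), de_tbl("g2", -1), targets)
  expect_equal(nrow(e), 0L)
})

test_that("edge selection is preserved under a global sign flip", {
  set.seed(91)
  for (rep in 1:20) {
    dems <- de_tbl(paste0("m", 1:5), round(rnorm(5), 2))
    degs <- de_tbl(paste0("g", 1:12), round(rnorm(12), 2))
    targets <- tibble::tibble(
      mature_id = sample(dems$feature_id, 15, replace = TRUE),
      gene_id = sample(degs$feature_id, 15, replace = TRUE)
    ) |> dplyr::distinct()
    e1 <- select_anticorrelated(dems, degs, targets)
    dems2 <- dems; dems2$log2fc <- -dems2$log2fc
    degs2 <- degs; degs2$log2fc <- -degs2$log2fc
    e2 <- select_anticorrelated(dems2, degs2, targets)
    expect_setequal(paste(e1$mature_id, e1$gene_id),
                    paste(e2$mature_id, e2$gene_id))
    # and matches the double-loop oracle
    want <- bf_anticorr(dems, degs, targets)
    expect_setequal(paste(e1$mature_id, e1$gene_id),
                    paste(want$mature_id, want$gene_id))
  }
})

test_that("anticorrelated target sets mirror the stratum logic", {
  dems <- de_tbl("m1", 0.9)
  gene_de <- de_tbl(c("g1", "g2", "g3"), c(-0.2, 0.4, -1.6))
  targets <- tibble::tibble(mature_id = c("m1", "m1", "m1"),
                            gene_id = c("g1", "g2", "g3"))
  got <- anticorrelated_target_set(dems, gene_de, targets)
  expect_equal(got, c("g1", "g3"))
  expect_equal(anticorrelated_target_set(dems[0, ], gene_de, targets),
               character(0))
})

test_that("the two networks compose per the toy enumeration", {
  dems <- de_tbl(c("mA", "mB"), c(0.8, -0.7))
  dems$bound <- TRUE
  gene_de <- de_tbl(c("g1", "g2", "g3"), c(-1.4, -1.2, 1.9))
  targets <- tibble::tibble(mature_id = c("mA", "mA", "mB"),
                            gene_id = c("g1", "g2", "g3"))
  edges <- select_anticorrelated(dems, gene_de, targets)
  binding <- tibble::tibble(id = c("g1", "g2", "g3"),
                            bound = c(TRUE, FALSE, FALSE))
  nets <- build_networks("TF", dems, edges, binding, gene_status = gene_de)

  expect_equal(nrow(nets$network_all$nodes), 6L)   # 1 tf + 2 mirna + 3 gene
  expect_equal(nrow(nets$network_bound$nodes), 4L) # 1 tf + 2 mirna + 1 gene
  expect_equal(sum(nets$network_all$edges$type == "tf_binds_mirna"), 2L)
  expect_equal(sum(nets$network_all$edges$type == "mirna_represses_gene"), 3L)
  expect_equal(sum(nets$network_all$edges$type == "tf_binds_gene"), 0L)
  expect_equal(sum(nets$network_bound$edges$type == "tf_binds_gene"), 1L)

  # bound network genes all carry tf_bound, and its edges (minus tf->gene)
  # are a subset of network_all's
  bg <- nets$network_bound$nodes
  expect_true(all(bg$tf_bound[bg$type == "gene"]))
  eb <- nets$network_bound$edges
  ea <- nets$network_all$edges
  sub <- eb[eb$type != "tf_binds_gene", ]
  expect_true(all(paste(sub$from, sub$to) %in% paste(ea$from, ea$to)))

  # no anti-correlated targets -> star of tf -> DEMs
  star <- build_networks("TF", dems, edges[0, ], binding)
  expect_equal(star$network_all$edges$type, rep("tf_binds_mirna", 2))

  expect_error(build_networks("TF", dplyr::mutate(dems, bound = FALSE),
                              edges, binding),
               class = "tfmirnet_validation_error")
})

test_that("network export formats round-trip and stay consistent", {
  dems <- de_tbl("mA", 0.8); dems$bound <- TRUE
  gene_de <- de_tbl(c("g1", "g2"), c(-1.4, -1.2))
  targets <- tibble::tibble(mature_id = c("mA", "mA"), gene_id = c("g1", "g2"))
  edges <- select_anticorrelated(dems, gene_de, targets)
  binding <- tibble::tibble(id = c("g1", "g2"), bound = c(TRUE, TRUE))
  net <- build_networks("TF", dems, edges, binding,
                        gene_status = gene_de)$network_bound

  prefix <- file.path(withr::local_tempdir(), "net")
  export_network(net, prefix)

  sif <- readLines(paste0(prefix, ".sif"))
  expect_equal(length(sif), nrow(net$edges))
  expect_true(all(grepl("^[^\t]+\t[^\t]+\t[^\t]+$", sif)))

  back <- read_network_graphml(paste0(prefix, ".graphml"))
  expect_setequal(paste(back$edges$from, back$edges$type, back$edges$to),
                  paste(net$edges$from, net$edges$type, net$edges$to))
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$tf_bound[match(net$nodes$id, back$nodes$id)],
               net$nodes$tf_bound)

  nodes_tsv <- read.delim(paste0(prefix, "_nodes.tsv"))
  expect_equal(nrow(nodes_tsv), nrow(net$nodes))

  # empty network still exports valid documents
  empty <- build_networks("TF", dems[0, ], edges[0, ],
                          binding)
  p2 <- file.path(withr::local_tempdir(), "empty")
  export_network(empty$network_all, p2)
  expect_equal(length(readLines(paste0(p2, ".sif"))), 0L)

  expect_error(export_network(net, prefix, formats = "dot"),
               class = "tfmirnet_validation_error")
})

test_that("tidy and glance expose the network tables", {
  dems <- de_tbl("mA", 0.8); dems$bound <- TRUE
  edges <- tibble::tibble(mature_id = "mA", gene_id = "g1",
                          mirna_log2fc = 0.8, gene_log2fc = -1)
  binding <- tibble::tibble(id = "g1", bound = TRUE)
  net <- build_networks("TF", dems, edges, binding)$network_bound
  expect_equal(nrow(tidy(net)), nrow(net$edges))
  g <- glance(net)
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$n_repression_edges, 1L)
  expect_s3_class(autoplot(net), "ggplot")
})
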