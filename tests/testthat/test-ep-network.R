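make_peak_row <- function(id, fdr = 0.01, logfc = -0.5, smarca4 = TRUE,
                          k27ac = TRUE, height = 5, start = 1000) {
  data.frame(peak_id = id, chrom = "chr1", start = start, end = start + 500,
             normalized_height = height, atac_logfc = logfc, atac_fdr = fdr,
             smarca4_overlap = smarca4, k27ac_overlap = k27ac,
             stringsAsFactors = FALSE)
}
make_gene_row <- function(id, fdr = 0.01, logfc = -1, tss = 50000,
                          strand = "+") {
  data.frame(gene_id = id, chrom = "chr1", tss = tss, strand = strand,
             rna_logfc = logfc, rna_fdr = fdr, stringsAsFactors = FALSE)
}

test_that("node selection applies all four peak criteria and both gene criteria", {
  peaks <- rbind(
    make_peak_row("p1", fdr = 0.01, logfc = -0.5),
    make_peak_row("p2", fdr = 0.2),
    make_peak_row("p3", logfc = 0.5),
    make_peak_row("p4", k27ac = FALSE)
  )
  genes <- rbind(
    make_gene_row("g1", fdr = 0.01, logfc = -1),
    make_gene_row("g2", logfc = -0.1)
  )
  nodes <- select_network_nodes(peaks, genes)
  expect_equal(nodes$peak_nodes, "p1")
  expect_equal(nodes$gene_nodes, "g1")

  ## boundary logFC exactly -0.25 fails the strict comparison
  b <- select_network_nodes(make_peak_row("pb", logfc = -0.25),
                            make_gene_row("gb", logfc = -0.25))
  expect_equal(length(b$peak_nodes), 0)
  expect_equal(length(b$gene_nodes), 0)

  e <- select_network_nodes(peaks[0, ], genes[0, ])
  expect_equal(length(e$peak_nodes), 0)
  expect_equal(length(e$gene_nodes), 0)

  expect_error(select_network_nodes(peaks[, setdiff(names(peaks),
                                                    "smarca4_overlap")],
                                    genes), "smarca4")
})

test_that("promoter windows are oriented by strand", {
  nodes <- select_network_nodes(
    make_peak_row("p1"),
    rbind(make_gene_row("plus", tss = 50000, strand = "+"),
          make_gene_row("minus", tss = 50000, strand = "-")))
  gr <- nodes$gene_regions
  expect_equal(gr$start[gr$node_id == "plus"], 48000)
  expect_equal(gr$end[gr$node_id == "plus"], 50201)
  expect_equal(gr$start[gr$node_id == "minus"], 49800)
  expect_equal(gr$end[gr$node_id == "minus"], 52001)
})

test_that("edges come only from loops bridging two node regions, deduplicated", {
  peaks <- rbind(make_peak_row("p1", start = 1000),
                 make_peak_row("p_non", fdr = 0.5, start = 10000))
  genes <- make_gene_row("g1", tss = 50000)
  nodes <- select_network_nodes(peaks, genes)
  loop <- function(s1, s2, source = "hichip") {
    data.frame(chrom1 = "chr1", start1 = s1, end1 = s1 + 300,
               chrom2 = "chr1", start2 = s2, end2 = s2 + 300,
               source = source)
  }
  ## p1 <-> promoter
  e1 <- build_edges(nodes, loop(1100, 49900))
  expect_equal(e1, data.frame(from = "p1", to = "g1", class = "peak_gene",
                              stringsAsFactors = FALSE))
  ## non-node peak contributes nothing
  e2 <- build_edges(nodes, loop(10100, 30000))
  expect_equal(nrow(e2), 0)
  ## duplicate evidence across sources collapses to one edge
  e3 <- build_edges(nodes, rbind(loop(1100, 49900, "hichip"),
                                 loop(1100, 49900, "chiapet")))
  expect_equal(nrow(e3), 1)
})

test_that("rank-product weights reproduce the worked three-edge example", {
  ## products of logFCs give R1 = (1, 2, 3); heights give R2 = (2, 1, 3)
  peaks <- rbind(make_peak_row("pA", logfc = -3, height = 5),
                 make_peak_row("pB", logfc = -2, height = 7),
                 make_peak_row("pC", logfc = -1, height = 2))
  genes <- make_gene_row("g1", logfc = -1)
  edges <- data.frame(from = c("pA", "pB", "pC"), to = "g1",
                      class = "peak_gene", stringsAsFactors = FALSE)
  g <- assign_edge_weights(edges, peaks, genes)
  w <- setNames(g$edges$weight, g$edges$from)
  expect_equal(unname(w[c("pA", "pB", "pC")]), c(1, 1, 0))
})

test_that("degenerate weight classes and ties behave as specified", {
  peaks <- rbind(make_peak_row("pA", logfc = -2, height = 5),
                 make_peak_row("pB", logfc = -2, height = 5))
  genes <- make_gene_row("g1")
  single <- assign_edge_weights(
    data.frame(from = "pA", to = "g1", class = "peak_gene"), peaks, genes)
  expect_equal(single$edges$weight, 1)

  ## two identical edges tie on both ranks -> equal rank products -> both 1
  both <- assign_edge_weights(
    data.frame(from = c("pA", "pB"), to = "g1", class = "peak_gene"),
    peaks, genes)
  expect_equal(both$edges$weight, c(1, 1))

  expect_error(assign_edge_weights(
    data.frame(from = "missing", to = "g1", class = "peak_gene"),
    peaks, genes), "missing")
})

test_that("improving both ranking variables never decreases an edge weight", {
  for (s in 1:20) {
    set.seed(500 + s)
    n <- 8
    peaks <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_peak_row(sprintf("p%02d", i), logfc = -runif(1, 0.3, 3),
                    height = runif(1, 1, 10))
    }))
    genes <- make_gene_row("g1", logfc = -1)
    edges <- data.frame(from = peaks$peak_id, to = "g1",
                        class = "peak_gene", stringsAsFactors = FALSE)
    g <- assign_edge_weights(edges, peaks, genes)
    w <- setNames(g$edges$weight, g$edges$from)
    v1 <- -peaks$atac_logfc  # larger product (more negative logfc) is better
    v2 <- peaks$normalized_height
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (v1[i] >= v1[j] && v2[i] >= v2[j]) {
        expect_gte(w[peaks$peak_id[i]], w[peaks$peak_id[j]])
      }
    }
  }
})

test_that("head-node augmentation connects the graph with 0.01-weight edges", {
  g <- regulatory_graph(
    data.frame(id = c("a", "b", "c", "d"),
               kind = c("gene", "peak", "gene", "peak")),
    data.frame(from = c("a", "c"), to = c("b", "d"), class = "peak_gene",
               weight = c(0.5, 0.7)))
  ga <- augment_head_node(g)
  expect_equal(nrow(ga$nodes), 5)
  expect_equal(sum(ga$edges$class == "head"), 4)
  expect_true(all(ga$edges$weight[ga$edges$class == "head"] == 0.01))
  ig <- igraph::graph_from_data_frame(ga$edges[, 1:2], directed = FALSE,
                                      vertices = ga$nodes$id)
  expect_equal(igraph::components(ig)$no, 1)
  expect_error(augment_head_node(ga), "head")
})

test_that("eigencentrality matches closed forms and the dense oracle", {
  ## star with 4 unit-weight leaves: lambda = 2, leaves at 1/2
  star <- regulatory_graph(
    data.frame(id = c("c", paste0("l", 1:4)),
               kind = c("gene", rep("peak", 4))),
    data.frame(from = "c", to = paste0("l", 1:4), class = "peak_gene",
               weight = 1))
  ce <- compute_eigencentrality(star)
  expect_true(ce$converged)
  expect_equal(ce$lambda, 2, tolerance = 1e-9)
  expect_equal(unname(ce$scores), c(1, 0.5, 0.5, 0.5, 0.5),
               tolerance = 1e-9)

  ## two nodes, one edge: symmetry forces equal scores
  two <- regulatory_graph(
    data.frame(id = c("a", "b"), kind = c("gene", "peak")),
    data.frame(from = "a", to = "b", class = "peak_gene", weight = 0.3))
  expect_equal(unname(compute_eigencentrality(two)$scores), c(1, 1),
               tolerance = 1e-9)

  ## random graphs against the dense eigen-decomposition oracle
  for (s in 1:10) {
    g <- simulate_random_graph(n_nodes = sample(5:50, 1), seed = 600 + s)
    ce <- compute_eigencentrality(g)
    oracle <- dense_centrality_oracle(g)
    expect_lt(max(abs(ce$scores - oracle[names(ce$scores)])), 1e-8)
  }

  empty <- regulatory_graph(data.frame(id = character(),
                                       kind = character()),
                            data.frame(from = character(),
                                       to = character(),
                                       class = character(),
                                       weight = numeric()))
  expect_error(compute_eigencentrality(empty), "empty")
})

test_that("centrality is invariant under uniform scaling of the weights", {
  g <- simulate_random_graph(n_nodes = 30, seed = 77)
  c1 <- compute_eigencentrality(g)
  g2 <- g
  g2$edges$weight <- g$edges$weight * 0.2
  c2 <- compute_eigencentrality(g2)
  expect_equal(c1$scores, c2$scores, tolerance = 1e-8)
  expect_equal(c2$lambda, 0.2 * c1$lambda, tolerance = 1e-8)
})

test_that("head augmentation perturbs centrality ranks only minimally", {
  rhos <- sapply(1:10, function(s) {
    g <- simulate_random_graph(n_nodes = 50, seed = 700 + s)
    before <- compute_eigencentrality(g)$scores
    ga <- augment_head_node(g)
    after <- compute_eigencentrality(ga)$scores[names(before)]
    cor(before, after, method = "spearman")
  })
  expect_true(all(rhos >= 0.99))
})

test_that("hub ranking enumerates subnetworks and their enhancer counts", {
  ## two components: sizes 5 (g1 + 4 peaks) and 3 (g2 + 2 peaks)
  nodes <- data.frame(
    id = c("g1", paste0("pa", 1:4), "g2", paste0("pb", 1:2)),
    kind = c("gene", rep("peak", 4), "gene", rep("peak", 2)))
  edges <- data.frame(
    from = c(rep("g1", 4), rep("g2", 2)),
    to = c(paste0("pa", 1:4), paste0("pb", 1:2)),
    class = "peak_gene", weight = 1)
  g <- regulatory_graph(nodes, edges)
  ga <- augment_head_node(g)
  ce <- compute_eigencentrality(ga)
  hubs <- rank_hubs(ga, ce)
  expect_equal(nrow(hubs$components), 2)
  expect_setequal(hubs$components$n_nodes, c(5, 3))
  expect_equal(hubs$genes$gene_id[1], "g1")
  expect_equal(hubs$genes$n_enhancers[hubs$genes$gene_id == "g1"], 4L)
  expect_equal(hubs$genes$n_enhancers[hubs$genes$gene_id == "g2"], 2L)
  expect_false("head" %in% c(hubs$genes$gene_id, hubs$enhancers$peak_id))
})

test_that("the planted hub is recovered from simulated inputs end to end", {
  for (s in 1:5) {
    sim <- simulate_network_inputs(sim_config(seed = 800 + s))
    nodes <- select_network_nodes(sim$peaks, sim$genes)
    edges <- build_edges(nodes, sim$loops)
    g <- assign_edge_weights(edges, sim$peaks, sim$genes)
    hubs <- rank_hubs(augment_head_node(g),
                      compute_eigencentrality(augment_head_node(g)))
    expect_equal(hubs$genes$gene_id[1], sim$truth$hub_gene_id)
    expect_equal(hubs$genes$n_enhancers[1], 19L)
  }
})

test_that("hypergeometric overlap enrichment matches exact enumeration", {
  expect_equal(overlap_enrichment(2, 2, 2, 10), 1 / 45)
  expect_equal(overlap_enrichment(3, 3, 3, 3), 1)
  for (case in list(c(2, 4, 5, 10), c(1, 3, 6, 12), c(4, 6, 7, 11))) {
    expect_equal(overlap_enrichment(case[1], case[2], case[3], case[4]),
                 enumerate_overlap_pvalue(case[1], case[2], case[3],
                                          case[4]),
                 tolerance = 1e-12)
  }
  expect_error(overlap_enrichment(3, 2, 5, 10), "inconsistent")
})

test_that("correlation-mode node selection uses correlation thresholds", {
  peaks <- rbind(make_peak_row("p1"), make_peak_row("p2"))
  peaks$atac_cor <- c(0.8, 0.3)
  peaks$atac_cor_p <- c(0.01, 0.01)
  genes <- rbind(make_gene_row("gup", logfc = 1), make_gene_row("gdn"))
  genes$rna_p <- 0.01
  nodes <- select_network_nodes(peaks, genes, mode = "correlation")
  expect_equal(nodes$peak_nodes, "p1")
  expect_equal(nodes$gene_nodes, "gup")
})
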