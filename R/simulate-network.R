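#' Simulate gene/peak tables and loop evidence with a planted hub
#'
#' Generates the three inputs of the network stage -- a differential
#' accessibility peak table, a differential expression gene table, and loop
#' evidence -- with a planted hub gene whose promoter is loop-linked to
#' \code{hub_k} qualifying enhancer peaks (by default 19, the size of the
#' strongest E-P subnetwork the method is built to recover). Decoy genes that
#' also pass the gene-node criteria are wired to at most
#' \code{decoy_max_degree} qualifying peaks of their own, and the remaining
#' peaks fail exactly one selection criterion each (high FDR, positive
#' log2FC, or a missing SMARCA4/H3K27ac overlap flag). Differential
#' statistics of selected features are drawn clear of the thresholds
#' (log2FC from a truncated normal below -0.25, FDR uniform below 0.04) so
#' pass/fail is never marginal. A few loops are duplicated across evidence
#' sources and a few touch non-node regions, exercising edge deduplication
#' and anchor filtering downstream.
#'
#' @param cfg a \code{\link{sim_config}} (see its \code{network} element).
#' @return List with \code{peaks}, \code{genes}, \code{loops} (data.frames)
#'   and \code{truth} (list: \code{hub_gene_id}, \code{hub_peaks},
#'   \code{planted_edges}, \code{decoy_genes}).
#' @examples
#' sim <- simulate_network_inputs(sim_config(seed = 3))
#' sim$truth$hub_gene_id
#' @export
simulate_network_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  np <- cfg$network
  if (np$n_genes < 2) stop("need at least 2 genes (hub plus decoys)")

  with_op_seed(cfg$seed, "network_inputs", {
    n_decoy_pass <- max(1, floor((np$n_genes - 1) / 2))
    decoy_deg <- if (n_decoy_pass > 0 && np$n_peaks > 0) {
      sample(seq_len(np$decoy_max_degree), n_decoy_pass, replace = TRUE)
    } else {
      integer(n_decoy_pass)
    }
    n_qualifying <- np$hub_k + sum(decoy_deg)
    if (n_qualifying > np$n_peaks) {
      stop("infeasible degree constraints: ", n_qualifying,
           " qualifying peaks needed (hub_k + decoy degrees) but n_peaks = ",
           np$n_peaks)
    }

    chrom <- "chrN"
    gene_ids <- sprintf("G%03d", seq_len(np$n_genes))
    hub <- sample(gene_ids, 1)
    pass_decoys <- sample(setdiff(gene_ids, hub), n_decoy_pass)
    fail_genes <- setdiff(gene_ids, c(hub, pass_decoys))

    trunc_below <- function(n, mean, sd, upper) {
      v <- rnorm(n, mean, sd)
      while (any(v >= upper)) {
        bad <- v >= upper
        v[bad] <- rnorm(sum(bad), mean, sd)
      }
      v
    }

    genes <- data.frame(
      gene_id = gene_ids, chrom = chrom,
      tss = 1e6 + (seq_len(np$n_genes) - 1) * 1e5,
      strand = rep_len(c("+", "-"), np$n_genes),
      rna_logfc = NA_real_, rna_fdr = NA_real_,
      stringsAsFactors = FALSE
    )
    sel_g <- genes$gene_id %in% c(hub, pass_decoys)
    genes$rna_logfc[sel_g] <- trunc_below(sum(sel_g), np$selected_logfc_mean,
                                          np$selected_logfc_sd, -0.25)
    genes$rna_fdr[sel_g] <- runif(sum(sel_g), 0, np$selected_fdr_max)
    ## failing genes alternate between non-significant and upregulated
    fi <- which(genes$gene_id %in% fail_genes)
    ns <- fi[seq_along(fi) %% 2 == 1]
    up <- setdiff(fi, ns)
    genes$rna_fdr[ns] <- runif(length(ns), 0.06, 0.9)
    genes$rna_logfc[ns] <- rnorm(length(ns), 0, 0.5)
    genes$rna_fdr[up] <- runif(length(up), 0, np$selected_fdr_max)
    genes$rna_logfc[up] <- runif(length(up), 0.3, 1.5)

    peak_ids <- sprintf("P%04d", seq_len(np$n_peaks))
    peaks <- data.frame(
      peak_id = peak_ids, chrom = rep(chrom, np$n_peaks),
      start = 2e7 + (seq_len(np$n_peaks) - 1) * 1e4,
      stringsAsFactors = FALSE
    )
    peaks$end <- peaks$start + 500
    qualifying <- seq_len(n_qualifying)  # first block qualifies
    peaks$atac_logfc <- rnorm(np$n_peaks, 0, 0.5)
    peaks$atac_fdr <- runif(np$n_peaks, 0.06, 0.9)
    peaks$smarca4_overlap <- rep(TRUE, np$n_peaks)
    peaks$k27ac_overlap <- rep(TRUE, np$n_peaks)
    peaks$normalized_height <- runif(np$n_peaks, 1, 10)
    peaks$atac_logfc[qualifying] <- trunc_below(
      n_qualifying, np$selected_logfc_mean, np$selected_logfc_sd, -0.25)
    peaks$atac_fdr[qualifying] <- runif(n_qualifying, 0,
                                        np$selected_fdr_max)
    ## non-qualifying peaks fail exactly one criterion each, cycling
    nq <- setdiff(seq_len(np$n_peaks), qualifying)
    mode <- rep_len(1:4, length(nq))
    peaks$atac_fdr[nq[mode == 1]] <- runif(sum(mode == 1), 0.06, 0.9)
    peaks$atac_logfc[nq[mode == 1]] <-
      trunc_below(sum(mode == 1), np$selected_logfc_mean,
                  np$selected_logfc_sd, -0.25)
    peaks$atac_logfc[nq[mode == 2]] <- runif(sum(mode == 2), 0.3, 1.5)
    peaks$atac_fdr[nq[mode == 2]] <- runif(sum(mode == 2), 0,
                                           np$selected_fdr_max)
    sm <- nq[mode == 3]
    peaks$smarca4_overlap[sm] <- FALSE
    peaks$atac_logfc[sm] <- trunc_below(length(sm), np$selected_logfc_mean,
                                        np$selected_logfc_sd, -0.25)
    peaks$atac_fdr[sm] <- runif(length(sm), 0, np$selected_fdr_max)
    k2 <- nq[mode == 4]
    peaks$k27ac_overlap[k2] <- FALSE
    peaks$atac_logfc[k2] <- trunc_below(length(k2), np$selected_logfc_mean,
                                        np$selected_logfc_sd, -0.25)
    peaks$atac_fdr[k2] <- runif(length(k2), 0, np$selected_fdr_max)

    promoter_anchor <- function(gid) {
      tss <- genes$tss[genes$gene_id == gid]
      c(tss - 100, tss + 101)
    }
    sources <- c("chiapet", "hichip", "enhancer_atlas")
    loop_row <- function(pidx, gid, source) {
      pa <- promoter_anchor(gid)
      data.frame(chrom1 = chrom, start1 = peaks$start[pidx],
                 end1 = peaks$end[pidx], chrom2 = chrom,
                 start2 = pa[1], end2 = pa[2], source = source,
                 stringsAsFactors = FALSE)
    }

    loops <- list()
    hub_peaks <- peak_ids[seq_len(np$hub_k)]
    for (j in seq_len(np$hub_k)) {
      loops[[length(loops) + 1]] <- loop_row(j, hub, sample(sources, 1))
    }
    ## the same link in a second evidence source must deduplicate
    for (j in seq_len(min(3, np$hub_k))) {
      loops[[length(loops) + 1]] <- loop_row(j, hub, "enhancer_atlas")
    }
    planted <- data.frame(peak_id = hub_peaks,
                          gene_id = rep(hub, length(hub_peaks)),
                          stringsAsFactors = FALSE)
    nxt <- np$hub_k
    for (k in seq_along(pass_decoys)) {
      for (d in seq_len(decoy_deg[k])) {
        nxt <- nxt + 1
        loops[[length(loops) + 1]] <- loop_row(nxt, pass_decoys[k],
                                               sample(sources, 1))
        planted <- rbind(planted,
                         data.frame(peak_id = peak_ids[nxt],
                                    gene_id = pass_decoys[k]))
      }
    }
    ## distractors: loops touching non-node features yield no edges
    if (length(nq) > 0 && length(fail_genes) > 0) {
      loops[[length(loops) + 1]] <- loop_row(nq[1], fail_genes[1], "hichip")
    }
    if (np$hub_k >= 1) {
      pa <- c(5e6, 5e6 + 200)  # empty intergenic space
      loops[[length(loops) + 1]] <- data.frame(
        chrom1 = chrom, start1 = peaks$start[1], end1 = peaks$end[1],
        chrom2 = chrom, start2 = pa[1], end2 = pa[2], source = "hichip",
        stringsAsFactors = FALSE)
    }
    loops <- if (length(loops)) do.call(rbind, loops) else
      data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                 chrom2 = character(), start2 = numeric(), end2 = numeric(),
                 source = character())
    if (np$n_peaks == 0) {
      loops <- loops[0, , drop = FALSE]
    }
    rownames(loops) <- NULL

    list(
      peaks = peaks[seq_len(np$n_peaks), , drop = FALSE],
      genes = genes,
      loops = loops,
      truth = list(hub_gene_id = hub, hub_peaks = hub_peaks,
                   planted_edges = planted, decoy_genes = pass_decoys)
    )
  })
}

#' Simulate a connected random weighted regulatory graph
#'
#' A random spanning tree plus independent extra edges with probability
#' \code{edge_prob}, uniform weights on (0, 1), and alternating gene/peak
#' node kinds. Used for numerical checks of the centrality machinery
#' (oracle comparisons, head-node perturbation).
#'
#' @param n_nodes number of nodes.
#' @param edge_prob probability of each extra edge beyond the spanning tree.
#' @param seed RNG seed.
#' @return A connected \code{\link{regulatory_graph}}.
#' @export
simulate_random_graph <- function(n_nodes = 50, edge_prob = 0.08, seed = 1) {
  stopifnot(n_nodes >= 2)
  with_op_seed(seed, "random_graph", {
    ids <- sprintf("n%03d", seq_len(n_nodes))
    from <- integer(0); to <- integer(0)
    for (i in 2:n_nodes) {
      j <- if (i == 2) 1L else sample.int(i - 1, 1)
      from <- c(from, j); to <- c(to, i)
    }
    extra <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    take <- runif(nrow(extra)) < edge_prob
    from <- c(from, extra[take, 1]); to <- c(to, extra[take, 2])
    e <- unique(data.frame(from = ids[pmin(from, to)],
                           to = ids[pmax(from, to)],
                           stringsAsFactors = FALSE))
    e$class <- "random"
    e$weight <- runif(nrow(e))
    nodes <- data.frame(id = ids,
                        kind = rep_len(c("gene", "peak"), n_nodes),
                        stringsAsFactors = FALSE)
    regulatory_graph(nodes, e)
  })
}
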