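#' Construct a typed, weighted regulatory graph
#'
#' The container for gene-peak regulatory networks: nodes are gene promoters,
#' enhancer peaks, or the artificial head node; edges are undirected with
#' weights in \code{[0, 1]}.
#'
#' @param nodes data.frame with columns \code{id}, \code{kind} (one of
#'   \code{"gene"}, \code{"peak"}, \code{"head"}).
#' @param edges data.frame with columns \code{from}, \code{to}, \code{class},
#'   \code{weight}.
#' @return An object of class \code{regulatory_graph}.
#' @export
regulatory_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "kind") %in% names(nodes)),
            all(c("from", "to", "class", "weight") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicated node ids")
  if (!all(nodes$kind %in% c("gene", "peak", "head"))) {
    stop("node kind must be gene, peak or head")
  }
  if (sum(nodes$kind == "head") > 1) stop("at most one head node allowed")
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    known <- nodes$id
    if (!all(c(edges$from, edges$to) %in% known)) {
      stop("edges reference unknown node(s)")
    }
    if (any(edges$weight < 0 | edges$weight > 1)) {
      stop("edge weights must lie in [0, 1]")
    }
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicated undirected edge(s)")
  }
  structure(list(nodes = nodes, edges = edges), class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat("regulatory_graph:", nrow(x$nodes), "nodes (",
      sum(x$nodes$kind == "gene"), "gene,", sum(x$nodes$kind == "peak"),
      "peak ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Select gene and peak nodes for the regulatory network
#'
#' In the default knockdown mode, peak nodes are differentially accessible
#' peaks (\code{atac_fdr < fdr_max} and \code{atac_logfc < logfc_max}, strict
#' comparisons) that overlap both a SMARCA4 ChIP-seq peak and an H3K27ac
#' ChIP-seq peak (the enhancer retention step); gene nodes are significantly
#' downregulated genes (\code{rna_fdr < fdr_max}, \code{rna_logfc <
#' logfc_max}). In correlation mode -- for cohorts of tumor models rather
#' than a knockdown contrast -- peak nodes require
#' \code{atac_cor > cor_min} with \code{atac_cor_p < p_max}, and gene nodes
#' require upregulation (\code{rna_logfc > 0}) at \code{rna_p < p_max}.
#'
#' Gene node regions are promoter windows spanning 2000 bp upstream to
#' 200 bp downstream of the TSS, oriented by strand.
#'
#' @param peaks data.frame with columns \code{peak_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{normalized_height}, \code{atac_logfc},
#'   \code{atac_fdr}, \code{smarca4_overlap}, \code{k27ac_overlap}
#'   (correlation mode instead needs \code{atac_cor}, \code{atac_cor_p}).
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand}, \code{rna_logfc}, \code{rna_fdr}
#'   (correlation mode: \code{rna_p}).
#' @param fdr_max,logfc_max selection thresholds (strict \code{<}).
#' @param mode \code{"knockdown"} (default) or \code{"correlation"}.
#' @param cor_min,p_max correlation-mode thresholds.
#' @return List with \code{peak_nodes}, \code{gene_nodes} (ids),
#'   \code{peak_regions}, \code{gene_regions} (interval data.frames with
#'   \code{node_id}).
#' @export
select_network_nodes <- function(peaks, genes, fdr_max = 0.05,
                                 logfc_max = -0.25,
                                 mode = c("knockdown", "correlation"),
                                 cor_min = 0.5, p_max = 0.05) {
  mode <- match.arg(mode)
  if (mode == "knockdown") {
    need <- c("smarca4_overlap", "k27ac_overlap", "atac_fdr", "atac_logfc")
    miss <- setdiff(need, names(peaks))
    if (length(miss)) {
      stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
    }
    pk_sel <- peaks$atac_fdr < fdr_max & peaks$atac_logfc < logfc_max &
      peaks$smarca4_overlap & peaks$k27ac_overlap
    gn_sel <- genes$rna_fdr < fdr_max & genes$rna_logfc < logfc_max
  } else {
    miss <- setdiff(c("atac_cor", "atac_cor_p"), names(peaks))
    if (length(miss)) {
      stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
    }
    pk_sel <- peaks$atac_cor > cor_min & peaks$atac_cor_p < p_max
    gn_sel <- genes$rna_p < p_max & genes$rna_logfc > 0
  }
  pk <- peaks[pk_sel, , drop = FALSE]
  gn <- genes[gn_sel, , drop = FALSE]
  gene_regions <- promoter_windows(gn)
  list(
    peak_nodes = pk$peak_id,
    gene_nodes = gn$gene_id,
    peak_regions = if (nrow(pk)) {
      data.frame(node_id = pk$peak_id, chrom = pk$chrom, start = pk$start,
                 end = pk$end, stringsAsFactors = FALSE)
    } else {
      data.frame(node_id = character(), chrom = character(),
                 start = numeric(), end = numeric())
    },
    gene_regions = gene_regions
  )
}

## promoter window: 2000 bp upstream to 200 bp downstream of the TSS,
## oriented by transcription direction
promoter_windows <- function(genes) {
  if (nrow(genes) == 0) {
    return(data.frame(node_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss - 200, genes$tss - 2000)
  end <- ifelse(minus, genes$tss + 2000 + 1, genes$tss + 200 + 1)
  data.frame(node_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, start), end = end, stringsAsFactors = FALSE)
}

#' Build network edges from loop evidence
#'
#' Each loop record's anchors are mapped to overlapping node regions (>= 1 bp
#' overlap, strand-ignored); every cross-anchor node pair yields an edge.
#' Peak-gene and peak-peak edges are kept, gene-gene pairs are ignored, and
#' duplicates (including the same link seen in several evidence sources) are
#' collapsed: evidence from a single source suffices.
#'
#' @param nodes result of \code{\link{select_network_nodes}}.
#' @param loops data.frame with columns \code{chrom1}, \code{start1},
#'   \code{end1}, \code{chrom2}, \code{start2}, \code{end2} and optionally
#'   \code{source}.
#' @return data.frame with columns \code{from}, \code{to}, \code{class}
#'   (\code{"peak_gene"} rows have the peak in \code{from}).
#' @export
build_edges <- function(nodes, loops) {
  empty <- data.frame(from = character(), to = character(),
                      class = character(), stringsAsFactors = FALSE)
  regions <- rbind(
    cbind(nodes$peak_regions, kind = rep("peak", nrow(nodes$peak_regions))),
    cbind(nodes$gene_regions, kind = rep("gene", nrow(nodes$gene_regions)))
  )
  if (nrow(loops) == 0 || nrow(regions) == 0) return(empty)
  regions$strand <- "."
  reg_gr <- gi_to_granges(regions)

  anchor_hits <- function(chrom, start, end) {
    gr <- gi_to_granges(data.frame(chrom = chrom, start = start, end = end,
                                   strand = "."))
    GenomicRanges::findOverlaps(gr, reg_gr, ignore.strand = TRUE)
  }
  h1 <- anchor_hits(loops$chrom1, loops$start1, loops$end1)
  h2 <- anchor_hits(loops$chrom2, loops$start2, loops$end2)
  d1 <- data.frame(loop = S4Vectors::queryHits(h1),
                   node = S4Vectors::subjectHits(h1))
  d2 <- data.frame(loop = S4Vectors::queryHits(h2),
                   node = S4Vectors::subjectHits(h2))
  pairs <- merge(d1, d2, by = "loop", suffixes = c("1", "2"))
  if (nrow(pairs) == 0) return(empty)

  a <- regions[pairs$node1, ]
  b <- regions[pairs$node2, ]
  keep <- a$node_id != b$node_id & !(a$kind == "gene" & b$kind == "gene")
  a <- a[keep, ]; b <- b[keep, ]
  if (nrow(a) == 0) return(empty)

  ## orient: peak first; peak-peak pairs sorted lexicographically
  peak_first <- a$kind == "peak"
  from <- ifelse(peak_first, a$node_id, b$node_id)
  to <- ifelse(peak_first, b$node_id, a$node_id)
  cls <- ifelse(a$kind == "peak" & b$kind == "peak", "peak_peak", "peak_gene")
  pp <- cls == "peak_peak"
  lo <- pmin(from[pp], to[pp]); hi <- pmax(from[pp], to[pp])
  from[pp] <- lo; to[pp] <- hi
  out <- unique(data.frame(from = from, to = to, class = cls,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Assign rank-product edge weights
#'
#' Within each edge class, edges receive two descending ranks (largest value
#' ranked 1, ties averaged): peak-gene edges by the product of the peak's
#' ATAC log2FC and the gene's RNA log2FC, then by the peak's normalized
#' height; peak-peak edges by the product of both peaks' ATAC log2FC, then
#' by the mean normalized height. The rank product R1*R2 is min-max scaled
#' within the class so the best rank product maps to weight 1 and the worst
#' to 0; when all rank products in a class are equal every edge gets
#' weight 1.
#'
#' @param edges data.frame from \code{\link{build_edges}}.
#' @param peaks,genes the statistic tables used for node selection.
#' @return A \code{\link{regulatory_graph}} whose nodes are the edge
#'   endpoints.
#' @export
assign_edge_weights <- function(edges, peaks, genes) {
  if (nrow(edges) == 0) {
    return(regulatory_graph(
      data.frame(id = character(), kind = character()),
      data.frame(from = character(), to = character(), class = character(),
                 weight = numeric())
    ))
  }
  pstat <- function(id, col) {
    i <- match(id, peaks$peak_id)
    if (anyNA(i)) {
      stop("edge endpoint(s) missing from peak table: ",
           paste(unique(id[is.na(i)]), collapse = ", "))
    }
    peaks[[col]][i]
  }
  gstat <- function(id, col) {
    i <- match(id, genes$gene_id)
    if (anyNA(i)) {
      stop("edge endpoint(s) missing from gene table: ",
           paste(unique(id[is.na(i)]), collapse = ", "))
    }
    genes[[col]][i]
  }
  desc_rank <- function(v) rank(-v, ties.method = "average")
  weight <- numeric(nrow(edges))
  for (cls in unique(edges$class)) {
    sel <- edges$class == cls
    e <- edges[sel, ]
    if (cls == "peak_gene") {
      v1 <- pstat(e$from, "atac_logfc") * gstat(e$to, "rna_logfc")
      v2 <- pstat(e$from, "normalized_height")
    } else {
      v1 <- pstat(e$from, "atac_logfc") * pstat(e$to, "atac_logfc")
      v2 <- (pstat(e$from, "normalized_height") +
               pstat(e$to, "normalized_height")) / 2
    }
    rp <- desc_rank(v1) * desc_rank(v2)
    weight[sel] <- if (max(rp) == min(rp)) {
      rep(1, length(rp))
    } else {
      (max(rp) - rp) / (max(rp) - min(rp))
    }
  }
  edges$weight <- weight
  ids <- unique(c(edges$from, edges$to))
  kind <- ifelse(ids %in% genes$gene_id & !(ids %in% peaks$peak_id),
                 "gene", "peak")
  regulatory_graph(data.frame(id = ids, kind = kind,
                              stringsAsFactors = FALSE),
                   edges)
}

#' Add the weakly connected head node
#'
#' Appends one artificial head node connected to every existing node with a
#' small fixed weight. The head node guarantees the graph is connected so a
#' single dominant eigenvector spans all nodes, while perturbing the
#' centrality ranking only minimally; it stands for the diffuse regulatory
#' influence of the factor whose perturbation defined the network.
#'
#' @param g a \code{\link{regulatory_graph}} without a head node.
#' @param head_weight weight of every head edge.
#' @return The augmented \code{\link{regulatory_graph}}.
#' @export
augment_head_node <- function(g, head_weight = 0.01) {
  stopifnot(inherits(g, "regulatory_graph"))
  if (any(g$nodes$kind == "head")) {
    stop("graph already contains a head node")
  }
  if (nrow(g$nodes) == 0) stop("cannot augment an empty graph")
  head_id <- "head"
  while (head_id %in% g$nodes$id) head_id <- paste0(".", head_id)
  nodes <- rbind(g$nodes,
                 data.frame(id = head_id, kind = "head",
                            stringsAsFactors = FALSE))
  head_edges <- data.frame(from = head_id, to = g$nodes$id, class = "head",
                           weight = head_weight, stringsAsFactors = FALSE)
  regulatory_graph(nodes, rbind(g$edges, head_edges))
}

#' Weighted eigenvector centrality by power iteration
#'
#' Computes the dominant eigenvector of the symmetric weighted adjacency
#' matrix: the centrality of a node is proportional to the weighted sum of
#' its neighbours' centralities, with the dominant eigenvalue as scaling
#' constant. Power iteration starts from a uniform positive vector (no
#' randomness) and runs on a diagonally shifted matrix so that convergence is
#' guaranteed even on bipartite graphs, whose extreme eigenvalues are paired;
#' the shift leaves the eigenvectors untouched and the reported eigenvalue is
#' the Rayleigh quotient of the unshifted matrix. Scores are normalized so
#' the maximum over non-head nodes equals 1.
#'
#' @param g a \code{\link{regulatory_graph}} (connected; augment with
#'   \code{\link{augment_head_node}} first if needed).
#' @param tol convergence tolerance (max absolute change of the unit
#'   eigenvector between iterations).
#' @param max_iter iteration cap; if reached, \code{converged} is
#'   \code{FALSE}.
#' @return An object of class \code{centrality_result}: list with
#'   \code{scores} (named, max 1 over non-head nodes), \code{lambda}
#'   (dominant eigenvalue), \code{iterations}, \code{converged}.
#' @examples
#' g <- regulatory_graph(
#'   data.frame(id = c("c", "l1", "l2", "l3", "l4"),
#'              kind = c("gene", rep("peak", 4))),
#'   data.frame(from = "c", to = c("l1", "l2", "l3", "l4"),
#'              class = "peak_gene", weight = 1))
#' compute_eigencentrality(g)$scores
#' @export
compute_eigencentrality <- function(g, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(g, "regulatory_graph"))
  n <- nrow(g$nodes)
  if (n == 0) stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(g$nodes$id, g$nodes$id))
  if (nrow(g$edges) > 0) {
    i <- match(g$edges$from, g$nodes$id)
    j <- match(g$edges$to, g$nodes$id)
    A[cbind(i, j)] <- A[cbind(i, j)] + g$edges$weight
    A[cbind(j, i)] <- A[cbind(i, j)]
  }
  if (max(A) <= 0) stop("graph has no positive edge weights")

  sigma <- 0.1 * max(rowSums(A))  # breaks the +/- lambda pairing
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- as.vector(A %*% v) + sigma * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed to the zero vector")
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  lambda <- as.numeric(t(v) %*% A %*% v)
  v <- abs(v)
  non_head <- g$nodes$kind != "head"
  top <- max(v[non_head])
  scores <- setNames(if (top > 0) v / top else v, g$nodes$id)
  structure(list(scores = scores, lambda = lambda, iterations = iter,
                 converged = converged),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("eigencentrality: lambda =", format(x$lambda, digits = 6), "-",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Rank hub genes and enumerate E-P subnetworks
#'
#' Removes the head node, takes the connected components of the remaining
#' graph as the E-P interaction subnetworks, and ranks gene nodes by
#' centrality. For each gene the enhancer count is the number of peak nodes
#' in its component; the top enhancer nodes by centrality are reported
#' alongside.
#'
#' @param g the head-augmented \code{\link{regulatory_graph}} the centrality
#'   was computed on.
#' @param centrality a \code{\link{compute_eigencentrality}} result on
#'   \code{g}.
#' @return An object of class \code{hub_report}: \code{genes} (ranked
#'   data.frame with \code{gene_id}, \code{score}, \code{component},
#'   \code{n_enhancers}), \code{enhancers} (peak nodes ranked by score),
#'   \code{components} (sizes per subnetwork).
#' @export
rank_hubs <- function(g, centrality) {
  stopifnot(inherits(g, "regulatory_graph"),
            inherits(centrality, "centrality_result"))
  keep <- g$nodes$kind != "head"
  nodes <- g$nodes[keep, , drop = FALSE]
  head_ids <- g$nodes$id[!keep]
  edges <- g$edges[!(g$edges$from %in% head_ids |
                       g$edges$to %in% head_ids), , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$id)
  comp <- igraph::components(ig)
  membership <- comp$membership[nodes$id]

  sc <- centrality$scores[nodes$id]
  is_peak <- nodes$kind == "peak"
  peaks_per_comp <- tapply(is_peak, membership, sum)
  genes_per_comp <- tapply(!is_peak, membership, sum)

  gdf <- data.frame(
    gene_id = nodes$id[!is_peak],
    score = unname(sc[!is_peak]),
    component = unname(membership[!is_peak]),
    stringsAsFactors = FALSE
  )
  gdf$n_enhancers <- as.integer(peaks_per_comp[as.character(gdf$component)])
  gdf <- gdf[order(-gdf$score), , drop = FALSE]
  rownames(gdf) <- NULL

  pdf <- data.frame(
    peak_id = nodes$id[is_peak],
    score = unname(sc[is_peak]),
    component = unname(membership[is_peak]),
    stringsAsFactors = FALSE
  )
  pdf <- pdf[order(-pdf$score), , drop = FALSE]
  rownames(pdf) <- NULL

  comp_ids <- sort(unique(membership))
  cdf <- data.frame(
    component = comp_ids,
    n_nodes = as.integer(table(membership)[as.character(comp_ids)]),
    n_peaks = as.integer(peaks_per_comp[as.character(comp_ids)]),
    n_genes = as.integer(genes_per_comp[as.character(comp_ids)])
  )
  cdf <- cdf[order(-cdf$n_nodes), , drop = FALSE]
  rownames(cdf) <- NULL

  structure(list(genes = gdf, enhancers = pdf, components = cdf),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat("hub report:", nrow(x$genes), "genes across",
      nrow(x$components), "subnetworks; top genes:\n")
  print(head(x$genes, 5))
  invisible(x)
}

#' Upper-tail hypergeometric overlap enrichment
#'
#' Probability of observing at least \code{hits_in_set} marked elements in a
#' draw of \code{set_size} from a universe of \code{universe} elements of
#' which \code{hits_universe} are marked -- the standard test for asking
#' whether a peak set overlaps a reference feature set more than chance.
#'
#' @param hits_in_set marked elements observed in the set.
#' @param set_size size of the drawn set.
#' @param hits_universe marked elements in the universe.
#' @param universe universe size.
#' @return The p-value \code{P(X >= hits_in_set)}.
#' @examples
#' overlap_enrichment(2, 2, 2, 10)  # 1/45
#' @export
overlap_enrichment <- function(hits_in_set, set_size, hits_universe,
                               universe) {
  if (hits_in_set > set_size || set_size > universe ||
      hits_in_set > hits_universe || hits_universe > universe ||
      any(c(hits_in_set, set_size, hits_universe, universe) < 0)) {
    stop("inconsistent counts for hypergeometric test")
  }
  phyper(hits_in_set - 1, hits_universe, universe - hits_universe,
         set_size, lower.tail = FALSE)
}
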