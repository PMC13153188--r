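## Shared fixtures and independent oracles for the test suite.

## A hand-built candidate set covering one violation per cascade step:
##   t1 clean multi-exon intergenic; t2 too short; t3 unstranded;
##   t4 low expression; t5 single-exon near a same-strand coding gene;
##   t6 same-strand exonic overlap with the gene.
toy_cascade_fixture <- function() {
  gene <- data.frame(gene_id = "gene1", chrom = "chr1", start = 100000,
                     end = 110000, strand = "+", biotype = "protein_coding")
  gexons <- data.frame(gene_id = "gene1", chrom = "chr1",
                       start = c(100000, 104000, 109000),
                       end = c(100600, 104600, 110000), strand = "+")
  tx <- data.frame(
    transcript_id = paste0("t", 1:6),
    chrom = "chr1",
    start = c(10000, 20000, 30000, 40000, 110500, 104100),
    end = c(11200, 20150, 30800, 41200, 111300, 105600),
    strand = c("+", "+", ".", "+", "+", "+")
  )
  exons <- rbind(
    data.frame(transcript_id = "t1", chrom = "chr1",
               start = c(10000, 10800), end = c(10400, 11200), strand = "+"),
    data.frame(transcript_id = "t2", chrom = "chr1", start = 20000,
               end = 20150, strand = "+"),
    data.frame(transcript_id = "t3", chrom = "chr1",
               start = c(30000, 30500), end = c(30300, 30800), strand = "."),
    data.frame(transcript_id = "t4", chrom = "chr1",
               start = c(40000, 40800), end = c(40400, 41200), strand = "+"),
    data.frame(transcript_id = "t5", chrom = "chr1", start = 110500,
               end = 111300, strand = "+"),
    data.frame(transcript_id = "t6", chrom = "chr1",
               start = c(104100, 105200), end = c(104500, 105600),
               strand = "+")
  )
  fpkm <- matrix(5, nrow = 6, ncol = 6,
                 dimnames = list(paste0("t", 1:6), paste0("s", 1:6)))
  fpkm["t4", ] <- 0.5
  calls <- data.frame(
    transcript_id = paste0("t", 1:6), cpat_prob = 0.1, txcds_score = 100,
    cpc2_label = "noncoding", lncadeep_label = "noncoding",
    cnit_label = "noncoding", stringsAsFactors = FALSE
  )
  list(
    candidates = transcript_set(tx, exons, fpkm),
    annotation = gene_annotation(gene, gexons),
    blacklist = data.frame(chrom = character(), start = numeric(),
                           end = numeric()),
    low_complexity = data.frame(chrom = character(), start = numeric(),
                                end = numeric()),
    coding_calls = calls
  )
}

## Dense eigen-decomposition oracle for the weighted eigenvector centrality:
## independent of the power-iteration path.
dense_centrality_oracle <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(g$edges$from, ids)
  j <- match(g$edges$to, ids)
  A[cbind(i, j)] <- A[cbind(i, j)] + g$edges$weight
  A[cbind(j, i)] <- A[cbind(i, j)]
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  non_head <- g$nodes$kind != "head"
  setNames(v / max(v[non_head]), ids)
}

## Brute-force hypergeometric upper tail by enumerating all draws.
enumerate_overlap_pvalue <- function(hits_in_set, set_size, hits_universe,
                                     universe) {
  marked <- seq_len(hits_universe)
  draws <- utils::combn(universe, set_size)
  hits <- colSums(matrix(draws %in% marked, nrow = set_size))
  mean(hits >= hits_in_set)
}

## Standardized log-rank |z| at a fixed cutpoint via survival::survdiff,
## an implementation-independent route.
survdiff_abs_z <- function(time, event, low) {
  if (length(unique(low)) < 2) return(NA_real_)
  sd <- survival::survdiff(survival::Surv(time, event) ~ low)
  sqrt(sd$chisq)
}

## Deterministic digest for determinism contracts (no external deps).
object_digest <- function(x) {
  paste(utils::capture.output(str(x, digits.d = 12, vec.len = 1e6)),
        collapse = "\n")
}
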