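## File-format boundaries. Internal coordinates are 0-based half-open; GTF
## is written/read as 1-based inclusive, BED/BEDPE as 0-based half-open.

#' Write transcripts (optionally with positional categories) as GTF
#'
#' @param ts a \code{\link{transcript_set}}.
#' @param path output file.
#' @param categories optional named character vector (by transcript id)
#'   written as a \code{position_class} attribute.
#' @param source source field for column 2.
#' @return \code{path}, invisibly.
#' @export
write_gtf_transcripts <- function(ts, path, categories = NULL,
                                  source = "ephub") {
  stopifnot(inherits(ts, "transcript_set"))
  lines <- character(0)
  for (i in seq_len(nrow(ts$transcripts))) {
    t <- ts$transcripts[i, ]
    attr_extra <- if (!is.null(categories) &&
                      t$transcript_id %in% names(categories)) {
      sprintf(' position_class "%s";', categories[[t$transcript_id]])
    } else ""
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                     t$transcript_id, t$transcript_id, attr_extra)
    lines <- c(lines, paste(t$chrom, source, "transcript", t$start + 1,
                            t$end, ".", t$strand, ".", attrs, sep = "\t"))
    ex <- ts$exons[ts$exons$transcript_id == t$transcript_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[j], source, "exon", ex$start[j] + 1,
                              ex$end[j], ".", ex$strand[j], ".", attrs,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene annotation as GTF
#'
#' Emits \code{gene} and \code{exon} features with \code{gene_id} and
#' \code{gene_biotype} attributes.
#'
#' @param ann a \code{\link{gene_annotation}}.
#' @param path output file.
#' @param source source field for column 2.
#' @return \code{path}, invisibly.
#' @export
write_gtf_annotation <- function(ann, path, source = "ephub") {
  stopifnot(inherits(ann, "gene_annotation"))
  lines <- character(0)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id,
                     g$biotype)
    lines <- c(lines, paste(g$chrom, source, "gene", g$start + 1, g$end,
                            ".", g$strand, ".", attrs, sep = "\t"))
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[j], source, "exon", ex$start[j] + 1,
                              ex$end[j], ".", ex$strand[j], ".", attrs,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcripts from GTF
#'
#' @param path GTF file with \code{transcript} and \code{exon} features
#'   carrying \code{transcript_id} attributes.
#' @param fpkm optional FPKM matrix (rows named by transcript id).
#' @return A \code{\link{transcript_set}}.
#' @export
read_gtf_transcripts <- function(path, fpkm = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- granges_to_gi(gr)
  df$type <- as.character(gr$type)
  df$transcript_id <- gr$transcript_id
  tx <- df[df$type == "transcript",
           c("transcript_id", "chrom", "start", "end", "strand")]
  ex <- df[df$type == "exon",
           c("transcript_id", "chrom", "start", "end", "strand")]
  rownames(tx) <- rownames(ex) <- NULL
  transcript_set(tx, ex, fpkm)
}

#' Read a gene annotation from GTF
#'
#' @param path GTF file with \code{gene} and \code{exon} features carrying
#'   \code{gene_id} and \code{gene_biotype} attributes.
#' @return A \code{\link{gene_annotation}}.
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- granges_to_gi(gr)
  df$type <- as.character(gr$type)
  df$gene_id <- gr$gene_id
  df$biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else NA
  genes <- df[df$type == "gene",
              c("gene_id", "chrom", "start", "end", "strand", "biotype")]
  exons <- df[df$type == "exon",
              c("gene_id", "chrom", "start", "end", "strand")]
  rownames(genes) <- rownames(exons) <- NULL
  gene_annotation(genes, exons)
}

#' Write intervals as BED6
#'
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{name}, \code{score}, \code{strand}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chrom = intervals$chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) {
      ifelse(intervals$strand == ".", ".", intervals$strand)
    } else ".",
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file as an interval data.frame
#'
#' @param path BED file (3-6 columns).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} and, when present, \code{name} and \code{score}.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- granges_to_gi(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  df
}

#' Write loops as BEDPE
#'
#' Standard six coordinate columns plus the evidence source in the name
#' column.
#'
#' @param loops data.frame with \code{chrom1}, \code{start1}, \code{end1},
#'   \code{chrom2}, \code{start2}, \code{end2} and optionally \code{source}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(
    loops$chrom1,
    format(loops$start1, scientific = FALSE, trim = TRUE),
    format(loops$end1, scientific = FALSE, trim = TRUE),
    loops$chrom2,
    format(loops$start2, scientific = FALSE, trim = TRUE),
    format(loops$end2, scientific = FALSE, trim = TRUE),
    if ("source" %in% names(loops)) loops$source else ".",
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE
#'
#' @param path BEDPE file; a seventh column, when present, is read as the
#'   evidence source.
#' @return data.frame with the six coordinate columns and \code{source}.
#' @export
read_bedpe <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE needs at least 6 columns")
  out <- data.frame(
    chrom1 = as.character(df[[1]]), start1 = as.numeric(df[[2]]),
    end1 = as.numeric(df[[3]]), chrom2 = as.character(df[[4]]),
    start2 = as.numeric(df[[5]]), end2 = as.numeric(df[[6]]),
    source = if (ncol(df) >= 7) as.character(df[[7]]) else ".",
    stringsAsFactors = FALSE
  )
  out
}

#' Write or read a plain TSV table
#'
#' Thin wrappers fixing the conventions used by every table in the package
#' (tab separator, header, no quoting, no row names).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return \code{write_tsv_table}: \code{path}, invisibly;
#'   \code{read_tsv_table}: a data.frame.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write or read a genes-by-samples numeric matrix as TSV
#'
#' The first column (\code{gene}) holds row names; remaining columns are
#' samples.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return \code{write_matrix_tsv}: \code{path}, invisibly;
#'   \code{read_matrix_tsv}: a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a contact matrix as bin table plus triplets
#'
#' @param m a \code{\link{contact_matrix}}.
#' @param bins_path TSV receiving \code{bin_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @param triplets_path TSV receiving \code{bin1}, \code{bin2}, \code{count}
#'   (upper triangle including the diagonal, non-zero entries only).
#' @return \code{triplets_path}, invisibly.
#' @export
write_contact_matrix <- function(m, bins_path, triplets_path) {
  stopifnot(inherits(m, "contact_matrix"))
  write_tsv_table(m$bins, bins_path)
  n <- nrow(m$values)
  up <- which(upper.tri(m$values, diag = TRUE) & m$values != 0,
              arr.ind = TRUE)
  trip <- data.frame(bin1 = m$bins$bin_id[up[, 1]],
                     bin2 = m$bins$bin_id[up[, 2]],
                     count = m$values[up])
  trip <- trip[order(trip$bin1, trip$bin2), , drop = FALSE]
  write_tsv_table(trip, triplets_path)
  invisible(triplets_path)
}

#' Read a contact matrix from bin table plus triplets
#'
#' @param bins_path,triplets_path files as written by
#'   \code{\link{write_contact_matrix}}.
#' @return A \code{\link{contact_matrix}}.
#' @export
read_contact_matrix <- function(bins_path, triplets_path) {
  bins <- read_tsv_table(bins_path)
  trip <- read_tsv_table(triplets_path)
  n <- nrow(bins)
  idx <- match(trip$bin1, bins$bin_id)
  jdx <- match(trip$bin2, bins$bin_id)
  if (anyNA(idx) || anyNA(jdx)) stop("triplet references unknown bin id")
  v <- matrix(0, n, n)
  v[cbind(idx, jdx)] <- trip$count
  v[cbind(jdx, idx)] <- trip$count
  bs <- if (n > 1) bins$end[1] - bins$start[1] else bins$end[1]
  contact_matrix(bins$chrom[1], bs, bins, v)
}

#' Write an aggregate matrix as dense TSV
#'
#' @param a an \code{aggregate_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_aggregate_matrix <- function(a, path) {
  write.table(a$matrix, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
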