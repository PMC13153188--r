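#' Transcript models with exon structure and abundances
#'
#' The unit flowing through the lncRNA filter cascade: a transcript interval,
#' its ordered exon chain, and per-sample FPKM values.
#'
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (0-based
#'   half-open).
#' @param exons data.frame with columns \code{transcript_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}; exons of one transcript must be
#'   disjoint and lie within its interval.
#' @param fpkm numeric matrix, rows named by transcript id, columns by sample.
#' @return An object of class \code{transcript_set}.
#' @export
transcript_set <- function(transcripts, exons, fpkm = NULL) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  required <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(required %in% names(transcripts))) {
    stop("transcripts needs columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicated transcript ids")
  }
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan)) stop("exons reference unknown transcript(s)")
  ## per-transcript exon sanity: sorted, disjoint, inside the interval
  sp <- split(exons, exons$transcript_id)
  for (id in names(sp)) {
    e <- sp[[id]][order(sp[[id]]$start), ]
    t <- transcripts[transcripts$transcript_id == id, ]
    if (any(e$start < t$start) || any(e$end > t$end)) {
      stop("exons of ", id, " extend beyond the transcript interval")
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("exons of ", id, " overlap")
    }
  }
  if (!is.null(fpkm)) {
    fpkm <- as.matrix(fpkm)
    if (!all(transcripts$transcript_id %in% rownames(fpkm))) {
      stop("fpkm matrix must cover every transcript")
    }
    fpkm <- fpkm[transcripts$transcript_id, , drop = FALSE]
  }
  structure(list(transcripts = transcripts, exons = exons, fpkm = fpkm),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,",
      if (is.null(x$fpkm)) "no" else ncol(x$fpkm), "samples\n")
  invisible(x)
}

#' Gene annotation with exon structure and biotypes
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{biotype}.
#' @param exons data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @return An object of class \code{gene_annotation}.
#' @export
gene_annotation <- function(genes, exons) {
  required <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(required %in% names(genes))) {
    stop("genes needs columns: ", paste(required, collapse = ", "))
  }
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan)) stop("exons reference unknown gene(s)")
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "protein_coding"), "protein-coding ),",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Symmetric binned contact matrix
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param bins data.frame with columns \code{bin_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open, consecutive).
#' @param values symmetric non-negative numeric matrix, one row/column per
#'   bin.
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(chrom, bin_size, bins, values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (nrow(values) != nrow(bins)) stop("matrix dimension must match bin count")
  if (any(values < 0)) stop("contact values must be non-negative")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("contact matrix must be symmetric")
  }
  structure(list(chrom = chrom, bin_size = bin_size, bins = bins,
                 values = values),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", nrow(x$bins), "bins of",
      x$bin_size, "bp\n")
  invisible(x)
}
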