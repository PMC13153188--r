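#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open (\code{[start, end)}), the convention used
#' throughout the package; conversion to the 1-based inclusive convention
#' happens only at GTF boundaries.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; \code{start < end}.
#' @param strand character vector in \code{"+"}, \code{"-"}, \code{"."}.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad)) {
    stop("invalid interval(s): require 0 <= start < end at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  df
}

## 0-based half-open -> GRanges (1-based inclusive). Strand "." maps to "*".
gi_to_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if ("strand" %in% names(df)) df$strand else "."
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

granges_to_gi <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

## Any-overlap (>= 1 bp) of query intervals against subject intervals,
## ignoring strand. Returns a logical vector along query rows.
gi_overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(gi_to_granges(query), gi_to_granges(subject),
                       ignore.strand = TRUE)
}
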