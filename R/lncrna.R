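#' Parameters of the lncRNA filter cascade
#'
#' Defaults follow common practice for high-confidence lncRNA discovery from
#' patient transcriptome assemblies: a 200 bp minimum transcript length, an
#' expression floor of FPKM 1.0 reached in at least five samples, a 2 kb
#' proximity window for discarding single-exon fragments of annotated genes,
#' and the standard human coding-potential cutoffs for CPAT (0.364) and
#' txCdsPredict (800).
#'
#' @param min_length minimum total exonic length (bp).
#' @param min_fpkm expression floor; a transcript counts as expressed in a
#'   sample when FPKM >= \code{min_fpkm}.
#' @param min_samples minimum number of samples reaching \code{min_fpkm}.
#' @param proximity edge-to-edge gap (bp, boundary inclusive) within which a
#'   single-exon candidate is treated as a fragment of a same-strand gene.
#' @param cpat_cutoff CPAT coding-probability cutoff (predictions below are
#'   noncoding).
#' @param txcds_cutoff txCdsPredict score cutoff (scores below are noncoding).
#' @return An object of class \code{filter_params}.
#' @export
filter_params <- function(min_length = 200, min_fpkm = 1.0, min_samples = 5,
                          proximity = 2000, cpat_cutoff = 0.364,
                          txcds_cutoff = 800) {
  p <- list(min_length = min_length, min_fpkm = min_fpkm,
            min_samples = min_samples, proximity = proximity,
            cpat_cutoff = cpat_cutoff, txcds_cutoff = txcds_cutoff)
  if (any(unlist(p) <= 0)) stop("all filter parameters must be positive")
  structure(p, class = "filter_params")
}

.step_names <- c("blacklist_overlap", "length_strand", "expression",
                 "proximal_single_exon", "exonic_overlap", "coding_potential")

#' Consensus noncoding call over five coding-potential predictors
#'
#' A transcript is accepted as noncoding only when all five tools agree:
#' CPAT probability below the cutoff, txCdsPredict score below the cutoff,
#' and CPC2, lncADeep and CNIT all label it "noncoding".
#'
#' @param calls data.frame with columns \code{cpat_prob},
#'   \code{txcds_score}, \code{cpc2_label}, \code{lncadeep_label},
#'   \code{cnit_label} (one row per transcript; a \code{transcript_id}
#'   column, if present, is used for error messages).
#' @param params a \code{\link{filter_params}}.
#' @return Logical vector along rows of \code{calls}.
#' @examples
#' consensus_noncoding(data.frame(cpat_prob = 0.1, txcds_score = 100,
#'   cpc2_label = "noncoding", lncadeep_label = "noncoding",
#'   cnit_label = "noncoding"), filter_params())
#' @export
consensus_noncoding <- function(calls, params = filter_params()) {
  req <- c("cpat_prob", "txcds_score", "cpc2_label", "lncadeep_label",
           "cnit_label")
  missing_col <- setdiff(req, names(calls))
  if (length(missing_col)) {
    stop("coding call table lacks field(s): ",
         paste(missing_col, collapse = ", "))
  }
  incomplete <- Reduce(`|`, lapply(calls[req], is.na))
  if (any(incomplete)) {
    who <- if ("transcript_id" %in% names(calls)) {
      paste(calls$transcript_id[incomplete], collapse = ", ")
    } else {
      paste("row", paste(which(incomplete), collapse = ", "))
    }
    stop("missing coding-potential field(s) for: ", who)
  }
  calls$cpat_prob < params$cpat_cutoff &
    calls$txcds_score < params$txcds_cutoff &
    calls$cpc2_label == "noncoding" &
    calls$lncadeep_label == "noncoding" &
    calls$cnit_label == "noncoding"
}

#' Positional classification of transcripts against protein-coding genes
#'
#' Strand-agnostic, first match in precedence order: \emph{exonic} if any
#' transcript exon overlaps any coding exon; \emph{intronic} if the
#' transcript lies entirely within one intron of a coding gene;
#' \emph{overlapping} if the transcript interval overlaps a coding gene body
#' otherwise; \emph{intergenic} if it overlaps nothing. The precedence makes
#' the four labels a partition: every transcript receives exactly one.
#'
#' @param transcripts a \code{\link{transcript_set}}.
#' @param annotation a \code{\link{gene_annotation}}; only
#'   \code{protein_coding} genes are considered.
#' @return Named character vector of categories along the transcripts.
#' @export
classify_position <- function(transcripts, annotation) {
  stopifnot(inherits(transcripts, "transcript_set"),
            inherits(annotation, "gene_annotation"))
  tx <- transcripts$transcripts
  out <- setNames(rep("intergenic", nrow(tx)), tx$transcript_id)
  if (nrow(tx) == 0) return(out)

  coding <- annotation$genes[annotation$genes$biotype == "protein_coding", ]
  if (nrow(coding) == 0) return(out)
  cex <- annotation$exons[annotation$exons$gene_id %in% coding$gene_id, ]

  tx_gr <- gi_to_granges(tx)
  body_gr <- gi_to_granges(coding)
  out[IRanges::overlapsAny(tx_gr, body_gr, ignore.strand = TRUE)] <-
    "overlapping"

  ## intronic: transcript interval entirely within one intron
  introns <- gene_introns(coding, cex)
  if (nrow(introns) > 0) {
    within <- IRanges::overlapsAny(tx_gr, gi_to_granges(introns),
                                   type = "within", ignore.strand = TRUE)
    out[within] <- "intronic"
  }

  ## exonic: any transcript exon overlaps any coding exon
  if (nrow(cex) > 0 && nrow(transcripts$exons) > 0) {
    hit <- IRanges::overlapsAny(gi_to_granges(transcripts$exons),
                                gi_to_granges(cex), ignore.strand = TRUE)
    exonic_ids <- unique(transcripts$exons$transcript_id[hit])
    out[names(out) %in% exonic_ids] <- "exonic"
  }
  out
}

## introns of each gene: gaps between its sorted exons
gene_introns <- function(genes, exons) {
  sp <- split(exons, exons$gene_id)
  res <- lapply(names(sp), function(g) {
    e <- sp[[g]][order(sp[[g]]$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(chrom = e$chrom[-1], start = e$end[-nrow(e)],
               end = e$start[-1], strand = e$strand[-1])
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character()))
  }
  res[res$start < res$end, , drop = FALSE]
}

#' Apply the six-step candidate lncRNA filter cascade
#'
#' Steps, in order, each removing the transcripts that violate it first:
#' \enumerate{
#'   \item any overlap (>= 1 bp) with blacklist or low-complexity regions;
#'   \item total exonic length below \code{min_length} or missing strand;
#'   \item fewer than \code{min_samples} samples with FPKM >=
#'     \code{min_fpkm};
#'   \item single-exon transcripts within \code{proximity} bp (edge-to-edge,
#'     boundary inclusive) of a same-strand annotated gene;
#'   \item exonic overlap with exons of annotated genes on the same strand
#'     (opposite-strand overlap survives, preserving antisense transcripts);
#'   \item failure of the five-tool coding-potential consensus
#'     (\code{\link{consensus_noncoding}}).
#' }
#' Survivors are labelled with their positional category
#' (\code{\link{classify_position}}).
#'
#' @param candidates a \code{\link{transcript_set}} with an FPKM matrix.
#' @param annotation a \code{\link{gene_annotation}} including protein-coding
#'   and annotated noncoding genes.
#' @param blacklist,low_complexity interval data.frames (\code{chrom},
#'   \code{start}, \code{end}).
#' @param coding_calls data.frame of per-transcript predictor outputs (see
#'   \code{\link{consensus_noncoding}}); required for every candidate that
#'   survives steps 1-5.
#' @param params a \code{\link{filter_params}}.
#' @return An object of class \code{filter_report}: list with \code{steps}
#'   (per-step removal counts), \code{removed} (transcript id, step),
#'   \code{survivors} (transcript id, category).
#' @export
apply_filter_cascade <- function(candidates, annotation, blacklist,
                                 low_complexity, coding_calls,
                                 params = filter_params()) {
  stopifnot(inherits(candidates, "transcript_set"),
            inherits(annotation, "gene_annotation"))
  tx <- candidates$transcripts
  ids <- tx$transcript_id
  removed_at <- setNames(rep(NA_integer_, length(ids)), ids)
  alive <- function() is.na(removed_at)

  if (length(ids) > 0) {
    ## step 1: blacklist / low-complexity overlap
    excl <- rbind(
      blacklist[, c("chrom", "start", "end"), drop = FALSE],
      low_complexity[, c("chrom", "start", "end"), drop = FALSE]
    )
    excl$strand <- rep(".", nrow(excl))
    hit <- gi_overlaps_any(tx, excl)
    removed_at[alive() & hit] <- 1L

    ## step 2: exonic length / strand
    exlen <- tapply(candidates$exons$end - candidates$exons$start,
                    candidates$exons$transcript_id, sum)
    len <- as.numeric(exlen[ids])
    short <- len < params$min_length | tx$strand == "."
    removed_at[alive() & short] <- 2L

    ## step 3: expression prevalence
    if (is.null(candidates$fpkm)) stop("candidates carry no FPKM matrix")
    n_expr <- rowSums(candidates$fpkm >= params$min_fpkm)
    removed_at[alive() & n_expr[ids] < params$min_samples] <- 3L

    ## step 4: proximal single-exon fragments (same strand, gap inclusive)
    n_exons <- table(candidates$exons$transcript_id)
    single <- as.integer(n_exons[ids]) == 1L
    prox <- rep(FALSE, length(ids))
    for (s in c("+", "-")) {
      qi <- which(alive() & single & tx$strand == s)
      gs <- annotation$genes[annotation$genes$strand == s, ]
      if (length(qi) == 0 || nrow(gs) == 0) next
      d <- GenomicRanges::distanceToNearest(
        gi_to_granges(tx[qi, ]), gi_to_granges(gs), ignore.strand = TRUE)
      hits <- S4Vectors::queryHits(d)[S4Vectors::mcols(d)$distance <=
                                        params$proximity]
      prox[qi[hits]] <- TRUE
    }
    removed_at[alive() & prox] <- 4L

    ## step 5: same-strand exonic overlap with annotated genes
    ex_hit <- rep(FALSE, length(ids))
    for (s in c("+", "-")) {
      te <- candidates$exons[candidates$exons$strand == s, ]
      ge <- annotation$exons[annotation$exons$strand == s, ]
      if (nrow(te) == 0 || nrow(ge) == 0) next
      hit <- IRanges::overlapsAny(gi_to_granges(te), gi_to_granges(ge),
                                  ignore.strand = TRUE)
      ex_hit[ids %in% unique(te$transcript_id[hit])] <- TRUE
    }
    removed_at[alive() & ex_hit] <- 5L

    ## step 6: coding-potential consensus
    cand6 <- ids[alive()]
    if (length(cand6) > 0) {
      miss <- setdiff(cand6, coding_calls$transcript_id)
      if (length(miss)) {
        stop("no coding-potential calls for transcript(s): ",
             paste(miss, collapse = ", "))
      }
      cc <- coding_calls[match(cand6, coding_calls$transcript_id), ]
      nc <- consensus_noncoding(cc, params)
      removed_at[cand6[!nc]] <- 6L
    }
  }

  surv_ids <- ids[alive()]
  surv_set <- subset_transcript_set(candidates, surv_ids)
  categories <- classify_position(surv_set, annotation)

  removed <- data.frame(
    transcript_id = ids[!is.na(removed_at)],
    step = removed_at[!is.na(removed_at)],
    name = .step_names[removed_at[!is.na(removed_at)]],
    row.names = NULL, stringsAsFactors = FALSE
  )
  steps <- data.frame(
    step = seq_along(.step_names), name = .step_names,
    n_removed = as.integer(tabulate(removed$step, length(.step_names))),
    stringsAsFactors = FALSE
  )
  structure(list(
    steps = steps,
    removed = removed,
    survivors = data.frame(transcript_id = surv_ids,
                           category = unname(categories[surv_ids]),
                           row.names = NULL, stringsAsFactors = FALSE)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("lncRNA filter cascade:",
      sum(x$steps$n_removed) + nrow(x$survivors), "candidates ->",
      nrow(x$survivors), "survivors\n")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  step %d %-22s removed %d\n", x$steps$step[i],
                x$steps$name[i], x$steps$n_removed[i]))
  }
  if (nrow(x$survivors)) {
    print(table(x$survivors$category))
  }
  invisible(x)
}

#' Restrict a transcript set to the given transcript ids
#'
#' @param ts a \code{\link{transcript_set}}.
#' @param ids transcript ids to keep.
#' @return The restricted \code{\link{transcript_set}}.
#' @export
subset_transcript_set <- function(ts, ids) {
  transcript_set(
    ts$transcripts[ts$transcripts$transcript_id %in% ids, , drop = FALSE],
    ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE],
    if (is.null(ts$fpkm)) NULL else ts$fpkm[rownames(ts$fpkm) %in% ids, ,
                                            drop = FALSE]
  )
}
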