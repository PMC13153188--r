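#' Stitch enhancer peaks after TSS exclusion
#'
#' ROSE-parameterized pre-processing of enhancer signal peaks (typically
#' H3K27ac): peaks overlapping any TSS +/- \code{tss_exclusion} window are
#' dropped entirely (no trimming), and the remaining same-chromosome peaks
#' whose edge-to-edge gap is at most \code{stitch_distance} are merged
#' transitively into stitched regions whose signal is the sum over member
#' peaks.
#'
#' @param peaks data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{signal} (non-negative density) and optionally
#'   \code{peak_id}.
#' @param tss data.frame with columns \code{chrom}, \code{pos} (bp), or a
#'   numeric vector of positions when all peaks share one chromosome.
#' @param tss_exclusion half-width (bp) of the promoter exclusion window.
#' @param stitch_distance maximum gap (bp) bridged when stitching.
#' @return data.frame of stitched regions: \code{region_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_peaks}, \code{total_signal},
#'   \code{members} (comma-separated peak ids).
#' @examples
#' pk <- data.frame(chrom = "chr1", start = c(0, 10000, 30000),
#'                  end = c(500, 10500, 30500), signal = c(1, 2, 3))
#' stitch_enhancers(pk, tss = data.frame(chrom = character(), pos = numeric()))
#' @export
stitch_enhancers <- function(peaks, tss, tss_exclusion = 3000,
                             stitch_distance = 12500) {
  if (any(peaks$signal < 0)) stop("peak signal must be non-negative")
  if (is.numeric(tss) && !is.data.frame(tss)) {
    tss <- data.frame(chrom = unique(peaks$chrom)[1], pos = tss)
  }
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  }
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_peaks = integer(), total_signal = numeric(),
                      members = character(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(empty)

  ## drop peaks touching any TSS window: [pos - excl, pos + excl] inclusive
  if (nrow(tss) > 0) {
    win <- data.frame(chrom = tss$chrom,
                      start = pmax(0, tss$pos - tss_exclusion),
                      end = tss$pos + tss_exclusion + 1, strand = ".")
    drop <- gi_overlaps_any(
      data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                 strand = "."), win)
    peaks <- peaks[!drop, , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(empty)

  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  ## gap measured against the running maximum end so contained peaks
  ## never split a region
  grp <- integer(nrow(peaks))
  g <- 0L; cur_end <- -Inf; cur_chrom <- ""
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != cur_chrom ||
        peaks$start[i] - cur_end > stitch_distance) {
      g <- g + 1L
      cur_chrom <- peaks$chrom[i]
      cur_end <- peaks$end[i]
    } else {
      cur_end <- max(cur_end, peaks$end[i])
    }
    grp[i] <- g
  }
  res <- do.call(rbind, lapply(split(peaks, grp), function(p) {
    data.frame(chrom = p$chrom[1], start = min(p$start), end = max(p$end),
               n_peaks = nrow(p), total_signal = sum(p$signal),
               members = paste(p$peak_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$region_id <- sprintf("SE_region%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("region_id", "chrom", "start", "end", "n_peaks", "total_signal",
          "members")]
}

#' Call super-enhancers on the ranked signal curve
#'
#' Stitched regions are sorted ascending by total signal; rank and signal are
#' min-max scaled to the unit square, and the cutoff is placed at the first
#' point (scanning ascending) whose centered-difference slope exceeds 1 --
#' the tangent rule of the ROSE rank curve. Regions with signal strictly
#' above the cutoff signal are flagged super-enhancers.
#'
#' @param regions data.frame from \code{\link{stitch_enhancers}} (needs
#'   \code{region_id} and \code{total_signal}).
#' @return List of class \code{se_call}: \code{regions} (input sorted
#'   ascending with \code{rank}, \code{is_super}), \code{curve} (data.frame
#'   \code{x}, \code{y}, \code{slope} on the scaled curve),
#'   \code{cutoff_signal}, \code{n_super}.
#' @examples
#' r <- data.frame(region_id = letters[1:5], total_signal = c(1, 1, 1, 1, 96))
#' call_superenhancers(r)$n_super
#' @export
call_superenhancers <- function(regions) {
  if (nrow(regions) < 2) stop("need at least 2 stitched regions")
  ord <- order(regions$total_signal)
  regions <- regions[ord, , drop = FALSE]
  s <- regions$total_signal
  n <- length(s)
  if (max(s) == min(s)) {
    warning("all stitched signals identical; no super-enhancers called")
    regions$rank <- seq_len(n)
    regions$is_super <- FALSE
    rownames(regions) <- NULL
    return(structure(list(regions = regions, curve = NULL,
                          cutoff_signal = NA_real_, n_super = 0L),
                     class = "se_call"))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  cut_idx <- which(slope > 1)[1]
  if (is.na(cut_idx)) {
    warning("rank-curve slope never exceeds 1; no super-enhancers called")
    cutoff <- Inf
  } else {
    cutoff <- s[cut_idx]
  }
  regions$rank <- seq_len(n)
  regions$is_super <- s > cutoff
  rownames(regions) <- NULL
  structure(list(
    regions = regions,
    curve = data.frame(x = x, y = y, slope = slope),
    cutoff_signal = if (is.finite(cutoff)) cutoff else NA_real_,
    n_super = sum(regions$is_super)
  ), class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat("super-enhancer call:", nrow(x$regions), "stitched regions,",
      x$n_super, "super (cutoff signal ",
      format(x$cutoff_signal, digits = 4), ")\n")
  invisible(x)
}

#' Assign genes to super-enhancers by TSS distance
#'
#' A (super-enhancer, gene) pair is emitted when the gene TSS lies within
#' \code{window} bp of the nearest region boundary (distance 0 when the TSS
#' falls inside the region).
#'
#' @param ses data.frame of regions (\code{region_id}, \code{chrom},
#'   \code{start}, \code{end}); typically the \code{is_super} subset of a
#'   \code{\link{call_superenhancers}} result.
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss}.
#' @param window maximum TSS-to-boundary distance (bp), inclusive.
#' @return data.frame with columns \code{region_id}, \code{gene_id},
#'   \code{distance}.
#' @export
assign_se_genes <- function(ses, genes, window = 50000) {
  out <- data.frame(region_id = character(), gene_id = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(ses) == 0 || nrow(genes) == 0) return(out)
  for (i in seq_len(nrow(ses))) {
    same <- genes[genes$chrom == ses$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) next
    inside <- same$tss >= ses$start[i] & same$tss < ses$end[i]
    d <- ifelse(inside, 0,
                pmin(abs(same$tss - ses$start[i]),
                     abs(same$tss - (ses$end[i] - 1))))
    keep <- d <= window
    if (any(keep)) {
      out <- rbind(out, data.frame(region_id = ses$region_id[i],
                                   gene_id = same$gene_id[keep],
                                   distance = d[keep],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a ranked enhancer curve with a planted elbow
#'
#' Generates stitched-region signals made of a dense low background plus a
#' small set of planted high-signal regions separated from the background by
#' a large jump, so the rank-curve tangent cutoff has an unambiguous planted
#' answer. Used to exercise \code{\link{call_superenhancers}} end to end.
#'
#' @param seed RNG seed.
#' @param n_background number of background regions (signals on a low range).
#' @param n_super number of planted super-enhancer regions.
#' @return List: \code{regions} (data.frame \code{region_id},
#'   \code{total_signal}), \code{truth} (ids of planted super regions).
#' @export
simulate_enhancer_curve <- function(seed = 1, n_background = 95,
                                    n_super = 5) {
  stopifnot(n_background >= 10, n_super >= 1)
  with_op_seed(seed, "enhancer_curve", {
    bg <- sort(runif(n_background, 1, 50))
    planted <- max(bg) + cumsum(runif(n_super, 100, 300))
    regions <- data.frame(
      region_id = sprintf("R%04d", seq_len(n_background + n_super)),
      total_signal = c(bg, planted),
      stringsAsFactors = FALSE
    )
    list(regions = regions,
         truth = regions$region_id[(n_background + 1):(n_background + n_super)])
  })
}
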