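#' Vanilla-coverage square-root normalization
#'
#' Divides every contact by the square root of the product of its row and
#' column sums (\code{m_ij / sqrt(r_i * c_j)}), the VC-sqrt balancing used
#' before aggregate peak analysis. Rows or columns with zero total are left
#' at zero. The transform is scale-equivariant: multiplying the matrix by a
#' constant leaves the output unchanged.
#'
#' @param m a \code{\link{contact_matrix}}.
#' @return The normalized \code{\link{contact_matrix}}.
#' @examples
#' b <- data.frame(bin_id = 0:1, chrom = "c", start = c(0, 10), end = c(10, 20))
#' m <- contact_matrix("c", 10, b, matrix(c(4, 2, 2, 1), 2))
#' round(normalize_vc_sqrt(m)$values, 3)
#' @export
normalize_vc_sqrt <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  r <- rowSums(v)
  denom <- sqrt(outer(r, r))  # symmetric: column sums equal row sums
  out <- ifelse(denom > 0, v / denom, 0)
  contact_matrix(m$chrom, m$bin_size, m$bins, out)
}

#' Observed-over-expected transform
#'
#' Divides each contact by the expected value at its bin distance, where
#' \code{expected(d)} is the mean of all entries at distance \code{d} --
#' removing the distance-decay background. Entries whose distance has zero
#' expectation are set to zero.
#'
#' @param m a \code{\link{contact_matrix}}.
#' @return The transformed \code{\link{contact_matrix}}.
#' @export
observed_over_expected <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  n <- nrow(v)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected_by_d <- tapply(as.vector(v), as.vector(d), mean)
  expected <- matrix(expected_by_d[as.character(d)], n, n)
  out <- ifelse(expected > 0, v / expected, 0)
  contact_matrix(m$chrom, m$bin_size, m$bins, out)
}

#' Aggregate contact windows over loop anchors
#'
#' For each intra-chromosomal loop whose anchor-midpoint distance lies within
#' \code{[min_dist, max_dist]}, extracts the \code{(n_bins + 1)} by
#' \code{(n_bins + 1)} submatrix centered on the anchor-pair bin of the
#' transformed matrix (VC-sqrt normalization followed by observed/expected,
#' in that order, by default) and averages the windows element-wise. Windows
#' that would cross the matrix boundary are skipped and counted. Rows of the
#' window run along the upstream anchor (upstream to downstream, top to
#' bottom), columns along the downstream anchor.
#'
#' @param m a \code{\link{contact_matrix}} of raw counts.
#' @param loops data.frame of loops (\code{chrom1}, \code{start1},
#'   \code{end1}, \code{chrom2}, \code{start2}, \code{end2}); anchors are
#'   mapped to bins by midpoint.
#' @param min_dist,max_dist inclusive anchor distance range (bp).
#' @param n_bins window reach: the window spans \code{n_bins / 2} bins on
#'   each side of the center (side length \code{n_bins + 1}, so 31 for the
#'   default 30).
#' @param transform one of \code{"vc_sqrt_obs_exp"} (default),
#'   \code{"obs_exp"} (no balancing), \code{"none"}.
#' @return An object of class \code{aggregate_matrix}: list with
#'   \code{matrix} (odd square), \code{n_loops} (aggregated), \code{n_skipped}
#'   (windows crossing the boundary).
#' @export
aggregate_contacts <- function(m, loops, min_dist = 50000,
                               max_dist = 1000000, n_bins = 30,
                               transform = c("vc_sqrt_obs_exp", "obs_exp",
                                             "none")) {
  stopifnot(inherits(m, "contact_matrix"))
  transform <- match.arg(transform)
  if (n_bins %% 2 != 0) stop("n_bins must be even (odd window side)")
  half <- n_bins / 2
  n <- nrow(m$values)

  intra <- loops$chrom1 == loops$chrom2 & loops$chrom1 == m$chrom
  loops <- loops[intra, , drop = FALSE]
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  dist <- abs(mid2 - mid1)
  loops <- loops[dist >= min_dist & dist <= max_dist, , drop = FALSE]
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  if (nrow(loops) == 0) {
    stop("no loops retained within the distance range")
  }

  t <- switch(transform,
    vc_sqrt_obs_exp = observed_over_expected(normalize_vc_sqrt(m)),
    obs_exp = observed_over_expected(m),
    none = m
  )
  v <- t$values
  bs <- m$bin_size
  ## orient windows so rows follow the upstream (smaller coordinate) anchor
  b1 <- floor(pmin(mid1, mid2) / bs) + 1
  b2 <- floor(pmax(mid1, mid2) / bs) + 1

  acc <- matrix(0, n_bins + 1, n_bins + 1)
  used <- 0L; skipped <- 0L
  for (k in seq_along(b1)) {
    ri <- (b1[k] - half):(b1[k] + half)
    ci <- (b2[k] - half):(b2[k] + half)
    if (min(ri) < 1 || min(ci) < 1 || max(ri) > n || max(ci) > n) {
      skipped <- skipped + 1L
      next
    }
    acc <- acc + v[ri, ci]
    used <- used + 1L
  }
  if (used == 0) stop("all loop windows crossed the matrix boundary")
  structure(list(matrix = acc / used, n_loops = used, n_skipped = skipped),
            class = "aggregate_matrix")
}

#' @export
print.aggregate_matrix <- function(x, ...) {
  cat("aggregate_matrix:", nrow(x$matrix), "x", ncol(x$matrix), "over",
      x$n_loops, "loops (", x$n_skipped, "skipped )\n")
  invisible(x)
}

#' APA corner-ratio score
#'
#' The aggregate peak analysis score: the center pixel (the loop anchor
#' pair) divided by the mean of the 3x3 pixel block in the bottom-left
#' corner of the aggregate (last rows, first columns under the row
#' orientation of \code{\link{aggregate_contacts}} -- the short-distance
#' background corner). Scores above 1 indicate focal enrichment at the
#' aggregated anchors.
#'
#' @param a an \code{aggregate_matrix} (odd square, side >= 7).
#' @return The score (a single number).
#' @examples
#' a <- structure(list(matrix = matrix(1, 31, 31), n_loops = 1L,
#'                     n_skipped = 0L), class = "aggregate_matrix")
#' apa_score(a)  # 1
#' @export
apa_score <- function(a) {
  stopifnot(inherits(a, "aggregate_matrix"))
  mat <- a$matrix
  n <- nrow(mat)
  if (n != ncol(mat) || n %% 2 == 0) stop("aggregate must be an odd square")
  if (n < 7) stop("aggregate too small for a 3x3 corner")
  center <- mat[(n + 1) / 2, (n + 1) / 2]
  corner <- mat[(n - 2):n, 1:3]
  if (mean(corner) <= 0) stop("undefined APA score: corner mean is zero")
  center / mean(corner)
}

#' Element-wise mean of aggregate matrices across replicates
#'
#' @param aggs list of \code{aggregate_matrix} objects of identical
#'   dimensions.
#' @return An \code{aggregate_matrix} with the element-wise mean;
#'   \code{n_loops} is summed for reporting.
#' @export
mean_aggregate <- function(aggs) {
  stopifnot(length(aggs) >= 1)
  dims <- vapply(aggs, function(a) dim(a$matrix), numeric(2))
  if (any(dims != dims[, 1])) stop("aggregate dimensions differ")
  acc <- Reduce(`+`, lapply(aggs, `[[`, "matrix")) / length(aggs)
  structure(list(matrix = acc,
                 n_loops = sum(vapply(aggs, `[[`, integer(1), "n_loops")),
                 n_skipped = sum(vapply(aggs, `[[`, integer(1),
                                        "n_skipped"))),
            class = "aggregate_matrix")
}
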