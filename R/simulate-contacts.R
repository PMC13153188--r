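#' Simulate planted loops for contact-matrix aggregation
#'
#' Draws intra-chromosomal loops whose anchor midpoints fall on bin centers
#' of the configured contact grid, with bin distances uniform between
#' \code{min_dist} and \code{max_dist} and both windows of the later 31x31
#' aggregation kept inside the matrix.
#'
#' @param cfg a \code{\link{sim_config}} (see its \code{contact} element).
#' @param min_dist,max_dist anchor midpoint distance range (bp).
#' @param margin_bins bins kept clear of the matrix edges so aggregation
#'   windows never cross the boundary.
#' @return data.frame of loops (\code{chrom1}, \code{start1}, \code{end1},
#'   \code{chrom2}, \code{start2}, \code{end2}, \code{source}).
#' @export
simulate_contact_loops <- function(cfg, min_dist = 50000,
                                   max_dist = 1000000, margin_bins = 16) {
  stopifnot(inherits(cfg, "sim_config"))
  cp <- cfg$contact
  bs <- cp$bin_size
  dmin <- ceiling(min_dist / bs)
  dmax <- floor(max_dist / bs)
  if (dmax + 2 * margin_bins >= cp$n_bins) {
    stop("n_bins too small for the requested distance range")
  }
  with_op_seed(cfg$seed, "contact_loops", {
    lo <- margin_bins + 1
    seen <- character(0)
    i <- integer(cp$n_loops); j <- integer(cp$n_loops)
    for (k in seq_len(cp$n_loops)) {
      repeat {  # resample until the bin pair is unique
        ds <- seq(dmin, dmax)
        dd <- ds[sample.int(length(ds), 1)]
        is <- seq(lo, cp$n_bins - margin_bins - dd)
        ii <- is[sample.int(length(is), 1)]
        key <- paste(ii, ii + dd)
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      i[k] <- ii; j[k] <- ii + dd
    }
    mid1 <- (i - 1) * bs + bs / 2
    mid2 <- (j - 1) * bs + bs / 2
    data.frame(
      chrom1 = "chrC", start1 = mid1 - 500, end1 = mid1 + 500,
      chrom2 = "chrC", start2 = mid2 - 500, end2 = mid2 + 500,
      source = "hichip", stringsAsFactors = FALSE
    )
  })
}

#' Simulate replicate contact matrices with planted loop enrichment
#'
#' The background follows a monotone distance decay,
#' \code{expected(d) = base_count / (1 + d / decay_scale)} with \code{d} the
#' genomic distance between bin midpoints; the bin pair under each planted
#' loop anchor pair is multiplied by the enrichment factor \code{f}; when
#' noise is on, each replicate resamples every cell from a Poisson
#' distribution with the constructed intensity (symmetrically).
#'
#' @param cfg a \code{\link{sim_config}} (see its \code{contact} element).
#' @param loops data.frame of intra-chromosomal loops (as from
#'   \code{\link{simulate_contact_loops}}); anchors are mapped to bins by
#'   midpoint and must fall inside the binned range.
#' @return List of \code{\link{contact_matrix}} objects, one per replicate.
#' @examples
#' cfg <- sim_config(seed = 2, contact = list(n_bins = 80, n_loops = 4,
#'                                            noise = FALSE))
#' loops <- simulate_contact_loops(cfg, max_dist = 2e5)
#' m <- simulate_contacts(cfg, loops)
#' length(m)
#' @export
simulate_contacts <- function(cfg, loops) {
  stopifnot(inherits(cfg, "sim_config"))
  cp <- cfg$contact
  n <- cp$n_bins
  bs <- cp$bin_size
  bins <- data.frame(
    bin_id = seq_len(n) - 1L,
    chrom = rep("chrC", n),
    start = (seq_len(n) - 1) * bs,
    end = seq_len(n) * bs
  )
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * bs
  base <- cp$base_count / (1 + d / cp$decay_scale)

  if (nrow(loops) > 0) {
    b1 <- floor(((loops$start1 + loops$end1) / 2) / bs) + 1
    b2 <- floor(((loops$start2 + loops$end2) / 2) / bs) + 1
    bad <- b1 < 1 | b1 > n | b2 < 1 | b2 > n
    if (any(bad)) {
      stop("loop anchor(s) outside the binned range at row(s): ",
           paste(which(bad), collapse = ", "))
    }
    for (k in seq_along(b1)) {
      base[b1[k], b2[k]] <- base[b1[k], b2[k]] * cp$enrichment_factor
      base[b2[k], b1[k]] <- base[b1[k], b2[k]]
    }
  }

  with_op_seed(cfg$seed, "contacts", {
    lapply(seq_len(cp$n_replicates), function(r) {
      values <- if (cp$noise) {
        up <- upper.tri(base, diag = TRUE)
        v <- matrix(0, n, n)
        v[up] <- rpois(sum(up), base[up])
        v + t(v) - diag(diag(v))
      } else {
        base
      }
      contact_matrix("chrC", bs, bins, values)
    })
  })
}

#' Simulate an expression/survival cohort with planted signature activity
#'
#' Each sample carries a latent activity \code{a ~ N(0, 1)}; the expression
#' of every signature gene is \code{a} plus independent Gaussian noise, while
#' background genes are pure noise. Survival times are exponential with
#' hazard \code{baseline_hazard * exp(effect_beta * a)}; independently of
#' everything else a fraction \code{censor_rate} of samples is censored at a
#' uniform point before its event time.
#'
#' @param cfg a \code{\link{sim_config}} (see its \code{cohort} element).
#' @param signature optional character vector of signature gene names; by
#'   default \code{SIG001 ...} up to \code{n_signature_genes}.
#' @return List of class \code{cohort_table}: \code{expr} (genes x samples
#'   matrix), \code{survival} (data.frame \code{sample}, \code{time},
#'   \code{event}), \code{signature}, \code{truth} (list: \code{activity},
#'   \code{group} -- "high"/"low" by the sign of the latent activity).
#' @export
simulate_cohort <- function(cfg, signature = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  co <- cfg$cohort
  if (is.null(signature)) {
    signature <- sprintf("SIG%03d", seq_len(co$n_signature_genes))
  }
  if (length(signature) < 1) stop("need at least one signature gene")
  with_op_seed(cfg$seed, "cohort", {
    ns <- co$n_samples
    samples <- sprintf("PT%04d", seq_len(ns))
    a <- rnorm(ns)
    sig_expr <- matrix(rep(a, each = length(signature)), nrow = length(signature)) +
      matrix(rnorm(length(signature) * ns, 0, co$noise_sd),
             nrow = length(signature))
    bg <- matrix(rnorm(co$n_background_genes * ns),
                 nrow = co$n_background_genes)
    expr <- rbind(sig_expr, bg)
    rownames(expr) <- c(signature,
                        sprintf("BG%03d", seq_len(co$n_background_genes)))
    colnames(expr) <- samples

    hazard <- co$baseline_hazard * exp(co$effect_beta * a)
    t_event <- rexp(ns, rate = hazard)
    censored <- rbinom(ns, 1, co$censor_rate) == 1
    time <- t_event
    time[censored] <- t_event[censored] * runif(sum(censored))
    time <- pmax(time, 1e-6)
    surv <- data.frame(sample = samples, time = time,
                       event = as.integer(!censored),
                       stringsAsFactors = FALSE)
    structure(list(
      expr = expr, survival = surv, signature = signature,
      truth = list(activity = setNames(a, samples),
                   group = setNames(ifelse(a > stats::median(a), "high", "low"),
                                    samples))
    ), class = "cohort_table")
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", ncol(x$expr), "samples,", nrow(x$expr), "genes (",
      length(x$signature), "signature ),",
      sum(x$survival$event), "events\n")
  invisible(x)
}
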