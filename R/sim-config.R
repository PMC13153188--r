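#' Configuration for the synthetic data generators
#'
#' Bundles the parameters of every \code{simulate_*} generator. The defaults
#' describe the reference simulation used throughout the package tests: a
#' planted hub gene wired to 19 enhancer peaks (the size of the strongest E-P
#' subnetwork the method is designed to recover), crisp differential
#' statistics on either side of the selection thresholds, a distance-decay
#' contact background with focal loop enrichment, and a cohort with a planted
#' hazard effect of signature activity.
#'
#' @param seed integer; every generator derives its own RNG stream from
#'   \code{(seed, operation-name)} so adding one generator never shifts the
#'   draws of another.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp) used to
#'   place annotation features.
#' @param n_samples number of expression samples in the simulated FPKM matrix.
#' @param transcript_counts named integer vector: number of candidates to
#'   plant per scenario. Clean scenarios (\code{clean_intergenic},
#'   \code{clean_intronic}, \code{clean_exonic_antisense},
#'   \code{clean_overlapping}) survive the filter cascade with a known
#'   positional category; violation scenarios (\code{violation_blacklist},
#'   \code{violation_short}, \code{violation_unstranded},
#'   \code{violation_low_expr}, \code{violation_proximal},
#'   \code{violation_exon_overlap}, \code{violation_coding}) are removed at a
#'   known step.
#' @param network list of gene-peak network parameters: \code{n_genes},
#'   \code{n_peaks}, \code{hub_k} (enhancer peaks wired to the planted hub),
#'   \code{decoy_max_degree}, \code{selected_logfc_mean},
#'   \code{selected_logfc_sd}, \code{selected_fdr_max}.
#' @param contact list of contact-matrix parameters: \code{bin_size} (bp),
#'   \code{n_bins}, \code{decay_scale} (bp; distance at which the background
#'   halves relative to short range), \code{base_count} (count scale at
#'   distance 0), \code{enrichment_factor} (multiplier \code{f >= 1} applied
#'   to planted loop pixels), \code{noise} (Poisson resampling on/off),
#'   \code{n_replicates}, \code{n_loops}.
#' @param cohort list of cohort parameters: \code{n_samples},
#'   \code{n_signature_genes}, \code{n_background_genes}, \code{effect_beta}
#'   (log hazard ratio per unit latent activity), \code{censor_rate} in
#'   \code{[0, 1)}, \code{baseline_hazard} (events/day), \code{noise_sd}
#'   (expression noise around the latent activity).
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$network$hub_k
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chrS = 1e8),
                       n_samples = 10,
                       transcript_counts = c(
                         clean_intergenic = 5,
                         clean_intronic = 5,
                         clean_exonic_antisense = 5,
                         clean_overlapping = 5,
                         violation_blacklist = 5,
                         violation_short = 5,
                         violation_unstranded = 5,
                         violation_low_expr = 5,
                         violation_proximal = 5,
                         violation_exon_overlap = 5,
                         violation_coding = 5
                       ),
                       network = list(),
                       contact = list(),
                       cohort = list()) {
  default_counts <- c(
    clean_intergenic = 0, clean_intronic = 0, clean_exonic_antisense = 0,
    clean_overlapping = 0, violation_blacklist = 0, violation_short = 0,
    violation_unstranded = 0, violation_low_expr = 0, violation_proximal = 0,
    violation_exon_overlap = 0, violation_coding = 0
  )
  unknown <- setdiff(names(transcript_counts), names(default_counts))
  if (length(unknown)) {
    stop("unknown transcript scenario(s): ", paste(unknown, collapse = ", "))
  }
  default_counts[names(transcript_counts)] <- transcript_counts

  network <- modify_defaults(list(
    n_genes = 12, n_peaks = 60, hub_k = 19, decoy_max_degree = 3,
    selected_logfc_mean = -0.8, selected_logfc_sd = 0.2,
    selected_fdr_max = 0.04
  ), network)
  contact <- modify_defaults(list(
    bin_size = 5000, n_bins = 400, decay_scale = 250000, base_count = 500,
    enrichment_factor = 3, noise = TRUE, n_replicates = 2, n_loops = 50
  ), contact)
  cohort <- modify_defaults(list(
    n_samples = 200, n_signature_genes = 25, n_background_genes = 50,
    effect_beta = log(3), censor_rate = 0.2, baseline_hazard = 0.001,
    noise_sd = 0.5
  ), cohort)

  if (any(default_counts < 0)) stop("transcript counts must be >= 0")
  if (contact$enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (cohort$censor_rate < 0 || cohort$censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector")
  }

  structure(list(
    seed = as.integer(seed),
    chrom_sizes = chrom_sizes,
    n_samples = as.integer(n_samples),
    transcript_counts = default_counts,
    network = network,
    contact = contact,
    cohort = cohort
  ), class = "sim_config")
}

modify_defaults <- function(defaults, values) {
  if (length(values) == 0) return(defaults)
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(values)] <- values
  defaults
}

## Derive a deterministic sub-seed from (seed, operation name) so that each
## generator owns an independent RNG stream.
op_seed <- function(seed, op) {
  codes <- utf8ToInt(op)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((as.numeric(seed) * 7919 + h) %% (.Machine$integer.max - 1L))
}

## Evaluate `expr` under a seeded RNG stream, restoring the caller's RNG state.
with_op_seed <- function(seed, op, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(op_seed(seed, op))
  expr
}
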