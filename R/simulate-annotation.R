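#' Simulate an annotation, candidate transcripts and planted filter truth
#'
#' Generates a protein-coding annotation, a set of candidate transcripts, a
#' blacklist / low-complexity interval set and coding-potential calls, wired
#' so that every candidate either survives the six-step lncRNA filter cascade
#' with a known positional category, or is removed at exactly one known step.
#' Each candidate occupies its own genomic block (50 kb) so scenarios cannot
#' interact: clean intergenic/overlapping transcripts stay well beyond the
#' proximity window of any host gene, and host genes exist only inside blocks
#' whose scenario needs one.
#'
#' Scenario geometry (offsets within a block, bp): host genes are 10 kb with
#' exons at \code{[0,500)}, \code{[3000,3500)}, \code{[9500,10000)} on the
#' plus strand. Clean intronic candidates sit antisense inside the second
#' intron; clean exonic candidates overlap the middle exon antisense; clean
#' overlapping candidates straddle the gene 3' end without touching an exon
#' (multi-exon, antisense).
#'
#' @param cfg a \code{\link{sim_config}}; \code{cfg$transcript_counts} sets
#'   how many candidates to plant per scenario and \code{cfg$n_samples} the
#'   width of the FPKM matrix (at least 5, so that clean candidates clear the
#'   default prevalence filter).
#' @return A list with elements \code{annotation}
#'   (\code{\link{gene_annotation}}), \code{candidates}
#'   (\code{\link{transcript_set}} with FPKM), \code{blacklist} and
#'   \code{low_complexity} (interval data.frames), \code{coding_calls}
#'   (data.frame, one row per candidate) and \code{truth} (data.frame with
#'   \code{transcript_id}, \code{scenario}, \code{status}, \code{step},
#'   \code{category}).
#' @examples
#' sim <- simulate_annotation(sim_config(seed = 1))
#' table(sim$truth$status)
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 5) {
    stop("n_samples must be >= 5 so clean candidates pass the prevalence filter")
  }
  counts <- cfg$transcript_counts
  scenarios <- rep(names(counts), counts)
  block <- 50000

  ## capacity check, naming the offending chromosome
  capacity <- floor(cfg$chrom_sizes / block)
  if (any(capacity < 1)) {
    small <- names(cfg$chrom_sizes)[capacity < 1][1]
    stop("chromosome ", small, " is too small to place any feature block (",
         block, " bp needed)")
  }
  if (length(scenarios) > sum(capacity)) {
    stop("chromosome(s) ", paste(names(cfg$chrom_sizes), collapse = ", "),
         " too small: ", length(scenarios), " blocks of ", block,
         " bp requested, capacity ", sum(capacity))
  }

  with_op_seed(cfg$seed, "annotation", {
    scenarios <- if (length(scenarios) > 1) sample(scenarios) else scenarios
    ## block -> chromosome assignment, filling chromosomes in order
    chrom_of <- rep(names(cfg$chrom_sizes), capacity)[seq_along(scenarios)]
    idx_in_chrom <- stats::ave(seq_along(scenarios), chrom_of,
                               FUN = seq_along)

    genes <- list(); gexons <- list()
    txs <- list(); texons <- list()
    blacklist <- list(); lcr <- list()
    truth <- list()
    fpkm <- list()
    calls <- list()
    n_lcr_used <- 0

    for (i in seq_along(scenarios)) {
      sc <- scenarios[i]
      chrom <- chrom_of[i]
      p <- (idx_in_chrom[i] - 1) * block + 5000
      tid <- sprintf("TU%04d", i)
      gid <- sprintf("G%04d", i)

      host <- function() {
        genes[[length(genes) + 1]] <<- data.frame(
          gene_id = gid, chrom = chrom, start = p, end = p + 10000,
          strand = "+", biotype = "protein_coding")
        gexons[[length(gexons) + 1]] <<- data.frame(
          gene_id = gid, chrom = chrom,
          start = p + c(0, 3000, 9500), end = p + c(500, 3500, 10000),
          strand = "+")
      }
      add_tx <- function(strand, exon_starts, exon_ends) {
        txs[[length(txs) + 1]] <<- data.frame(
          transcript_id = tid, chrom = chrom,
          start = min(exon_starts), end = max(exon_ends), strand = strand)
        texons[[length(texons) + 1]] <<- data.frame(
          transcript_id = tid, chrom = chrom,
          start = exon_starts, end = exon_ends, strand = strand)
      }

      good_fpkm <- function() runif(cfg$n_samples, 1.5, 20)
      low_fpkm <- function() {
        v <- runif(cfg$n_samples, 0.01, 0.8)
        hot <- sample(cfg$n_samples, min(3, cfg$n_samples))
        v[hot] <- runif(length(hot), 1.5, 20)
        v
      }
      noncoding_calls <- function() data.frame(
        transcript_id = tid, cpat_prob = runif(1, 0, 0.3),
        txcds_score = runif(1, 0, 700), cpc2_label = "noncoding",
        lncadeep_label = "noncoding", cnit_label = "noncoding")
      coding_calls <- function() data.frame(
        transcript_id = tid, cpat_prob = runif(1, 0.5, 0.95),
        txcds_score = runif(1, 900, 2000), cpc2_label = "coding",
        lncadeep_label = "coding", cnit_label = "coding")

      fp <- good_fpkm(); cc <- noncoding_calls()
      row <- switch(sc,
        clean_intergenic = {
          add_tx("+", p + c(0, 800), p + c(300, 1100))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "survivor", step = NA_integer_,
                     category = "intergenic")
        },
        clean_intronic = {
          host()
          add_tx("-", p + 4000, p + 4800)
          data.frame(transcript_id = tid, scenario = sc,
                     status = "survivor", step = NA_integer_,
                     category = "intronic")
        },
        clean_exonic_antisense = {
          host()
          add_tx("-", p + 2900, p + 3600)
          data.frame(transcript_id = tid, scenario = sc,
                     status = "survivor", step = NA_integer_,
                     category = "exonic")
        },
        clean_overlapping = {
          host()
          add_tx("-", p + c(8000, 10500), p + c(8500, 11000))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "survivor", step = NA_integer_,
                     category = "overlapping")
        },
        violation_blacklist = {
          iv <- data.frame(chrom = chrom, start = p + 200, end = p + 700,
                           strand = ".")
          n_lcr_used <- n_lcr_used + 1
          if (n_lcr_used %% 2 == 0) {
            lcr[[length(lcr) + 1]] <- iv
          } else {
            blacklist[[length(blacklist) + 1]] <- iv
          }
          add_tx("+", p + c(400, 1400), p + c(900, 1700))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 1L, category = NA_character_)
        },
        violation_short = {
          add_tx("+", p, p + 150)
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 2L, category = NA_character_)
        },
        violation_unstranded = {
          add_tx(".", p + c(0, 900), p + c(400, 1200))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 2L, category = NA_character_)
        },
        violation_low_expr = {
          fp <- low_fpkm()
          add_tx("+", p + c(0, 800), p + c(300, 1100))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 3L, category = NA_character_)
        },
        violation_proximal = {
          host()
          add_tx("+", p + 10500, p + 11300)
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 4L, category = NA_character_)
        },
        violation_exon_overlap = {
          host()
          add_tx("+", p + c(2900, 4000), p + c(3200, 4300))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 5L, category = NA_character_)
        },
        violation_coding = {
          cc <- coding_calls()
          add_tx("+", p + c(0, 800), p + c(300, 1100))
          data.frame(transcript_id = tid, scenario = sc,
                     status = "removed", step = 6L, category = NA_character_)
        },
        stop("unknown scenario ", sc)
      )
      truth[[i]] <- row
      fpkm[[i]] <- fp
      calls[[i]] <- cc
    }

    tx_df <- do.call(rbind, txs)
    ex_df <- do.call(rbind, texons)
    truth_df <- do.call(rbind, truth)
    if (is.null(tx_df)) {
      tx_df <- data.frame(transcript_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character())
      ex_df <- tx_df
      truth_df <- data.frame(transcript_id = character(),
                             scenario = character(), status = character(),
                             step = integer(), category = character())
    }
    fpkm_mat <- if (length(fpkm)) {
      m <- do.call(rbind, fpkm)
      rownames(m) <- tx_df$transcript_id
      colnames(m) <- sprintf("S%02d", seq_len(cfg$n_samples))
      m
    } else {
      matrix(numeric(), 0, cfg$n_samples,
             dimnames = list(NULL, sprintf("S%02d", seq_len(cfg$n_samples))))
    }
    gene_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character(),
                 biotype = character())
    gex_df <- if (length(gexons)) do.call(rbind, gexons) else
      data.frame(gene_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character())
    empty_iv <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), strand = character())
    calls_df <- if (length(calls)) do.call(rbind, calls) else
      data.frame(transcript_id = character(), cpat_prob = numeric(),
                 txcds_score = numeric(), cpc2_label = character(),
                 lncadeep_label = character(), cnit_label = character())

    list(
      annotation = gene_annotation(gene_df, gex_df),
      candidates = transcript_set(tx_df, ex_df, fpkm_mat),
      blacklist = if (length(blacklist)) do.call(rbind, blacklist) else empty_iv,
      low_complexity = if (length(lcr)) do.call(rbind, lcr) else empty_iv,
      coding_calls = calls_df,
      truth = truth_df
    )
  })
}
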