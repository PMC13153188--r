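test_that("the filter cascade removes the hand-built violations at the stated steps", {
  fx <- toy_cascade_fixture()
  rep <- apply_filter_cascade(fx$candidates, fx$annotation, fx$blacklist,
                              fx$low_complexity, fx$coding_calls)
  expect_equal(rep$survivors$transcript_id, "t1")
  expect_equal(rep$survivors$category, "intergenic")
  removed <- setNames(rep$removed$step, rep$removed$transcript_id)
  expect_equal(removed[c("t2", "t3", "t4", "t5", "t6")],
               c(t2 = 2L, t3 = 2L, t4 = 3L, t5 = 4L, t6 = 5L))
})

test_that("a transcript violating several steps is reported at the first", {
  fx <- toy_cascade_fixture()
  ## t_multi: shorter than 200 bp AND same-strand exon overlap -> step 2
  tx <- rbind(fx$candidates$transcripts,
              data.frame(transcript_id = "t_multi", chrom = "chr1",
                         start = 104100, end = 104250, strand = "+"))
  ex <- rbind(fx$candidates$exons,
              data.frame(transcript_id = "t_multi", chrom = "chr1",
                         start = 104100, end = 104250, strand = "+"))
  fpkm <- rbind(fx$candidates$fpkm,
                t_multi = rep(5, ncol(fx$candidates$fpkm)))
  cands <- transcript_set(tx, ex, fpkm)
  rep <- apply_filter_cascade(cands, fx$annotation, fx$blacklist,
                              fx$low_complexity, fx$coding_calls)
  expect_equal(rep$removed$step[rep$removed$transcript_id == "t_multi"], 2L)
})

test_that("the cascade conserves counts, is idempotent, and handles empty input", {
  fx <- toy_cascade_fixture()
  rep <- apply_filter_cascade(fx$candidates, fx$annotation, fx$blacklist,
                              fx$low_complexity, fx$coding_calls)
  expect_equal(sum(rep$steps$n_removed) + nrow(rep$survivors),
               nrow(fx$candidates$transcripts))

  surv <- subset_transcript_set(fx$candidates, rep$survivors$transcript_id)
  rep2 <- apply_filter_cascade(surv, fx$annotation, fx$blacklist,
                               fx$low_complexity, fx$coding_calls)
  expect_equal(nrow(rep2$removed), 0)
  expect_equal(rep2$survivors, rep$survivors)

  empty <- subset_transcript_set(fx$candidates, character(0))
  rep0 <- apply_filter_cascade(empty, fx$annotation, fx$blacklist,
                               fx$low_complexity, fx$coding_calls)
  expect_equal(sum(rep0$steps$n_removed), 0)
  expect_equal(nrow(rep0$survivors), 0)
})

test_that("a survivor of steps 1-5 without coding calls raises a named error", {
  fx <- toy_cascade_fixture()
  calls <- fx$coding_calls[fx$coding_calls$transcript_id != "t1", ]
  expect_error(
    apply_filter_cascade(fx$candidates, fx$annotation, fx$blacklist,
                         fx$low_complexity, calls),
    "t1")
})

test_that("consensus_noncoding requires unanimity at the published cutoffs", {
  base <- data.frame(cpat_prob = 0.1, txcds_score = 100,
                     cpc2_label = "noncoding", lncadeep_label = "noncoding",
                     cnit_label = "noncoding")
  expect_true(consensus_noncoding(base))
  expect_false(consensus_noncoding(transform(base, cpat_prob = 0.40)))
  expect_false(consensus_noncoding(transform(base, txcds_score = 805)))
  expect_false(consensus_noncoding(transform(base, cpc2_label = "coding")))
  ## boundary: cutoffs are strict
  expect_false(consensus_noncoding(transform(base, cpat_prob = 0.364)))
  expect_false(consensus_noncoding(transform(base, txcds_score = 800)))
  expect_error(consensus_noncoding(base[, -1]), "cpat_prob")
  expect_error(consensus_noncoding(transform(base, cpat_prob = NA)),
               "missing")
})

test_that("positional classification follows the exonic > intronic > overlapping > intergenic precedence", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 1000,
                     end = 11000, strand = "+", biotype = "protein_coding")
  gex <- data.frame(gene_id = "g", chrom = "chr1",
                    start = c(1000, 5000, 10000),
                    end = c(1500, 5500, 11000), strand = "+")
  ann <- gene_annotation(gene, gex)
  mk <- function(id, start, end, strand = "-") {
    transcript_set(
      data.frame(transcript_id = id, chrom = "chr1", start = start,
                 end = end, strand = strand),
      data.frame(transcript_id = id, chrom = "chr1", start = start,
                 end = end, strand = strand))
  }
  ## disjoint from the gene body
  expect_equal(unname(classify_position(mk("a", 50000, 51000), ann)),
               "intergenic")
  ## antisense, wholly inside the second intron, no exon contact
  expect_equal(unname(classify_position(mk("b", 6000, 9000), ann)),
               "intronic")
  ## overlaps a coding exon on the opposite strand
  expect_equal(unname(classify_position(mk("c", 5200, 6000), ann)),
               "exonic")
  ## overlaps the gene body but neither an exon nor within one intron:
  ## one exon in the last intron, one beyond the gene end
  d <- transcript_set(
    data.frame(transcript_id = "d", chrom = "chr1", start = 9000,
               end = 12000, strand = "-"),
    data.frame(transcript_id = "d", chrom = "chr1",
               start = c(9000, 11200), end = c(9800, 12000), strand = "-"))
  expect_equal(unname(classify_position(d, ann)), "overlapping")
})

test_that("classification is a partition on fuzzed generated inputs", {
  for (s in 1:5) {
    sim <- simulate_annotation(sim_config(seed = 100 + s))
    cats <- classify_position(sim$candidates, sim$annotation)
    expect_equal(length(cats), nrow(sim$candidates$transcripts))
    expect_true(all(cats %in% c("intergenic", "exonic", "intronic",
                                "overlapping")))
  }
})

test_that("survivors and categories match the generator truth across seeds", {
  for (s in 1:3) {
    sim <- simulate_annotation(sim_config(seed = 200 + s))
    rep <- apply_filter_cascade(sim$candidates, sim$annotation,
                                sim$blacklist, sim$low_complexity,
                                sim$coding_calls)
    truth <- sim$truth
    expect_setequal(rep$survivors$transcript_id,
                    truth$transcript_id[truth$status == "survivor"])
    m <- merge(rep$survivors, truth, by = "transcript_id")
    expect_equal(m$category.x, m$category.y)
    r <- merge(rep$removed, truth, by = "transcript_id")
    expect_equal(r$step.x, r$step.y)
  }
})
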