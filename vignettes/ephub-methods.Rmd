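---
title: "Methods: enhancer-promoter hub discovery with ephub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer-promoter hub discovery with ephub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephub)
```

`ephub` re-implements, as a reusable and tested pipeline, the computational
stages used to nominate a tumor-specific long non-coding RNA from patient
transcriptome assemblies and to characterize the enhancer-promoter (E-P)
regulatory network it acts on: candidate-lncRNA filtering and positional
classification, ROSE-style super-enhancer calling, weighted gene-peak
network construction with eigenvector-centrality hub scoring, a network
activity score with survival stratification, and aggregate peak analysis
(APA) of HiChIP contact matrices. The cohorts such analyses are normally run
on (dbGaP/TCGA-scale RNA-seq and ATAC-seq, commercial clinical panels) are
restricted; the package therefore ships a synthetic-data module that
generates every input with planted ground truth, and all claims made by the
test suite are claims about those synthetic conditions.

## Candidate lncRNA filtering

`apply_filter_cascade()` applies six filters in a fixed order, recording for
each removed transcript the *first* step it violates:

1. any overlap (>= 1 bp) with blacklist or low-complexity regions;
2. total exonic length < 200 bp, or missing strand;
3. expression below FPKM 1.0 in all but fewer than 5 samples;
4. single-exon transcripts within 2,000 bp (edge-to-edge, boundary
   inclusive) of a same-strand annotated gene -- likely fragments;
5. same-strand exonic overlap with exons of annotated genes of any biotype;
6. failure of the five-tool coding-potential consensus
   (`consensus_noncoding()`): CPAT probability < 0.364, txCdsPredict
   score < 800, and "noncoding" labels from CPC2, lncADeep and CNIT,
   all required.

Step 5 is deliberately strand-specific: antisense transcripts overlapping
coding exons must survive, because antisense exonic lncRNAs are a
recognized (and here, the motivating) class. All comparisons sit exactly on
the published cutoffs and are strict, so boundary values (CPAT = 0.364,
txCds = 800, FPKM just under 1.0) fail.

Survivors are classified against protein-coding gene bodies,
strand-agnostically, with precedence **exonic** (any exon-exon overlap) >
**intronic** (wholly inside one intron) > **overlapping** (gene-body overlap
otherwise) > **intergenic**. The precedence order makes the four labels a
partition; the widely used positional taxonomy it follows does not publish
exact tie-breaking rules, so the order here is a documented choice rather
than a guaranteed reproduction.

## Super-enhancer calling

`stitch_enhancers()` drops signal peaks overlapping any TSS ± 3 kb window
(whole-peak exclusion, no trimming), then merges peaks whose edge-to-edge
gap is <= 12.5 kb, tracking the running maximum end so nested peaks never
split a region. `call_superenhancers()` sorts stitched regions ascending by
total signal, min-max scales rank and signal to the unit square, and places
the cutoff at the first point (scanning ascending) whose centered-difference
slope exceeds 1 -- the tangent rule on the hockey-stick curve. Regions with
signal strictly above the cutoff signal are super-enhancers; a curve of
identical signals is degenerate and yields none, with a warning. Genes are
assigned to super-enhancers when their TSS lies within 50 kb of a region
boundary (`assign_se_genes()`).

Because the cutoff is a property of the scaled curve, appending a region
far above the previous maximum compresses everything else toward zero: the
newcomer is always flagged, and the flagged set among pre-existing regions
can only shrink. The tests assert exactly this monotonicity rather than any
stability of the old calls.

## Gene-peak regulatory network

`select_network_nodes()` takes differential-accessibility and
differential-expression tables from a perturbation contrast (e.g. lncRNA
knockdown). Peak nodes require FDR < 0.05, log2FC < -0.25 (strict), an
overlap with SMARCA4 ChIP-seq peaks, and an overlap with H3K27ac peaks (the
enhancer-retention step); gene nodes require FDR < 0.05 and log2FC < -0.25.
Gene node regions are promoter windows from 2,000 bp upstream to 200 bp
downstream of the TSS, oriented by strand. A correlation mode covers cohort
designs without a knockdown contrast (peaks by Pearson r > 0.5 at p < 0.05
against the regulator's expression; genes upregulated at p < 0.05).

`build_edges()` maps each loop record's anchors (ChIA-PET, HiChIP, curated
enhancer-gene links -- one source suffices) onto node regions by >= 1 bp
overlap and emits peak-gene and peak-peak edges for every cross-anchor
pair, deduplicated; gene-gene pairs are ignored. `assign_edge_weights()`
ranks each edge class separately -- peak-gene edges by the product of ATAC
and RNA log2FC (rank 1 = largest product) and by normalized peak height;
peak-peak edges by the product of both peaks' log2FC and by mean height --
with ties receiving average ranks. The rank product R1·R2 is min-max scaled
per class so the best edge gets weight 1 and the worst 0 (all-equal classes
get weight 1 throughout). Scaling is per class because the two classes'
criteria are stated separately; pooling them would let a dense class crowd
out the other's dynamic range.

`augment_head_node()` adds one artificial node connected to every other
node at weight 0.01, guaranteeing a connected graph (hence one dominant
eigenvector spanning all nodes) while perturbing rankings negligibly -- the
tests require Spearman rho >= 0.99 against the unaugmented graph.

`compute_eigencentrality()` returns the dominant eigenvector of the
symmetric weighted adjacency: node importance proportional to the weighted
sum of neighbours' importances, scaled by the dominant eigenvalue. Power
iteration starts from a uniform positive vector (no randomness anywhere in
the centrality path) and runs on a diagonally shifted matrix
(shift = 0.1 × max row sum). The shift matters: bipartite graphs -- the
star micro-example is one -- have paired extreme eigenvalues ±λ and
unshifted power iteration oscillates forever between the two eigenspaces.
Shifting preserves eigenvectors, strictly separates the top shifted
eigenvalue, and the reported λ is the Rayleigh quotient of the *unshifted*
matrix. Scores are normalized so the maximum over non-head nodes is 1,
matching the convention of normalized centrality displays; convergence is
declared when the unit eigenvector moves by less than `tol = 1e-10`
(sup-norm), with `converged = FALSE` (never an error) past `max_iter`.

`rank_hubs()` removes the head node, takes connected components of the
remainder as E-P subnetworks, ranks genes by centrality, and counts the
peak nodes in each gene's component -- the "enhancer count" of a hub.
`overlap_enrichment()` is the upper-tail hypergeometric test used for
peak-set overlap questions.

## Activity score and survival stratification

`network_activity_score()` z-scores each signature gene across samples
(sample standard deviation, n - 1 -- stated explicitly because the
convention is often left implicit), sums z-scores per sample, and
standardizes the sums to mean 0, SD 1. Signature genes missing from the
matrix are dropped with a warning: the score exists precisely because the
regulator itself is absent from hybrid-capture panels, so partial overlap
is the expected case. `pathway_activity_wmean()` computes
sum(w·z) / sum(|w|) per sample; unit weights are the default since
published pathway weightings are method-specific and user-supplied here.

`logrank_test()` implements the standard two-group log-rank from the
observed/expected/variance sums at each distinct event time;
`maxstat_cutpoint()` scans every observed score value whose low/high split
keeps both groups within `minprop = 0.1` of the cohort (the de facto
default of maximally-selected-rank-statistic cutpoint tools), evaluates the
standardized statistic |z| at each, and returns the maximizing cutpoint,
ties toward the smaller value. The p-value reported at the selected
cutpoint is anticonservative by construction -- the maximum over many
candidate splits is not chi-square(1) -- which is why model-based
regression p-values (out of scope here, available off the shelf in
`survival::coxph` with penalized splines) should accompany Kaplan-Meier
displays; the print method says so on every result.

## Aggregate peak analysis

`normalize_vc_sqrt()` divides each contact by the square root of the
product of its row and column sums (vanilla coverage, square-rooted);
zero-sum rows stay zero, and the transform is invariant to rescaling the
whole matrix. `observed_over_expected()` divides by the per-distance mean
of the matrix -- the mean, not sum, estimator, which is the documented
choice where tool conventions differ. `aggregate_contacts()` filters loops
to anchor-midpoint distances in [50 kb, 1 Mb], extracts the 31 × 31 window
(for `n_bins = 30`) centered on each anchor-pair bin of the transformed
matrix (VC-sqrt first, then obs/exp, then windowing), skips and counts
windows crossing the matrix boundary, and averages element-wise. Rows of a
window follow the upstream anchor top-to-bottom, so the *bottom-left* 3 × 3
corner (last rows, first columns) sits nearest the diagonal -- the
short-distance background. `apa_score()` is the center pixel over that
corner mean; `mean_aggregate()` averages replicates element-wise before
scoring. Anchors map to bins by midpoint.

## The synthetic data module

Every generator draws from an RNG stream derived from `(seed,
operation-name)`, so outputs are byte-identical across runs and adding one
generator never shifts another's draws. Defaults are chosen once as the
reference conditions of the whole test suite:

* **Annotation** (`simulate_annotation()`): each candidate transcript
  occupies a private 50 kb block, with a 10 kb three-exon host gene where
  the scenario needs one. Clean scenarios survive the cascade with a known
  category (the intronic and exonic survivors are antisense, mirroring the
  biology that motivates the strand-specific step 5); violation scenarios
  are built to trip exactly one step. Expression for clean candidates is
  drawn well above FPKM 1.0 in every sample, low-expression violations are
  high in only 3 samples.
* **Network** (`simulate_network_inputs()`): a hub gene wired through loop
  evidence to `hub_k = 19` qualifying enhancer peaks -- the size of the
  E-P subnetwork the method is designed to recover -- among decoy genes
  with degree <= 3 and non-qualifying peaks each failing exactly one
  selection criterion. Selected features draw log2FC from a truncated
  normal (mean -0.8, sd 0.2, truncated below -0.25) and FDR uniform on
  (0, 0.04), so threshold decisions are never marginal; the published
  thresholds act on crisp inputs.
* **Contacts** (`simulate_contacts()`): background
  `expected(d) = base / (1 + d / d0)` with `d0 = 250` kb at 5 kb bins over
  400 bins -- monotone distance decay, which is all the obs/exp transform
  requires of it; planted loop pixels are multiplied by `f >= 1`; Poisson
  resampling per replicate when noise is on. `base_count = 500` keeps
  corner pixels at >= 100 expected counts so the corner mean is stable.
* **Cohort** (`simulate_cohort()`): latent activity a ~ N(0,1); signature
  genes a + N(0, 0.5); survival exponential with hazard
  `0.001 · exp(beta · a)` per day (median ~700 days at a = 0, of the order
  of clinical mCRPC follow-up), `beta = ln 3` by default; censoring is an
  independent Bernoulli(0.2) flag with the censoring time uniform on
  (0, T), a simple independent-censoring mechanism.

What the generators do *not* emulate: read-level noise, mappability and GC
structure, correlated fragments in FPKM estimates, LD/copy-number
structure, cohort covariates, or informative censoring. Tests passing on
these inputs show the *algorithms* are implemented correctly and recover
planted structure under controlled noise -- not that any particular
biological discovery would replicate.

## Numerical choices and problem sizes

Power iteration: tolerance 1e-10, uniform start, diagonal shift as above;
agreement with a dense eigen-decomposition is required to 1e-8 on graphs up
to 50 nodes. Rank ties: average ranks. Degenerate inputs: all-equal
stitched signals yield no super-enhancers (warning); all-equal rank
products yield all-1 weights; zero-variance signature genes are dropped
(error only when none remain); empty graphs and empty loop sets are errors
where a result would be meaningless. The test-suite problem sizes -- 100
random graphs, 100 planted-hub networks, 10 × 1000-transcript annotation
sets, 50 planted elbow curves, 20 contact simulations per enrichment level,
100 cohorts of 200 patients -- were chosen so the full suite and the
acceptance script each complete in a few minutes on one CPU while keeping
Monte-Carlo error well below the asserted margins.

## Known limitations

The positional-classification precedence is a faithful but not
certified-identical reconstruction of the cited taxonomy. The
super-enhancer caller assumes plain signal (no input subtraction); an
input-subtracted variant is a matter of subtracting before calling. The
cutpoint p-value is intentionally uncorrected (see above). The CRPC-style
correlation mode selects nodes but reuses the knockdown weighting columns;
cohorts whose statistics live in different columns should be mapped onto
the expected names. Binary `.hic`/`.cool` formats are out of scope --
matrices enter as bin-table plus triplet text, to which those formats are
externally convertible.
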