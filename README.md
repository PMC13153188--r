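# ephub

Enhancer–promoter regulatory hub networks from chromatin and expression
data.

## What problem this solves

Tumor-specific long non-coding RNAs are routinely discovered from patient
transcriptome assemblies, linked to super-enhancers, and shown to act in
*trans* on distant oncogene loci through enhancer–promoter (E-P) looping.
The computational backbone of such a study is a chain of bespoke analyses
that rarely ships as reusable code: a candidate-lncRNA filter cascade, a
ROSE-parameterized super-enhancer caller, a weighted gene–peak network with
eigenvector-centrality hub scoring, a panel-friendly network activity score
with optimal-cutpoint survival stratification, and aggregate peak analysis
(APA) of HiChIP contact maps. `ephub` implements that chain as tested R
functions for regulatory genomicists, plus a synthetic-data module that
generates every input with planted ground truth, so the whole pipeline is
verifiable without access to restricted cohorts.

## The core model

Nodes of the regulatory network are differential ATAC-seq peaks
(FDR < 0.05, log2FC < −0.25, overlapping both SMARCA4 and H3K27ac peaks)
and downregulated gene promoters ([TSS − 2000, TSS + 200], oriented by
strand). Loop evidence (ChIA-PET / HiChIP / curated E-P links) contributes
peak–gene and peak–peak edges, weighted by min–max-scaled rank products of
differential and accessibility statistics. After adding a weakly connected
"head node" (weight 0.01 to every node) the influence of node *n* is its
weighted eigenvector centrality

    C_n = (1/λ) Σ_{i∈N(n)} a_{n,i} C_i ,

the dominant eigenvector of the weighted adjacency *a*, computed by
deterministic power iteration and normalized so the top non-head node
scores 1. Genes are ranked by C_n; connected components after removing the
head node are the E-P subnetworks, and a gene's "enhancer count" is the
number of peak nodes in its component.

Downstream, a gene signature's activity in a cohort sample is the
standardized sum of per-gene z-scores (`network_activity_score`), survival
strata come from maximally selected rank statistics
(`maxstat_cutpoint` + `logrank_test`), and looping strength is quantified
as the APA corner ratio — center pixel over the bottom-left 3×3 mean of the
31×31 observed/expected aggregate around loop anchors after VC-sqrt
normalization (`aggregate_contacts` + `apa_score`).

## Worked example

Recover a planted 19-enhancer hub from synthetic knockdown tables and loop
evidence:

```r
library(ephub)

sim   <- simulate_network_inputs(sim_config(seed = 1))
nodes <- select_network_nodes(sim$peaks, sim$genes)
g     <- assign_edge_weights(build_edges(nodes, sim$loops),
                             sim$peaks, sim$genes)
ga    <- augment_head_node(g)
hubs  <- rank_hubs(ga, compute_eigencentrality(ga))
print(hubs)
#> hub report: 6 genes across 6 subnetworks; top genes:
#>   gene_id        score component n_enhancers
#> 1    G008 1.000000e+00         1          19
#> 2    G004 1.241341e-04         3           3
#> 3    G005 9.602744e-05         2           2
#> 4    G003 7.548232e-05         6           1
#> 5    G012 7.382714e-05         4           1
sim$truth$hub_gene_id
#> [1] "G008"
```

The planted hub tops the gene ranking with its 19 enhancer nodes; decoy
genes (degree ≤ 3) trail by four orders of magnitude. Stratifying a
simulated 200-patient cohort by the network activity score:

```r
co <- simulate_cohort(sim_config(seed = 1))
sc <- network_activity_score(co$expr, co$signature)
print(maxstat_cutpoint(sc, co$survival))
#> maxstat cutpoint: -0.0818 | standardized log-rank 9.33 | groups: 87 low / 113 high
#>   log-rank at cutpoint: chi-sq = 87.06 , p = 1.06e-20 (anticonservative for the selected split)
```

And scoring planted loop enrichment (factor 3, Poisson noise, two
replicates averaged):

```r
cfg   <- sim_config(seed = 1, contact = list(enrichment_factor = 3))
loops <- simulate_contact_loops(cfg)
aggs  <- lapply(simulate_contacts(cfg, loops), aggregate_contacts,
                loops = loops)
apa_score(mean_aggregate(aggs))
#> [1] 2.992
```

A thin command-line wrapper over the same functions lives at
`inst/cli/ephub.R` (subcommands `simulate`, `lncfilter`, `se-call`,
`network`, `score`, `survival`, `apa`).

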