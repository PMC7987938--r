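# cistransnet

Tools for asking a simple structural question of a gene co-expression
network (GCN): how much co-expression stays **within** chromosomes (*cis-*)
versus crossing **between** them (*trans-*), and how that balance differs
between phenotypes — the signature of interest being tumor transcriptomes
whose co-expression collapses into small, chromosome-local (often
single-cytoband) neighborhoods while normal tissue keeps a large
chromosome-spanning component.

The package is aimed at computational biologists working with bulk RNA-seq
count matrices plus a BioMart-style gene annotation (chromosome, start/end,
GC fraction, biotype, cytoband). It provides:

- **Preprocessing** — mean-CPM filtering, full-quantile correction within
  GC and gene-length bins, trimmed-mean-of-M (TMM) scaling, `log2(x+1)`.
- **MI network inference** — a deterministic plug-in mutual-information
  estimator on equal-frequency bins,

  `MI(x, y) = Σ_ij p(i,j) ln [ p(i,j) / (p(i) p(j)) ]`  (nats),

  with `b = ⌊√n⌋` bins by default, all-pairs computation, top-*k* pruning,
  a permutation-calibrated MI significance threshold, and optional
  data-processing-inequality (DPI) triangle pruning.
- **Genomic edge classification** — every edge becomes *trans*,
  *cis-inter-arm*, *cis-intra-arm-inter-band*, or *cis-intra-band*, with
  genomic distances, per-chromosome cis fractions, top-*k* cutoff sweeps,
  Fisher/Wilcoxon phenotype comparisons, and a degree-preserving rewiring
  test for intra-cytoband enrichment.
- **Network comparison** — edge-set intersections with shared percentages
  and fold ratios, connected components and giant-component fractions,
  and a subsampling robustness procedure.
- **Differential expression** — a two-group moderated *t* with
  empirical-Bayes variance shrinkage, BH adjustment, DEG calls at
  |log2FC| ≥ 1.5 and adjusted p < 0.01, and classification of edges by
  expression-trend concordance.
- **A synthetic cohort generator** — negative-binomial counts through a
  Gaussian copula with planted within-cytoband / distance-decaying
  (cis-dominant) or cross-chromosome module (trans-dominant) correlation,
  planted fold changes, and a full ground-truth record, so the whole
  pipeline can be validated end to end.

## Worked example

```r
library(cistransnet)

cfg <- synthetic_config(seed = 11)   # 200 genes, 5 chromosomes, 100 samples
lay <- build_genome(cfg)
ann <- lay$genes

cohort <- function(structure) {
  counts <- simulate_counts(lay, cfg, "baseline", structure)
  norm <- preprocess_counts(counts, ann)
  pairwise_mi(norm$matrix)
}

mi_cis   <- cohort("cis_dominant")     # tumor-like regime
mi_trans <- cohort("trans_dominant")   # normal-like regime

net_cis   <- top_k_edges(mi_cis, 1000)
net_trans <- top_k_edges(mi_trans, 1000)

cis_fraction(classify_edges(net_cis, ann))$cis_fraction
#> [1] 0.974
cis_fraction(classify_edges(net_trans, ann))$cis_fraction
#> [1] 0.186
```

With strong within-cytoband correlation planted (`rho_band = 0.9`), 97.4%
of the tumor-like network's strongest 1,000 edges join genes on the same
chromosome; the normal-like cohort, whose correlation lives in
chromosome-spanning modules, yields 18.6% — close to the 19.6% expected if
edges ignored chromosomes entirely. The category census makes the contrast
concrete — the cis-dominant network is almost entirely intra-cytoband:

```r
cis_fraction(classify_edges(net_cis, ann))$totals
#>   trans  cis-inter-arm  cis-intra-arm-inter-band  cis-intra-band
#>      26              4                         9             961
cis_fraction(classify_edges(net_trans, ann))$totals
#>   trans  cis-inter-arm  cis-intra-arm-inter-band  cis-intra-band
#>     814             26                        20             140

cytoband_proximity_test(net_cis, ann, n_rewire = 999, seed = 11)[c("p_value", "enrichment")]
#> $p_value
#> [1] 0.001
#> $enrichment
#> [1] 2.896281
```

The proximity test shows 2.9-fold more intra-cytoband edges than
degree-preserving rewiring within chromosomes would produce (empirical
p = 0.001, the floor for 999 rewirings).

`run_pipeline(pipeline_config(...))` chains every stage (simulation or
file input, preprocessing, network inference, classification, comparison,
differential expression, trend classification) and writes all artifacts
plus a `summary.tsv` of headline statistics;
`inst/scripts/cistransnet.R` exposes the same stages as shell
subcommands.

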