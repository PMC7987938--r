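---
title: "Cis/trans co-expression analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis/trans co-expression analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistransnet)
```

## The question and the approach

In several tumor transcriptomes, gene co-expression reorganizes along the
genome: instead of a single chromosome-spanning ("giant") co-expression
component, the strongest correlations concentrate between genes on the
same chromosome, frequently inside the same cytoband. `cistransnet`
operationalizes that observation as a measurable pipeline: infer a gene
co-expression network (GCN) from counts with a mutual-information (MI)
estimator, keep the top-*k* edges, classify every edge by genomic relation,
and quantify the cis/trans balance — overall, per chromosome, across
cutoffs, between phenotypes, and under subsampling.

Because the interesting quantity is a *property of the network's edge
ranking*, most design choices below aim at determinism and testability:
every stochastic step takes an explicit seed, and every estimator has an
independently checkable definition.

## Mutual-information estimation

The estimator is the plug-in MI on equal-frequency bins. Each gene's
profile across $n$ samples is discretized into $b$ bins of near-equal
occupancy — ties broken by stable rank (original sample order), so bin
occupancies depend only on $n$ and $b$ — and

$$\widehat{MI}(x,y) = \sum_{i,j} \hat p(i,j)\,
  \ln\frac{\hat p(i,j)}{\hat p(i)\,\hat p(j)} \quad \text{(nats)},$$

with $0\ln 0 := 0$. Defaults: $b = \lfloor\sqrt{n}\rfloor$ (at least 2),
requiring $n \ge 2b$. The choice over kernel estimators is deliberate: the
plug-in on fixed bins is deterministic, exactly reproducible across
chunked computation, rank-based (hence invariant to the monotone
normalization steps that precede it), and verifiable cell-by-cell against
brute-force summation — the test suite holds it to $10^{-12}$ absolute
agreement with an independent oracle on hundreds of random instances.

Numerical details that matter: cell terms are evaluated in the single-log
product form $\frac{c_{ij}}{n}\ln\frac{c_{ij}\,n}{c_{i\cdot}c_{\cdot j}}$
and summed in sorted order, which makes $\widehat{MI}(x,y)$ bitwise equal
to $\widehat{MI}(y,x)$; the value is clamped at 0 (the plug-in is
non-negative in exact arithmetic); a constant profile returns 0 with a
warning rather than letting tie-spreading manufacture dependence.

The estimator is biased upward under independence (approximately
$(b-1)^2/2n$ nats), which is harmless here: the analysis consumes the edge
*ranking*, and the permutation calibration measures the null including its
bias. Top-*k* pruning breaks ties at the cut lexicographically by gene
pair, so networks are unique. DPI triangle pruning is available but off by
default, since a top-*k* ranked network, not a parsimonious topology, is
the analysis object.

### Permutation calibration

`permutation_threshold()` builds a null by permuting the sample labels of
one member of randomly drawn gene pairs. P-values at or above 1/(pool
size) are read from the empirical quantile; more extreme thresholds are
extrapolated with an exponential fit to the tail above the 95th
percentile (rate = reciprocal mean exceedance). The exponential tail is a
pragmatic model for the extreme tail this family of analyses uses (e.g.
$p < 10^{-8}$ at genome scale), where no feasible permutation pool reaches
empirically; the suite checks its type-I calibration at $p = 0.01$ on
independent data, within three binomial standard errors.

## Preprocessing

The order is fixed: mean-CPM filter on raw counts → GC full-quantile
correction → gene-length full-quantile correction → TMM scaling →
$\log_2(x+1)$. Choices worth stating:

- **"CPM < 10 removed"** is read as *mean* CPM across samples, inclusive
  at the boundary (mean CPM exactly 10 is kept). A per-sample reading
  would make retention depend on cohort size in a way a single threshold
  cannot express.
- **Covariate full-quantile correction** splits genes into
  equal-frequency covariate bins (quantile breaks collapsed over ties, so
  equal covariate values never straddle bins) and, within each sample,
  maps every bin onto the cross-bin mean quantile profile. Its output
  resolution equals bin occupancy — each value becomes a reference
  quantile at its within-bin rank — so the pipeline caps the effective
  bin count to keep at least 100 genes per bin. On a 20,000-gene matrix
  the 10-bin default is untouched; on a 200-gene synthetic panel two bins
  are used. Without the cap, a small panel would leave each gene with as
  few as 20 distinct values, and downstream MI discretization of such
  heavily tied profiles degrades the network ranking badly.
- **TMM factors** are defined on the raw values: M- and A-values against
  a reference sample on genes nonzero in both, 30% two-sided trim on M,
  5% on A, factor $2^{\text{weighted mean }M}$ with delta-method inverse
  binomial-variance weights, rescaled to geometric mean 1. Defining M on
  raw rather than depth-scaled values folds sequencing depth into the
  factor, so dividing by the factor normalizes depth and composition in
  one step; the doubled-library identity (sample B = 2×A gives factors
  $(1/\sqrt2, \sqrt2)$) is the hand-computable anchor the tests pin.
- One coherent normalization path is implemented; combining several
  normalization families (NOISeq-style corrections *and* a DESeq2-style
  size-factor pass) without a stated order is ambiguous, and batch
  correction (ARSyN-style) is out of scope — the synthetic cohorts have
  no batch structure.

## Edge classification and statistics

A gene belongs to the cytoband containing its **start** position;
genomic distance between same-chromosome genes is the absolute difference
of starts. Edges fall into four mutually exclusive, exhaustive classes:
trans, cis-inter-arm, cis-intra-arm-inter-band, cis-intra-band. The
cutoff sweep classifies the full MI stream once and reads prefix cis
fractions, so smaller cutoffs are nested subsets of larger ones by
construction.

The original analyses report extreme p-values for the tumor/normal
cis-trans difference and for intra-cytoband concentration without naming
their tests; rather than guess, this package fixes its own and reports
both: a pooled Fisher exact test on the (cis, trans) × network table plus
a paired per-chromosome Wilcoxon signed-rank (needing ≥ 6 chromosomes;
mitochondrial and scaffold entries are excluded from the paired test but
kept in totals), and, for cytoband proximity, a permutation test whose
null rewires each chromosome's cis subgraph degree-preservingly
(`igraph::keeping_degseq`), with empirical p
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{rewire}})$. The
rewiring is constrained within chromosomes so the test asks specifically
whether *band-level* concentration exceeds what chromosome-level edge
placement already implies. Published p-values are treated as qualitative
anchors, not reproduction targets.

## Differential expression

A two-group moderated *t* on log2 normalized expression: per-gene pooled
variance $s^2$ with $d$ degrees of freedom is shrunk to
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, the prior $(d_0, s_0^2)$
estimated by method of moments on $\log s^2$ using the moments of
$\log F(d, d_0)$ (trigamma inversion by Newton iteration; an excess
variance ≤ 0 yields $d_0 = \infty$, i.e. complete shrinkage). The
statistic is referred to $t_{d_0+d}$. This follows the standard
empirical-Bayes construction; matching any specific implementation's
numerics is explicitly *not* a goal — the suite instead pins calibration
(null type-I error 0.05 ± 0.02 on 2,000 null genes) and checks agreement
of the p-value ordering with limma as an independent cross-check. DEG
calls use |log2FC| ≥ 1.5 (inclusive) and BH-adjusted p < 0.01 (strict),
matching the usual reading of "threshold at ±1.5" and "p < 0.01".

Edge trend concordance defaults to sign mode (classes by the sign of the
fold change, zero giving involves-ns) because published trend-colored
network figures color edges whose genes may be individually
sub-threshold; a significant-only mode is exposed since the two slices
answer different questions, and the published black/green edge totals do
not say which slice they count.

## The synthetic generator

`simulate_counts()` is the package's study system, not a fixture. Latent
per-gene Gaussians are drawn with one of two correlation structures:

- **cis_dominant** — $\rho_{\text{band}}$ between genes sharing a
  cytoband and $\rho_{\text{band}} e^{-d/\lambda}$ between genes on the
  same chromosome at start-distance $d$ ($\lambda$ = `decay_length`);
- **trans_dominant** — $\rho_{\text{trans}}$ inside gene modules dealt
  across chromosomes in interleaved order (so every module spans several
  chromosomes), plus a weak global factor (0.02) standing in for
  cohort-wide covariation.

Covariance blocks are repaired to the nearest PSD matrix by eigenvalue
clipping when needed. Latent values map through a Gaussian copula to
negative-binomial counts with per-sample library sizes drawn uniformly
from `libsize_range`; the copula is rank-preserving, so planted
correlation survives the monotone normalization steps. Under
`condition = "altered"`, a fraction `frac_de` of genes carries planted
$\log_2$ fold changes $\sim N(0, \text{lfc\_sd}^2)$ applied to the NB
means. `planted_truth()` records DE genes with signs, module memberships,
and both expected correlation matrices, enabling recovery scoring.

Defaults are the package's fixed study conditions: 200 genes on 5
chromosomes (2 cytobands per arm, 100 Mb chromosomes), 100 samples per
condition, $\rho_{\text{band}} = 0.9$, $\lambda = 10$ Mb (so adjacent
genes at the ~2.5 Mb mean spacing retain most of the band correlation
while opposite chromosome ends are effectively uncorrelated),
$\rho_{\text{trans}} = 0.7$ in four modules of 30/30/20/20 genes,
`frac_de` = 0.1 with `lfc_sd` = 2, NB dispersion 0.15 (typical bulk
RNA-seq), library sizes 5–20 million. The subsampling-robustness analysis
draws 100-column subsamples from a 200-sample cis-dominant cohort so the
draw is non-degenerate while staying desk-scale.

What the generator does *not* emulate: real chromosome lengths and gene
density, GC- or length-dependent expression bias (GC is independent of
expression, so the quantile corrections are exercised as no-ops plus
noise), batch effects, outlier samples, and the 20,000-gene scale. Tests
passing on this system therefore demonstrate that the pipeline recovers
planted genomic covariance structure through realistic count noise and
normalization — not that any particular biological dataset will show the
tumor signature.

## Problem sizes and determinism

The validation suite runs the full pipeline at 200 genes × 100 samples
(19,900 gene pairs), sweeps cutoffs 1,000–10,000, uses 10 × 100-column
subsamples, 5,000-pair permutation nulls, 999 rewirings (99 in the
smallest calibration loops), and 2,000-gene null DE matrices. At these
sizes the complete suite and the acceptance script each run in well under
a minute. All-pairs MI is computed via per-bin indicator cross-products
(BLAS), identical to the scalar estimator within $10^{-12}$; the scalar
path is the reference definition. Every result is reproducible from a
single master seed; child seeds for replicates are drawn once from the
master stream.

## Known limitations

- The plug-in MI bias grows as $b^2/n$; with the $\lfloor\sqrt n\rfloor$
  default this is appreciable for $n \lesssim 50$ and rankings, not MI
  magnitudes, should be interpreted.
- The exponential tail extrapolation of the permutation null is a model;
  far-tail thresholds (many orders beyond the pool) inherit its error.
- The moderated-*t* assumes roughly normal log-expression within groups;
  counts with many zeros surviving the CPM filter would violate it.
- Percent-shared-edge denominators use each network's own edge count
  (they coincide in the fixed top-*k* design); union-based percentages
  would be smaller.
- SIF export is write-only, since the format carries no weights and the
  network container requires weight-consistent ranks.
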