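---
title: "Methods: PPI-constrained co-expression networks, module mining and consensus classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPI-constrained co-expression networks, module mining and consensus classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsnet)
```

## The analysis

`gbsnet` implements an integrative network analysis for small two-group
expression cohorts — the motivating setting is an autoimmune neuropathy
(Guillain–Barré syndrome) profiled in 7 patients and 7 controls — in which
the question is how disease-associated genes relate to immune genes at the
level of co-expression structure. The pipeline has five stages:

1. **Network construction.** Pearson correlation is computed for every
   gene pair; pairs with \(|r| > 0.3\) and Benjamini–Hochberg
   \(q < 0.05\) (one family over all tested pairs) form a co-expression
   network, which is then restricted to pairs also present in a
   protein–protein-interaction (PPI) edge list. The node set is
   edge-induced. Scale-freeness is assessed by an ordinary least-squares
   fit of \(\log_{10}(\text{count})\) on \(\log_{10}(\text{degree})\).
2. **Category analysis.** Network genes are partitioned into
   disease-and-immune, disease-only, immune-only and other, by membership
   in two annotation sets; the overlapping views (all disease, all
   immune) are unions of these. Degree and incident-edge \(|r|\)
   distributions are compared across categories with two-sided Wilcoxon
   rank-sum tests, and first-neighbour subnetworks are extracted around
   the disease genes.
3. **Module mining.** Dense clusters are mined by greedy modularity
   community detection on the \(|r|\)-weighted network, split into
   connected components where needed, filtered at a minimum size and
   ranked by internal edge density.
4. **Consensus classification.** For each module, samples are clustered
   by Monti-style resampling consensus clustering of the module's
   expression submatrix; the number of clusters is chosen by the relative
   change in the area under the consensus-index CDF; the resulting labels
   are tested against the true case/control status by an uncorrected
   Pearson chi-squared test.
5. **Expression statistics.** Per-module pairwise co-expression
   fractions, per-gene Welch t-tests (unadjusted \(p < 0.05\) calls
   DE genes), hypergeometric enrichment of DE genes in module genes, and
   over-representation analysis (ORA) of module genes against a gene-set
   collection with BH adjustment.

## Statistical details and conventions

**Correlation p-values** use the t transform
\(t = r\sqrt{(n-2)/(1-r^2)}\) with \(n-2\) degrees of freedom. A
numerically perfect correlation is assigned the smallest representable
positive p rather than zero, so it survives any FDR threshold without
producing a zero that breaks downstream logs. Constant genes cannot be
tested and are excluded from the pair family with a message.

**FDR family.** BH is applied once over all tested pairs, and the
\(|r|\) and \(q\) conditions are applied jointly afterwards. Genes are
sorted lexicographically before pairing, so results are invariant to
input row/column order and bit-reproducible.

**Wilcoxon rank-sum** uses exhaustive enumeration of rank assignments
(two-sided p = doubled smaller tail, capped at 1) whenever the combined
sample size is at most 12 and there are no ties; otherwise a normal
approximation with tie correction and no continuity correction. A fully
tied input is degenerate and returns p = 1 with a warning.

**Consensus clustering.** Each of the `n_resamples` draws takes
\(\lceil 0.8\,n \rceil\) samples without replacement; the base clusterer
is average-linkage hierarchical clustering on Euclidean sample distances
(k-means available). The consensus index conditions on co-sampling;
never-co-sampled pairs (vanishingly rare at the default 1000 resamples)
get consensus 0 with a logged count. The area under the consensus CDF is
the exact integral of the right-continuous empirical CDF over \([0,1]\)
(equivalently \(\sum_i (1-v_i)/m\)); this convention gives AUC 0 for a
perfectly consensual matrix (all ones) and 1 for all zeros, which a naive
trapezoid over the jump points would not. k is selected as the smallest k
whose next step adds less than 10% relative area; if every step stays
large, the largest k is returned with a warning — on 14 samples this
fallback is common and is itself informative (no stable structure at
small k).

**Hypergeometric tests** are one-sided upper tails (over-representation).
The enrichment background defaults to the genes of the analysed network —
a conservative, self-contained universe. A consequence worth knowing:
when the query covers most of that small universe (e.g. pooled module
genes against a 45-gene network), ORA is near-powerless by construction;
per-module queries are the informative ones. The DE threshold is an
unadjusted per-gene \(p < 0.05\) — a deliberately liberal convention that
matches how such module-level DE summaries are usually reported;
module-level conclusions rest on the subsequent hypergeometric test, not
on individual DE calls.

**Chi-squared** is the uncorrected Pearson statistic; with 14 samples
every expected count is below 5 and a warning says so. This is the
standard choice for validating a clustering against known classes, but
p-values on such small tables are approximate.

**Module mining** replaces a discontinued web service whose algorithm was
never published; greedy modularity maximisation on \(|r|\) weights is a
reproducible, widely used stand-in with the same outcome shape (a handful
of dense, hub-centred clusters). igraph's implementation is
deterministic, so runs are bit-reproducible for a fixed input.

## The synthetic-data generator

Real inputs for this design (GEO expression series, HPRD-style PPI,
curated immune/disease gene lists) depend on database versions that
cannot be pinned, so the package ships a generator that emulates their
statistical structure:

* **Expression.** `n_genes` × 14 (7 cases, 7 controls). Module genes
  follow a shared-latent-factor model
  \(x_g = \sqrt{\rho}\, f_m + \sqrt{1-\rho}\,\varepsilon\) with
  \(\rho\) = `within_module_r`, so the expected pairwise within-module
  correlation is exactly \(\rho\) and the marginal SD is 1. Disease
  modules add `disease_effect` (in SD units) to case samples of every
  member gene. Background genes are independent N(0, 1).
* **PPI.** A Barabási–Albert preferential-attachment graph over all
  genes (heavy-tailed degrees), with gene ids assigned to vertices at
  random, plus a controlled fraction of each planted module's pairs.
* **Annotation.** The disease set contains all disease-module genes plus
  random fill; the immune set contains a controlled fraction of the
  disease set (default 0.7, matching the large observed overlap between
  disease and immune gene lists in this setting), the non-disease planted
  modules, and random fill to 15% of genes.
* **Pathways.** The planted modules as named sets plus random decoys, so
  ORA has known positives.

Defaults: 1000 genes, 5 modules of 10 genes, \(\rho = 0.8\), disease
effect 2, one disease module, 2 preferential-attachment edges per node,
80% of module pairs wired into the PPI. These mirror the scale of the
motivating study (a handful of coherent modules of modest size in a
sparse network); the 7v7 design is its defining constraint. What the
generator does *not* emulate: probe-level noise, batch effects,
heteroskedastic microarray variance, identifier mapping artefacts — so a
green test suite certifies the statistics and the plumbing, not
robustness to real microarray pathology.

## Design choices made where the design was open

* **Disease effect at module level.** All genes of a disease module shift
  together, mirroring the empirical observation that co-expression
  modules tend to be coherently up- or down-regulated in disease.
* **A structural consequence worth stating plainly:** because all module
  genes load equally on the shared factor, a uniform case shift lies
  *parallel* to the factor direction, and the achievable case/control
  separation of a module is
  \(d = \text{effect}/\sqrt{\rho + (1-\rho)/m}\) — about 2.1 SD in one
  dimension at \(\rho = 0.9\), *independent of module size*. A 1-D
  two-group clustering at \(d \approx 2.1\) misplaces two samples of 14
  on average, so the chi-squared validation of a single disease module is
  significant in roughly three quarters of simulated cohorts, not
  near-always. This is a property of any generative model with a high
  within-module correlation target, not of the implementation; the test
  suite documents it. (Only lowering the correlation target or raising
  the effect would change it, and both are study conditions, not tuning
  knobs.)
* **Neighbour subnetworks keep induced edges** (neighbour–neighbour
  connections), since those connections are the point of inspecting the
  neighbourhood; a seed-incident-only mode exists.
* **An edge joining two categories contributes its \(|r|\) to both
  categories' CDFs** — the consistent reading when categories are
  compared pairwise.
* **Per-stage seeds** are derived from the single pipeline seed by fixed
  offsets, so any stage rerun in isolation reproduces the full run.

## Problem sizes used by the tests

The suite exercises the pipeline at sizes chosen to make the statistics
sharp while keeping runs interactive: null-calibration at 200 genes × 14
samples × 20 replicates (FDR) and 2000 genes × 5 replicates (t-test);
planted-module recovery at 300 genes, 5 modules × 10 genes, 10 seeds;
consensus recovery at 100 genes × 14 samples × 200 resamples, 10 seeds;
the end-to-end run at the full 1000-gene default, 10 seeds. The
`analysis/` scripts run the same defaults once, end to end.

## Known limitations

* The power-law fit regresses binned log-frequencies — the conventional
  check in this literature, not a rigorous tail estimator; with two
  distinct degrees it is trivially perfect (documented caveat).
* Consensus clustering of 14 samples is at the small end of what the
  method is designed for; the k-selection fallback (largest k, with a
  warning) is common at this size.
* No probe-to-gene collapsing, identifier mapping or missing-value
  handling: readers reject such input rather than guessing.
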