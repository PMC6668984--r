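# gbsnet

Integrative co-expression network analysis for small two-group expression
cohorts, motivated by immune-mediated disease (the design it targets is a
7-patient vs 7-control Guillain–Barré syndrome microarray study). The
package answers a systems-level question: how do disease-associated genes
sit among immune genes in the co-expression structure, and do the dense
modules of that structure carry disease signal?

The pipeline, every step of which is an exported, tested function:

1. **PPI-constrained co-expression network** — Pearson correlation for
   every gene pair, kept when |r| > 0.3 and Benjamini–Hochberg q < 0.05
   (one family over all pairs), then intersected with a
   protein–protein-interaction edge list; scale-freeness checked by a
   log–log least-squares fit of the degree distribution.
2. **Gene-category analysis** — network genes partitioned into
   disease-and-immune / disease-only / immune-only / other; degree and
   incident-edge |r| distributions compared across categories (Wilcoxon
   rank-sum, exact by enumeration for small samples); first-neighbour
   subnetworks around disease genes.
3. **Module mining** — greedy-modularity communities on the |r|-weighted
   network, size-filtered and ranked by edge density.
4. **Consensus classification** — Monti-style resampling consensus
   clustering of each module's expression submatrix; the number of sample
   groups k chosen where the relative gain in area under the
   consensus-index CDF drops below 10%; labels tested against true
   case/control status by Pearson chi-squared.
5. **Expression statistics** — per-module co-expression fractions,
   per-gene Welch t-tests, hypergeometric enrichment of DE genes in
   modules, and GMT-based over-representation analysis.

A synthetic-data generator (`simulate_study()`) plants co-expression
modules (shared-latent-factor model with calibrated within-module
correlation), a scale-free PPI overlay, annotation sets with controlled
overlap and a pathway collection with known positives, so the entire
analysis runs and is tested without any external database.

## Worked example

The `analysis/` directory holds the numbered scripts of the full
workflow; each is a thin driver over the package and writes its tables
under `results/analysis/`. Running them in order
(`Rscript analysis/01_simulate.R` … `07_enrichment.R`) on the default
synthetic study (1000 genes, 7 vs 7 samples, five planted modules of 10
genes at within-module r = 0.9, one module carrying a 2-SD disease
effect) prints, among other things:

```
PPI-supported network: 45 nodes, 143 edges
4 modules mined
  module size density disease_and_immune disease_only immune_only other
1      1   10  1.0000                  0            0          10     0
2      2   10  0.8000                  0            0          10     0
3      3   10  0.8000                  8            2           0     0
4      4   10  0.5111                  0            0          10     0
per-module consensus classification vs true groups:
  module k_selected chisq df        p
1      1          5   2.0  4 0.735800
2      2          4   4.8  3 0.187000
3      3          3  10.0  2 0.006738
4      4          5   3.2  4 0.524900
  module size frac_gt_0.5 frac_gt_0.7 n_de direction de_enrichment_p
3      3   10           1           1   10         1       8.965e-08
```

Reading this: the network contains only the genes with PPI-supported
co-expression; four of the five planted modules are recovered as dense
clusters; module 3 — the one composed of disease-annotated genes — is the
only module whose consensus clustering separates samples in agreement
with true disease status (chi-squared p = 0.0067 at the selected k = 3),
and all ten of its genes are differentially expressed, giving a
hypergeometric DE-enrichment p of 9e-8. The non-disease modules are
tightly co-expressed (every pairwise |r| > 0.7) but carry no group
signal, exactly as planted.

The same end-to-end run is available in one call:

```r
library(gbsnet)
report <- run_pipeline(sim_config(within_module_r = 0.9,
                                  frac_module_edges_in_ppi = 1, seed = 1))
print(report)
```

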