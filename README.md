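# chromarch

Comparative analysis of Hi-C chromatin architecture between two biological
conditions, in tidyverse-native R.

Plant and animal genomes fold into a hierarchy of structures that Hi-C
resolves as features of a binned contact matrix: megabase-scale **A/B
compartments** (gene-rich, active A vs gene-poor, inactive B), **TAD-like
domains** (blocks of elevated self-contact bounded by insulation minima),
and focal **chromatin loops** (pixel-level enrichment between two distant
anchors). When two tissues or phenotypes are compared — for example
inflorescence buds of monoecious vs gynoecious plants — the questions are
where these structures differ, which contacts change significantly, and
whether differentially expressed genes (DEGs) concentrate in the altered
regions. `chromarch` implements that comparative workflow end to end,
starting from binned intra-chromosomal contact matrices, together with a
ground-truth simulator used to benchmark every stage.

## Methods at a glance

* **Balancing** — iterative correction (ICE): find per-bin biases
  *b<sub>i</sub>* with *balanced(i,j) = raw(i,j) / (b<sub>i</sub>
  b<sub>j</sub>)* such that unmasked marginals are equal (coefficient of
  variation ≤ 1e-6). Low-coverage bins are masked.
* **Expected and O/E** — the distance-decay expectation *E(d)* is the mean
  balanced value at bin separation *d*; O/E = balanced / *E(d)*.
* **Compartments** — per chromosome, the first principal component of the
  Pearson correlation matrix of O/E columns; the sign is oriented so
  gene-dense bins are positive (A). Significance of the A-vs-B gene-density
  contrast uses Welch's two-sample *t*-test.
* **Domains** — insulation score (mean signal in a sliding off-diagonal
  square, log2 ratio to its chromosome mean, locally detrended); boundaries
  at prominent minima; an interval between boundaries is a domain when its
  interior O/E exceeds the flanking O/E by a contrast factor. An
  arrowhead-transform caller (`A(i,d) = (M(i,i−d) − M(i,i+d)) / (M(i,i−d) +
  M(i,i+d))`) provides an independent cross-check.
* **Loops** — donut-filter caller: each pixel is tested against the larger
  of two distance-corrected local backgrounds (donut and lower-left
  kernel) with a Poisson upper tail on raw-count equivalents, BH-corrected;
  calls are validated by aggregate peak analysis (APA score = centre of the
  aggregated O/E submatrix over its lower-left 3×3 corner).
* **Differential contacts** — the MD-plot procedure: per-pixel
  *M = log2((x₂+1)/(x₁+1))* vs distance *D*, joint loess normalization of
  *M* on *D*, per-distance-stratum Z-scores, Benjamini–Hochberg FDR; the
  anchor bins of significant pixels merge into differential contact
  regions.
* **Integration** — DEGs filtered at FDR ≤ 0.05 and fold ≥ 2; strand-aware
  promoters; hypergeometric enrichment (upper tail, `P(X ≥ k)` for
  population *N*, class *K*, draw *n*, overlap *k*, computed in log space)
  of gene sets and differential-contact anchors across common/changed
  architecture classes; promoter-density contrasts; virtual-4C per-gene
  interaction profiles.
* **Simulator** — paired-condition Poisson counts from the multiplicative
  model *μ<sub>ij</sub> = depth · (|i−j|+1)<sup>−α</sup> ·
  (1 + c·s<sub>i</sub>s<sub>j</sub>) · t<sup>[same domain]</sup> ·
  λ<sup>[loop]</sup> · f<sup>[differential]</sup>*, with programmed
  compartment flips, boundary shifts, loop gains/losses, depth ratios, and
  a gene/DEG table whose DEGs sit preferentially in altered regions.

## Worked example

Simulate a two-condition experiment (2 chromosomes × 400 bins at 10 kb,
the package default), call every layer, and test DEG enrichment:

```r
library(chromarch)

cfg <- simulation_config(seed = 42)
sim <- simulate_pair(cfg)

b1 <- balance(sim$cm1)
b2 <- balance(sim$cm2)
b1
#> <balanced_matrix> sample=cond1 | 141261 pixels, 18 masked bins, 58 iterations, marginal CV 9.84e-07

t1 <- call_compartments(oe_transform(b1), sim$genes)
t2 <- call_compartments(oe_transform(b2), sim$genes)
compartment_gene_stats(t1, sim$genes)
#> Gene density A vs B: 3.581 vs 1.798 genes/bin (n = 391, 391)
#> Welch two-sample t-test: t = 14.75, df = 730.39, p = 2.627e-43

cc <- compare_compartments(t1, t2)
attr(cc, "summary")
#>   class    n_bins
#> 1 A->B         25
#> 2 B->A         78
#> 3 common-A    363
#> 4 common-B    301

d1 <- call_domains(b1); d2 <- call_domains(b2)
domain_stats(d1)
#>       n median_length coverage
#> 1    29         90000     0.31

dc <- detect_differential(loess_joint_normalize(md_table(sim$cm1, sim$cm2)))
dc
#> <differential_contacts> 158 of 157816 pixels at FDR <= 0.05; 72 merged differential contact regions

classes <- region_class_map(cc, compare_domains(d1, d2))
enrich_genes_in_classes(filter_degs(sim$degs), sim$genes, classes, "comp_class")
#>      class    N    K  n  k  fold       p   p_adj
#> 1  changed 2068  221 98 21 2.005 0.00107 0.00321
#> 2 common-A 2068 1291 98 57 0.932 0.84134 0.94833
#> 3 common-B 2068  556 98 20 0.759 0.94833 0.94833
```

Reading the output: balancing converged (marginal CV below 1e-6); the A
compartment carries about twice the gene density of B, as it should by the
generator's design; 103 of 767 classified bins switch compartment between
conditions (the generator flips two 25-bin blocks per chromosome, plus
call jitter at block edges); called domains have a 90-kb median length and
cover 31% of the genome; 158 pixel-level contacts differ at FDR ≤ 0.05;
and the 98 DEGs are two-fold enriched in changed-compartment bins
(hypergeometric p ≈ 1e-3 on this single draw — the acceptance script pools
three draws for a sharper test).

`run_pipeline(default_run_config(seed = 1), out_dir = "run1")` chains all
stages (simulate → balance → compartments → domains → loops → diffhic →
enrich → profile → report), writes BED/BEDPE/bedGraph/TSV artifacts plus a
JSON run log with per-file checksums, and is byte-reproducible from config
and seed. `autoplot()` methods and `plot_md()` / `plot_matrix()` draw the
standard figures for each result type.

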