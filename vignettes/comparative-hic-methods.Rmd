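---
title: "Comparative Hi-C architecture analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hi-C architecture analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromarch)
```

`chromarch` compares the chromatin architecture of two conditions from
binned intra-chromosomal Hi-C matrices: compartments, TAD-like domains,
loops, pixel-level differential contacts, and the enrichment of
differentially expressed genes (DEGs) in the regions where architecture
changes. This vignette is the package's account of the underlying models,
the parameters that matter, the numerical choices we made where the design
was genuinely open, and what the bundled simulator does and does not
emulate.

## The data model

Everything lives on a `binned_genome`: ordered chromosomes, lengths and a
bin size, with 0-based half-open bins. A `contact_matrix` is a tibble of
upper-triangle triplets `(chrom, bin1, bin2, count)`; symmetry is implied
and enforced on construction (lower-triangle records are reflected,
duplicates summed). Only cis (intra-chromosomal) contacts are modelled:
every downstream analysis here is cis, and trans matrices would need a
different normalization and background model.

## Balancing

`balance()` is iterative correction (ICE): alternate between computing
marginals over unmasked bins and dividing the matrix by their outer
product, accumulating per-bin biases, until the coefficient of variation
of the marginals is below `tol` (default 1e-6, within `max_iter = 200`
sweeps — the default simulated genome converges in ~60). The equal-marginal
contract, not the specific algorithm, is what downstream code and the
tests rely on; Knight–Ruiz balancing would satisfy the same contract.
Biases are rescaled at the end so the overall count scale is preserved,
which keeps "raw-count equivalents" (`balanced * b_i * b_j`) meaningful
for the Poisson tests in the loop caller.

Bins are masked when they have no nonzero pixel, fewer than `min_nnz`
nonzero pixels, or fall in the lowest `mask_quantile` (default 2%) of
nonzero-pixel counts. Public Hi-C pipelines do not agree on a single
coverage filter; the quantile form is configurable and the tests assert
only the contract (masked bins propagate as `NA` everywhere).

One consequence of equalizing marginals on a finite chromosome matters
repeatedly: bins near the chromosome ends have truncated distance support,
so ICE upweights them, bowing both the balanced signal and O/E upward near
the ends. Two downstream choices compensate (see Domains).

## Expected profile and O/E

`expected_profile()` averages balanced values per distance stratum over
unmasked pairs, counting absent pixels as zero; `oe_transform()` divides
by it. Strata with zero or undefined expectation propagate `NA`. Note the
expectation is genome-wide at each distance: where domains cover a large
genome fraction, the short-range expectation is itself inflated by them,
so a true domain's interior O/E sits only moderately above 1 — the reason
the domain filter below uses a local contrast, not an absolute O/E level.

## Compartments

`call_compartments()` follows the standard eigenvector convention: per
chromosome, the Pearson correlation matrix of O/E columns over usable bins
(unmasked, nonzero variance), then the first principal component of that
correlation matrix. The PC sign is arbitrary, so the track is oriented by
gene density: positive bins must have at least the gene (TSS) density of
negative bins, otherwise the track is negated; positive = A. Orientation
by gene density is a design choice — the convention in the field's tools —
and ties are kept as computed with a warning. Whole chromosomes (not arms)
are analysed; the desk-scale simulated chromosomes have no centromere
structure that would argue otherwise.

`compare_compartments()` classifies each bin jointly (`common-A`,
`common-B`, `A->B`, `B->A`, `NA`) and merges discordant runs into changed
regions (minimum run length 1 bin by default: on simulated data even
single-bin flips at block edges are real signal; on noisy real data a
larger `min_run` is advisable).

The A-vs-B gene-density contrast (`compartment_gene_stats()`) uses Welch's
two-sample *t*-test — unequal variances, Welch–Satterthwaite degrees of
freedom, two-sided — implemented in closed form and cross-checked in the
tests against `stats::t.test`.

## Domains

The default caller is insulation-based. The insulation statistic at bin
*i* is the mean balanced value in the `w × w` square connecting the `w`
bins upstream to the `w` bins downstream (`w = window / resolution`,
window default 50 kb); the score is its log2 ratio to the chromosome mean,
then **detrended by a running median** over `4w + 1` bins. The detrending
removes the slow positional bow that balancing introduces near chromosome
ends; without it a structure-free decay matrix shows spurious end
structure and the null score is far from flat. Boundaries are local minima
with prominence ≥ `delta` (default 0.15 log2 units, about 4 null standard
deviations at the simulator's default depth).

Candidate domains are the intervals between consecutive boundaries, 2 to
`max_domain_bins` bins long. An interval is retained when its mean
interior O/E exceeds `oe_floor` (default 1.2) **times the mean O/E of the
flanking off-diagonal blocks at comparable distances**. The local contrast
is again the end-bow-robust choice: an absolute floor either rejects true
domains (genome-wide expectation inflated by domain coverage) or accepts
chromosome-end bows. The reported boundary set of a `domain_set` is the
set of retained domain edges; raw candidate minima stay available as an
attribute.

The arrowhead caller uses `A(i, d) = (M(i,i−d) − M(i,i+d)) / (M(i,i−d) +
M(i,i+d))` — decay cancels in the ratio — and the mean over `d ≤ w` as a
signed boundary statistic: strongly negative at domain starts, strongly
positive at ends. Signed extrema beyond `delta` are boundary candidates;
domains are then filtered exactly as above. This is a deliberate
reduction of the full dynamic-programming arrowhead corner score: the
comparative claims depend on domain positions, which both callers must
agree on (the suite checks ≥80% boundary agreement at ±1 bin), not on
arrowhead internals. Nested domains are out of scope; the segmentation is
flat.

`compare_domains()` matches greedily by reciprocal overlap (default 0.8)
and classifies bins with boundary regions of `boundary_width` bins
(default 1 = 10 kb at the default resolution; the width of a "boundary
region" is not standardised, so it is a parameter).

### Benchmark design

The domain-recovery benchmark runs on compartment-free maps (`c = 0`).
Compartment-block transitions are genuine insulation minima — the dip is
about `2c` in log2 units, overlapping the prominence range of weak TAD
boundaries — but they are not in the TAD truth set, so on a full map they
would be scored "spurious" while being real structure. Compartment
recovery has its own benchmark on the full default map. This is a
statement about how the benchmark isolates one structure at a time, not
about the callers, which run unchanged on full maps.

## Loops

`call_loops()` tests **every** pixel whose donut fits inside the matrix
and clears the diagonal (separation > `2 * donut_width`); testing all
pixels, not a high-O/E preselection, keeps the BH correction valid over
the full family. The local expected value is the distance-corrected mean
O/E over two neighbourhoods — the donut (square of halfwidth
`donut_width = 5` minus the peak box of halfwidth `peak_width = 1` and the
pixel's own row/column bands) and the lower-left box between the pixel and
the diagonal — with the larger of the two used. The lower-left kernel is
essential, not cosmetic: for a pixel at a domain corner the donut spans
mostly outside the domain and under-estimates the background, and with the
donut alone the caller floods domain interiors with calls. Significance is
a Poisson upper tail on raw-count equivalents, BH across all tested
pixels; retained pixels need adjusted p ≤ `fdr` (0.05), fold ≥ `min_fold`
(2) over the local expectation, and observed count ≥ `min_obs` (15) —
isolated low-count pixels can reach extreme Poisson tails through a
handful of reads and the count floor removes them. Touching significant
pixels merge to the strongest.

APA (`apa()`) averages O/E submatrices of halfwidth 5 (an 11×11
aggregate) over loop pixels far enough from edges and diagonal; the score
is the centre over the mean of the lower-left 3×3 corner. Random pixel
sets score ≈1; programmed loops score well above 2.

## Differential contacts

`md_table()` builds the per-pixel comparison over the union of nonzero
pixels: distance `D` in bins and `M = log2((x₂ + 1)/(x₁ + 1))` (pseudocount
1; double-zero pixels excluded). `loess_joint_normalize()` fits a
tricube-weighted local linear regression of `M` on `D` and subtracts it —
the fit is computed on per-distance means weighted by pixel counts, which
has the same limit as a pixel-level fit at a fraction of the cost, with
`surface = "direct"` for exact prediction. Span defaults to 0.4: wide
enough to be stable on 200–400 distance strata, narrow enough to track the
depth-and-distance bias.

`detect_differential()` standardises adjusted `M` within distance strata
(strata under `min_stratum = 100` pixels pool with neighbours) and
converts to two-sided normal p-values, BH across all tested pixels.
Two numerical choices matter:

* **Mean/SD, not median/MAD, by default.** Under exact Poisson counts the
  log-ratio distribution is discrete and short-but-heavier-tailed than
  normal in a way that makes the MAD underestimate the relevant scale; at
  the benchmark conditions the MAD default costs ~13 points of precision.
  `robust = TRUE` restores median/MAD for heavy contamination scenarios.
* **`min_avg = 15`:** pixels whose mean count is below 15 are kept in the
  table but not tested. Their log ratios take a handful of discrete
  values, carry no usable evidence, and deep-tail artefacts among a
  hundred thousand of them destroy precision.

Anchor bins of significant pixels merge (when adjacent) into 1-D
differential contact regions. Replicates are assumed pooled per condition
before comparison — the procedure compares exactly two matrices; a
replicate-aware count model is a different method family and out of scope.

## Integration

DEGs are genes with FDR ≤ `max_fdr` (0.05) and |log2 fold change| ≥
log2(`min_fold`) (fold 2, two-sided). Promoters default to 2,000 bp
upstream + 200 bp downstream of the strand-aware TSS — a conventional
span; it is a parameter because no single definition is standard. Genes
map to bins by TSS (promoter-centric claims motivate this; whole-body
assignment would double-count long genes across bins).

Enrichment uses the upper-tail hypergeometric probability `P(X ≥ k)`,
computed in log space with a suffix log-sum-exp (`hyper_upper_tail()`),
exact to enumeration for all populations the tests cover and asserted at
`k = 0 → p = 1` exactly. For gene sets the population is all annotated
genes on classified bins; for differential contacts the unit is the anchor
bin (population = classified bins). Units were an open choice — pixels,
anchor bins, or merged regions; anchor bins make the two enrichment
analyses symmetric and keep the population finite and well-defined. BH
across classes is reported alongside raw p. The "background" of the
promoter-density contrast is the genomic complement of the merged
differential regions — the other natural choice, matched random regions,
adds a sampling layer without changing the contract.

The `region_class_map` carries the compartment dimension
(`common-A`/`common-B`/`changed`), the domain dimension
(common/changed × interior/boundary, non-TAD) and a derived
`combined_class` (changed in either dimension vs common) for headline
contrasts.

## The simulator

`simulation_config()` materialises, deterministically from its seed, a
full generative layout; `simulate_pair()` draws independent Poisson counts
for the two conditions from

μ(i,j) = depth · (|i−j|+1)^(−α) · (1 + c·sᵢsⱼ) · t^[same domain] · λ^[loop] · f^[differential, condition 2]

with condition 2 additionally applying compartment-block flips,
domain-boundary shifts, loop gains/losses and a global depth ratio.
Defaults define the benchmark conditions: 2 chromosomes × 400 bins at
10 kb (an 8-Mb desk-scale genome), α = 1, depth = 400 (so adjacent-bin
pixels expect ~200 counts and the deepest analyses are not
count-starved), compartment blocks of 25 bins with contrast c = 0.15,
12 domains per chromosome of 8–15 bins with interior fold t = 2, 10 loops
per chromosome at separations 15–60 bins with fold λ = 4, 2 flipped
blocks and 3 shifted boundaries (4 bins — deliberately beyond the 0.8
reciprocal-overlap match so a shifted domain is unambiguously "changed")
per chromosome, 5 gained and 5 lost loops, and 30 differential pixels
(fold 3) at separations 1–8 bins where counts are informative. Genes are
placed per bin with class-dependent Poisson rates (A:B density 2:1,
boundary:interior 2:1); 100 DEGs are drawn with weight
`deg_enrichment_fold` (default 3) on altered bins (flipped blocks and
differential anchors), with log2 fold changes from ±N(2, 0.25²) floored
just above the 2-fold cutoff and FDRs drawn so programmed DEGs pass the
standard thresholds and no others do. `null_config()` strips all structure
(one 200-bin chromosome, pure decay, depth ratio 1.5) for calibration
runs.

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: restriction-fragment and mappability bias
(biases here are whatever ICE induces, not sequence-driven), overdispersed
counts (real Hi-C is super-Poissonian; the differential test's calibration
on real data depends on replicate pooling), nested/hierarchical domains,
compartment strength varying along the chromosome, trans contacts, and
structural variation between conditions. The generator is the minimal
multiplicative model exhibiting every structure the pipeline measures; it
is not a polymer simulation.

## Benchmarks and problem sizes

The acceptance suite (and `scripts/acceptance.R`) measures, at the default
conditions above: balancing convergence and agreement with a dense
Sinkhorn oracle; ≥95% compartment label agreement and flip
precision/recall pooled over 20 seeds; TAD boundary recall/spurious rate
(5 compartment-free seeds, pooled) and insulation-vs-arrowhead agreement;
loop recall/precision pooled over 3 seeds with APA validation on true and
50 random pixel sets; differential type-I control over 20 null seeds and
power/precision over 3 seeds; exact hypergeometric and Welch oracle
agreement; pooled DEG-enrichment significance over 3 simulated
experiments (a single experiment is one hypergeometric draw with sizeable
spread) with a 100-simulation uniformity check of null p-values; and
byte-level reproducibility of the full pipeline from config + seed. These
sizes keep the whole suite within a few minutes on one CPU while leaving
every recovery margin wide.

## Pipeline and configuration

`run_pipeline()` / `run_stage()` chain the stages with an explicit state
list, write all artifacts as plain text (sparse TSV, BED, BEDPE, bedGraph)
and a JSON run log with parameters, seed, versions and per-file checksums.
Configuration is a nested R list, loadable from YAML
(`read_run_config()`); unknown sections are rejected rather than silently
ignored. Logging goes to standard error via `message()`. The package is a
library first: the exported functions are the interface, and the
acceptance script is the only shell entry point.

## Known limitations

* Cis-only, single-replicate-per-condition comparisons; no GLM-based
  replicate-aware differential testing.
* The arrowhead caller is a reduced corner-statistic, cross-checked
  against insulation rather than against the original dynamic-programming
  implementation.
* Loop calling uses two kernels (donut + lower-left); horizontal and
  vertical band kernels are not implemented.
* Enrichment p-values are raw hypergeometric probabilities (with BH across
  classes reported); they inherit the usual caveats of overlapping
  genomic annotations.
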