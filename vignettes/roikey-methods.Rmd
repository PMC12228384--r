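---
title: "roikey methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{roikey methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`roikey` analyses region-of-interest (ROI) expression profiles from spatial
whole-transcriptome tissue profiling: counts pooled over a hand-drawn tissue
region rather than over cells or spots. The intended study shape is a
case/control cohort with two tissue compartments profiled per slide — a
myenteric plexus / intestinal epithelium colon design — with the ROI as the
statistical unit. This vignette records the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the package's tests do not
themselves compute.

## The synthetic study generator

Real ROI-level count data for this design are not publicly deposited, so the
package ships a generator (`sim_params()`, `generate_design()`,
`simulate_counts()`, `simulate_ppi()`, `simulate_gene_sets()`,
`simulate_study()`) whose defaults encode the study's stated world: 5 PD and
5 control specimens, one slide each, 6 ROIs per compartment (120 ROIs), and
18,677 gene targets. Plexus ROIs draw areas uniformly from 5,000–30,000 µm²
with 21–100 nuclei; epithelium ROIs 15,000–150,000 µm² with 101–1,000
nuclei, reproducing the observed size and cellularity contrast.

Counts are negative binomial with mean

    mu[g, j] = baseline[g] * 2^(lfc[g] * PD[j]) * exp(sum_b lambda[g, b] * F[j, b]) * lib[j]

and variance `mu + alpha * mu^2` with a single dispersion `alpha` per
simulation (the simplest structure the DE stage must recover). Where the
study states no value, defaults were chosen once as field-plausible and are
not revisited:

* `baseline_log_mean = 3`, `baseline_log_sd = 1.5` (natural log): median
  baseline ≈ 20 counts with a long right tail — a realistic shallow
  whole-transcriptome ROI depth. Per-ROI sequencing depth is nowhere
  reported, so this is flagged as invented.
* `dispersion = 0.2`: typical biological overdispersion for bulk-style
  counts; `0` gives the Poisson limit.
* `n_deg = 200`, `lfc_magnitude = 1`: planted effects, signs alternating so
  half go up in PD, half down.
* One batch factor per slide (`n_batch_factors = 1`), slide values standard
  normal, gene loadings `N(0, batch_sd = 0.5)` on the log-mean scale —
  matching the "replicate structure" that factor-based normalization
  leverages.
* Library factor = `area / mean(area)` × lognormal(0, `libsize_sd = 0.2`)
  noise: larger ROIs collect more material, which also makes library size
  compartment-structured, as in real slides.

All randomness flows from the single integer `seed` (internal sub-streams
use fixed small offsets of it); no global RNG state leaks. The ground truth
(planted genes with signed log2 fold changes, the centered ROI × factor
batch matrix, library factors) is returned and round-trips losslessly
through TSV.

What the generator does **not** emulate: probe-level effects, background
counts and QC failures, spatial autocorrelation between neighboring ROIs,
patient-level biological heterogeneity beyond the slide factor, compositional
(cell-type mixture) signal, and gene–gene correlation beyond the planted
factors. A green recovery test therefore establishes that a method works
under its own model assumptions — not that it is robust to everything real
tissue does.

The PPI stand-in is a Barabási–Albert preferential-attachment graph
(connected, scale-free), which reproduces the heavy-tailed degree
distribution of curated interactomes; `simulate_study()` places planted
effect genes on the highest-degree nodes so that end-to-end hub-recovery is
a meaningful target. Gene-set libraries mix uniform random terms with
planted terms seeded from the effect genes.

## Normalization and unwanted variation

`between_lane_normalize()` implements three between-sample methods. The
default is upper-quartile: each ROI column is scaled so the 75th percentile
of its **nonzero** values equals the across-column geometric mean of those
percentiles. Upper-quartile is the conventional default for sparse count
columns (plexus ROIs have many zeros, making medians unstable); median and
full-quantile variants are provided since the variant used upstream is not
recorded. Full-quantile replaces each column's sorted values with the mean
order statistic across columns, ties receiving the average of their tied
positions — so column multisets are identical afterwards only up to
tie-averaging.

`estimate_unwanted_variation()` is a replicate-based factor estimator:
`log(x + 1)`-transformed expression is centered per gene within each
replicate group, and the first `k` right-singular vectors of the centered
matrix (ROI space) are the unwanted factors. The pseudo-count is fixed at 1.

**Replicate grouping.** Replicates must *span* the nuisance structure:
centering within a group removes everything constant in it. A slide-level
batch factor is constant within a slide, so grouping by slide would
annihilate exactly the signal to be estimated. The default is therefore
group × compartment (slides pooled), under which condition-level biology is
removed and slide-to-slide variation survives into the SVD. An explicit
partition can be passed for other designs. `k` defaults to 1 and is
configurable; there is no attempt to select it automatically.

A practical note on rank: a strong lognormal factor acting on the log-mean
of *counts* is not exactly rank-1 in `log1p` space — weakly expressed genes
respond nonlinearly, spreading a single planted factor over trailing
components. The second singular value therefore dominates noise only in
bright, deeply sampled regimes; the factor *direction* itself is recovered
accurately (|correlation| > 0.9 with the planted slide factor at full
default scale) much more broadly.

`remove_unwanted()` subtracts the per-gene ordinary-least-squares projection
of `log1p` expression onto the factor columns (with an intercept, so gene
means are untouched), then maps back with `exp(·) − 1` floored at 0.
Projection makes the operation idempotent wherever the floor does not bind;
the floor can bind for weakly expressed genes, which is the price of
returning a count-scale matrix. The default pipeline route avoids the issue
entirely by passing factors as covariates into the differential test — the
conventional factor-analysis + NB-regression idiom — with matrix adjustment
behind `ruv_mode = "adjust"`.

## Differential expression

The test is a deliberately transparent negative-binomial Wald regression,
per compartment, ROIs as units:

* **Size factors**: median-of-ratios over genes with all-positive counts,
  with a positive-count-only fallback, normalized to geometric mean 1.
* **Dispersions**: gene-wise method-of-moments
  `alpha = max(0, (s² − m)/m²)` on size-factor-normalized counts; a trend
  `a₁/μ + a₀` is least-squares fitted to the positive raw estimates, and
  the final value shrinks raw toward trend with weight 0.5 (configurable).
  Genes with no overdispersion evidence (`s² ≤ m`, including constant
  genes) keep `alpha = 0`.
* **Fit**: iteratively reweighted least squares for the log-link NB model
  with `log(size factor)` offset, design intercept + PD indicator
  (+ covariates), vectorized across genes; convergence is a relative
  deviance change below 1e-8 or 100 iterations, with per-gene convergence
  flags (non-convergent genes are flagged, never silently dropped).
  Positive log2 fold change means higher in PD.
* **Inference**: Wald `z = coefficient/SE` against the standard normal;
  Benjamini–Hochberg step-up adjustment with all-zero genes excluded from
  the denominator and propagated as `NA`; DEG rule `adj_p < 0.05` and
  `|log2FC| > 0.5`, both strict.

Divergences from the full DESeq2-style machinery are intentional and
documented: no independent filtering, no outlier (Cook's distance)
handling, no fold-change shrinkage, no dispersion prior beyond the trend
shrinkage. Acceptance is parameter recovery on synthetic data — calibrated
type-I error in [0.03, 0.07] at α = 0.05 and planted-effect recovery within
±0.15 log2 units — not numerical equality with any specific package.
Whether patient/slide should enter as a covariate is left to the caller
(`covariates =`); neither choice is claimed as canonical. Note one
statistical caveat the tests exercise: strongly direction-imbalanced
planted effects induce composition bias in median-of-ratios size factors,
as they do in any global-scaling normalization.

## Over-representation statistics

For overlap `k` between a `K`-gene set and an `n`-gene query in an `N`-gene
background: hypergeometric upper tail `P(X ≥ k)`, odds ratio
`k(N − K − n + k)/((K − k)(n − k))` (0 at `k = 0`, +∞ on a vanishing
denominator), combined score `OR × (−ln p)`. The background defaults to
`N = 20,003` — the unique value consistent with every checkable published
odds ratio of the reference analysis — and is configurable, with the run
log recording it. The query size `n` is the post-deduplication,
post-universe-intersection count. Only the upper tail is tested (no
depletion), and BH adjustment runs across the terms actually tested
(overlap ≥ 1). Adjusted p-values depend on the full term collection, so
only `p`/`OR`/`CS` per row are reproducible statistics; term-level `adj_p`
from a different library is not comparable.

## Network propagation and key genes

The interaction network is undirected and unweighted; self-loops are
dropped and duplicate edges collapsed; BioGRID TAB3 input is reduced to its
official-symbol columns with symbols upper-cased. The transition matrix is
the column-normalized adjacency `W'[i, j] = A[i, j]/degree(j)`.

The random walk with restart iterates
`p_{t+1} = (1 − r) W' p_t + r p0` to an L1 tolerance of 1e-8 (cap 1,000
iterations; non-convergence is an error carrying the residual), with an
exact mode solving `(I − (1 − r)W'')p = r·p0` for verification. Isolated
nodes have all-zero columns; the mass a walker would lose there is
re-injected through the seed distribution (`W''` fills those columns with
`p0`), a documented deviation from strict column-stochasticity that keeps
iterates on the probability simplex.

Choices worth recording:

* **Restart rate** `r` is not stated in the reference analysis; the default
  is 0.5, it is mandatory in the run log, and `rwr_stability()` sweeps
  r ∈ {0.3, 0.5, 0.7} to report key-gene sensitivity.
* **Seeding** uses |log2FC| of all tested genes mapped to the network,
  normalized to sum 1. A probability vector must be non-negative, so
  magnitudes are the minimal faithful reading of "initialized with the
  fold changes"; a signed variant (negatives floored at 0) is available as
  `seed_mode = "signed_positive"`.
* **Propagation runs on the full network** with fold-change seeding, not on
  a DEG-induced subgraph (mapping "the genes in the data" onto the
  network); nothing prevents passing a subnetwork explicitly.
* **Betweenness** is unweighted shortest-path betweenness over *ordered*
  pairs `s ≠ v ≠ t` (Brandes accumulation, O(VE)), i.e. twice the
  unordered convention; downstream use is rank-based so the factor 2 is
  immaterial. The printed definition's `σ_st` "from s to v" reads as a typo
  for "s to t" and the standard definition is implemented. Disconnected
  pairs contribute 0.

Key genes are the top-20 genes by steady-state probability — ties broken by
betweenness, then name, for determinism — intersected with the union of
overlap genes of significantly enriched terms (adj. p < 0.05). With 20
candidates against hundreds of pathway genes the intersection, not the
ranking, is the selective step.

## Pipeline

`run_pipeline()` executes normalize → unwanted-variation → differential
expression → enrichment (up- and down-regulated queries separately) →
propagation per compartment, mirroring the paired plexus/epithelium
reporting of the source design. Configuration is a flat `key = value` file;
`validate_config()` returns all problems (named by key) before any compute;
every intermediate table is written as TSV at full numeric precision, and a
fixed-seed run is byte-identical. The report echoes the resolved
configuration for provenance.

## Numerical notes and degenerate inputs

* All-zero ROI columns abort normalization with the ROI named; all-zero
  genes are carried through the DEG table with `NA` p-values.
* `estimate_unwanted_variation()` errors on singleton replicate groups and
  on `k` above the maximum possible rank; an exactly-centered matrix
  legitimately returns singular value 0.
* IRLS linear predictors are clamped to ±30 to avoid overflow on degenerate
  genes (e.g. one group all zeros); such genes are flagged by the
  convergence indicator.
* Full-quantile tie handling interpolates mean order statistics at averaged
  ranks; upper/median quantiles use R's default (type-7) sample quantile on
  nonzero values.
* Hypergeometric tails use the stable survival function rather than naive
  summation; tests verify it against exhaustive enumeration on small
  universes.

## Known limitations

* The ROI is the statistical unit; ROIs from one slide are treated as
  exchangeable within a compartment unless the caller adds a patient/slide
  covariate, so p-values can overstate patient-level evidence — exactly as
  in the design this mirrors.
* Dispersion shrinkage is a fixed-weight trend compromise, adequate for the
  simulated world at n = 30+ ROIs per group; small-cohort behavior should
  be benchmarked before reuse.
* The synthetic world cannot validate claims about real tissue (see the
  generator section); published DEG counts and key-gene identities from the
  reference tissue study are explicitly out of reach without the original
  raw counts.
* Enrichment requires a user-supplied GMT; no gene-set release is bundled.
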