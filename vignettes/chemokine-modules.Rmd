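---
title: "Chemokine co-expression modules and radiation-response assays: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemokine co-expression modules and radiation-response assays: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomodules)
```

# Scope and scientific background

Irradiated tumor cells mount a senescence-associated secretory phenotype
(SASP) whose chemokine component shapes which leukocytes infiltrate the
tumor. A central question is whether chemokines are induced individually,
uniformly, or in *modules* — groups of chemokine genes co-expressed across
cancer cells — and whether those modules interact redundantly with groups of
chemokine receptors co-expressed on immune cells. `chemomodules` implements
the computational side of that question end to end:

1. preprocessing of annotated single-cell expression matrices (gene
   detection filter, binned-dispersion feature selection, a variance-target
   PC rule, k-NN graph clustering with Rand-index stability selection);
2. correlation-based module discovery with leave-one-out stability and
   per-patient module scoring against immune infiltration;
3. a label-shuffling permutation test for receptor–ligand (RL) redundancy
   between chemokine and receptor modules;
4. the companion wet-lab statistics: linear-quadratic (LQ) clonogenic
   survival fits with RBE at 10% survival, SASP factor scores, migration
   indices, and a semiautomated SA-β-Gal image quantifier;
5. a synthetic-data module that generates every input with planted ground
   truth, so all of the above is testable without any external download.

# Data model

Expression data live in a `SingleCellExperiment` (genes × cells, assay
`logcounts`) with per-cell `patient`, `cell_type` and `treatment` labels;
`annotated_expression()` builds one from a cells × genes matrix. Values are
assumed non-negative and log-normalized (library-size normalization to a
fixed total followed by log1p). All flat interfaces are plain text: module
assignments and receptor–ligand maps as TSV, assay tables as CSV, images as
TIFF.

# Module discovery

For a gene panel (chemokines in cancer cells; chemokine receptors in
leukocytes), `spearman_panel()` computes midrank Spearman correlations over
the cells of the chosen population. Genes with zero variance in that
population cannot be rank-correlated; they are retained in the matrix with
r = 0, flagged, and excluded from clustering.

`extract_modules()` treats each gene's row of correlation coefficients as
its profile vector, computes Euclidean distances between profiles, clusters
them by average-linkage agglomeration, and cuts flat clusters at a fixed
cophenetic height (defaults used throughout: 1.65 for chemokine panels, 1.5
for receptor panels, the values appropriate for panels of roughly 50–80
genes — the cut height scales with panel size because profile vectors get
longer). A cluster becomes a module only if it has at least two genes and
its mean within-cluster pairwise Spearman r exceeds 0.15; singleton clusters
have no pairwise correlation and are never modules. Everything else is
reported as `unassigned`.

Module robustness is assessed two ways:

* `leave_one_out_stability()` repeats correlation + extraction with each
  patient held out and reports per gene pair the fraction of iterations in
  which both genes shared a module. Genes unassigned in an iteration count
  as not co-clustered; iterations left with fewer than three cells are
  skipped and removed from the denominator.
* the planted-truth recovery tests: on synthetic data with factor loading
  0.8 and 2000 cells the extraction recovers the planted partition with
  adjusted Rand index ≥ 0.9 (observed: 1.0) across ten generator seeds.

`score_modules_per_patient()` gives each patient the mean expression of the
module genes over that patient's population cells. Whether a module counts
as "expressed" in a patient has no canonical threshold; the package's
declared choice (`module_expression_calls()`) is a per-module null built by
drawing random same-size gene sets from the panel and flagging patients
whose score exceeds the null's 75th percentile. This is scale-free across
modules with different baseline expression; a fixed numeric threshold can be
supplied instead, and both raw and z-scored score matrices are available.
`correlate_modules_with_infiltration()` relates scores to per-patient
immune-cell abundances by Spearman correlation with pairwise deletion;
constant columns yield an undefined correlation reported as `NA`, never as
zero.

# The receptor–ligand permutation test

Given chemokine modules, receptor modules and a ligand→receptor pairing
table, the observed statistic for a module pair is the number of table pairs
with the ligand in the chemokine module and the receptor in the receptor
module. The null shuffles gene→module assignments: in each iteration the
genes currently assigned to any chemokine module are permuted across the
chemokine modules preserving module sizes, independently for receptors, and
all pairs are recounted from the same shuffle (a joint null). The p value is
the plain proportion of iterations with an equal or greater count, default
10,000 iterations. Design choices:

* **Shuffle universe.** Only genes assigned to some module participate;
  unassigned genes are excluded. This keeps the marginal module structure
  fixed, which is the standard exchangeability argument; the alternative
  (shuffling over the whole panel) would change module sizes' composition
  with unassigned genes and test a different null.
* **Plain proportion.** p = (#null ≥ observed)/n_iter, so p can be exactly 0
  when no null count reaches the observed one. The positively biased
  (k+1)/(n+1) estimator is available via `pseudo = TRUE`.
* **Oracle.** `exhaustive_rl_null()` enumerates every distinguishable
  assignment (multiset permutations) and returns exact tail probabilities;
  it refuses beyond 10^6 assignment combinations. The Monte-Carlo test is
  validated against it to within three binomial standard errors, and its
  null calibration (fraction of p ≤ 0.05 under a random pairing table) is
  verified to be conservative (≤ 0.07 over 500 simulated datasets; observed
  ≈ 0.03 — conservatism is expected because the discrete counts make the
  test's p values stochastically larger than uniform).

The shipped `default_rl_map()` is a consensus table of human chemokine →
receptor pairings assembled from the standard pharmacology literature, with
a provenance column; it is a replaceable default, not a claim about any
particular study's table, and interaction counts naturally depend on the
table used.

# Preprocessing

* `filter_genes_min_cells()` keeps genes detected (nonzero) in at least 10
  cells by default.
* `select_highly_variable()` implements CellRanger-style binned dispersion:
  genes are split into 20 equal-frequency mean-expression bins and the
  dispersion (variance/mean) is normalized within each bin by median and
  MAD. The robust scale is essential: with a z-score the normalized
  dispersion of an outlying gene is bounded by the bin size, which defeats
  the purpose of the ranking in small panels. Constant genes rank last by
  construction; remaining ties break by raw dispersion and then gene id, so
  the ranking is fully deterministic. Bins whose genes share a single
  dispersion value cannot be scaled and fall back to raw dispersion with a
  warning.
* `choose_pcs()` computes PCs on per-gene centered (not unit-scaled)
  expression — the standard workflow for log-normalized data, where scaling
  would up-weight noise-dominated genes — and keeps the smallest number of
  PCs explaining ≥ 25% of total variance, floored at 50 and capped at 100
  (and at the available rank). The decision is checked in the tests against
  a direct eigendecomposition oracle.
* `knn_cluster()` builds a Euclidean k-NN graph in PC space, weights edges
  by the Jaccard overlap of neighbor sets, and partitions by Leiden
  modularity. Community detection is deliberately pluggable — the stability
  criterion is the guarantee, not a specific algorithm. The default
  resolution (0.1) is coarse, appropriate for major-population structure;
  finer substructure needs a larger value.
* `clustering_stability()` computes pairwise Rand indices across a k grid
  and selects the smallest k whose partitions agree (Rand > 0.8) with the
  next two larger k values, mirroring the adjacent-k stability readout.
  `rand_index()`/`adjusted_rand_index()` are validated against brute-force
  pair enumeration.

# Linear-quadratic survival and RBE

Clonogenic surviving fractions follow S(D) = exp(−αD − βD²). `fit_lq()`
fits ln S = −αD − βD² by least squares in log-survival space with equal
weights (a variance-weighted option exists), replicates pooled rather than
averaged, under the physical constraints α ≥ 0, β ≥ 0 (a two-parameter
active-set solve; an active constraint is flagged, and coefficients negative
only to numerical precision are clamped silently). Iso-survival doses use
the cancellation-free root D_s = 2t/(α + √(α² + 4βt)), t = −ln s, so the
nearly-linear case (β → 0) stays accurate. The covariance of (α, β) is the
standard least-squares one and is reported only for unconstrained fits.
`compute_rbe()` is the dose ratio D_s(reference)/D_s(test) at s = 0.10
(RBE₁₀). Recovery behavior under multiplicative lognormal replicate noise
(σ = 0.1, triplicates, doses 0–8 Gy) is a median relative α error of ~6%
over 20 simulated curves, and noiseless curves are recovered to 1e−9.

`sasp_score()` is the per-replicate mean fold change over ten canonical SASP
factors (CCL2, CCL4, CCL5, CXCL1, CXCL8, CXCL10, ICAM1, IL1a, IL6, TNFa),
reported as mean ± SD across replicates. `migration_index()` first
normalizes migrated-cell counts to acquired bead counts (reference = the
maximum acquired bead count; any fixed reference cancels in the ratio) and
divides test by negative-control counts per immune subset.

# SA-β-Gal image quantification

The quantifier mirrors an interactive macro workflow on paired DAPI /
bright-field images:

1. **Rolling-ball background subtraction** — grayscale opening by a
   non-flat hemispherical structuring element (erode, then dilate with the
   ball's height profile), background subtracted and clipped at zero.
   Structures narrower than the ball survive; smooth gradients are removed.
2. **Gaussian blur** with the chosen radius (interpreted as the Gaussian
   sigma in pixels).
3. **Find Maxima with prominence** — pixels are flooded in decreasing
   intensity order; a local maximum survives as its own region only if it
   exceeds the saddle toward any higher region by at least the prominence,
   otherwise it merges. Prominence follows the topographic definition (peak
   minus highest saddle to a higher peak); dialects differ, so the tests pin
   the exact merge behavior with a two-peak fixture of controlled saddle
   depth. The DAPI nucleus count is the number of regions.
4. **Stain detection** — the SA-β-Gal signal is extracted from the RGB
   bright-field as a blue-dominance score (blue − mean(red, green), clipped
   at zero; the macro's "color intensity maxima" has no published formula,
   so this is a declared, pluggable choice), then background-subtracted,
   blurred and segmented exactly as the DAPI channel.
5. **Proximity restriction** — nucleus regions are enlarged by `enlarge_px`
   pixels, each enlarged pixel attributed to its nearest nucleus
   (Voronoi-style propagation), and a nucleus is positive when a connected
   stain region overlaps its enlarged area by at least `min_positive_area`
   pixels. Percent senescent = 100 × positives / total;
   `batch_quantify()` pools a directory of pairs as Σpositives / Σtotals.

Thresholds can be expressed as intensity quantiles
(`quantile_thresholds = TRUE`), making counts invariant to uniform intensity
rescaling. Coordinates are reported 1-based (row, col) — the R and EBImage
convention — rather than 0-based; areas are in px² with no physical
calibration, since the readout is a per-image fraction.

The default parameters (blur 2, min threshold 30, prominence 40, rolling
ball 15, enlarge 10, min positive area 150, on a 0–255 intensity scale) are
published values matched to the synthetic generator's geometry. The area
cutoff is derived from that geometry rather than tuned: with nuclei at least
2.5 × radius = 15 px apart and an effective stain extent of ~14 px, the
largest possible spill of one cell's stain past the Voronoi midline into a
neighbor's territory is ≈ 110 px², while a stained cell's own overlap is
≥ ~450 px²; 150 px² separates the two with margin on both sides. In the
interactive workflow these settings are chosen per batch, and they must be
re-tuned for other magnifications.

# The synthetic-data module

`simulate_modular_expression()` plants modules with a per-cell latent
factor: module gene = loading·factor + √(1−loading²)·noise, background genes
pure noise, then a common shift of +3 × (largest marginal SD) and clipping
at zero to mimic the non-negative log-normalized scale. The shift is common
to all genes so that feature selection sees the module genes' extra variance
rather than a mean offset; clipping affects ~0.1% of values and is a
documented distributional approximation. With unit noise the within-module
Pearson correlation is loading² and the Spearman correlation follows the
bivariate-normal relation r_s = (6/π)·arcsin(ρ/2) — for loading 0.8 that
predicts r_s ≈ 0.62, and the generated data match (empirical ≈ 0.63).
Patients are assigned round-robin; optionally a module is "active" only in
chosen patients, whose cells draw the factor with a positive mean shift,
planting per-patient heterogeneity for testing expression calls.

The generator deliberately does **not** emulate UMI counts, ambient RNA,
doublets, batch effects, mean–variance trends of real transcriptomes, or
patient-specific cell-type composition. Passing tests therefore demonstrate
the correctness and calibration of the algorithms under the stated
correlation model, not robustness to those artifacts. The per-patient
cell-count distribution of real cohorts is unknown to us and is exposed as a
parameter rather than fixed.

`simulate_survival_data()` draws SF = exp(−αD−βD²)·exp(ε),
ε ~ N(0, σ²), with the same multiplicative noise at every dose including 0
(the model value at dose 0 is exactly 1, so σ = 0 reproduces the curve
bit-exactly). `simulate_cytokine_panel()` applies lognormal replicate noise
to specified fold changes (the small e^{σ²/2} mean bias of multiplicative
noise is accepted and documented). `simulate_cell_images()` renders
non-overlapping Gaussian-profile nuclei (rejection-sampled centers at
minimum separation 2.5 × radius, bounded retries, error on failure) and
blue-dominant perinuclear stain discs for a designated positive subset, and
returns exact truth counts.

# Problem sizes and determinism

Every stochastic routine takes a single integer seed and no global state is
consumed. The validation suite uses: 2000-cell × 70-gene matrices over ten
seeds for module recovery; 10-patient leave-one-out at 1500 cells; 10^5
permutation iterations against exhaustive enumeration (≤ ~2000 assignment
combinations); 500 simulated datasets × 400 iterations for calibration; 20
simulated survival curves; and twenty 256² image fixtures with 50–150 cells.
These sizes were chosen so that each check is statistically meaningful while
the whole suite runs in a few minutes on a single core.

# Known limitations

* The receptor–ligand map is a consensus default; module-pair interaction
  counts are only as good as the supplied table.
* Cut heights (1.65 / 1.5) are panel-size dependent; for panels much smaller
  or larger than ~50–80 genes they must be rescaled (the tests demonstrate
  this with a 10-gene panel at height 1.2).
* The blue-dominance stain transform is validated against synthetic truth
  only; histology-grade stain separation (e.g. eosin counterstains) is out
  of scope.
* The LQ fit assumes homoscedastic log-scale noise; heavily weighted designs
  should pass explicit `weights`.
* H5AD ingestion is not provided; matrices arrive as
  `SingleCellExperiment` objects or plain matrices, and all tabular
  interfaces are TSV/CSV.
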