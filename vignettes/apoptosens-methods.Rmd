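---
title: "Models and methods behind apoptosens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apoptosens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptosens)
```

`apoptosens` predicts, cell by cell, how close a tumor's cells sit to the
point of no return of intrinsic apoptosis, starting from segmented
multiplexed-immunofluorescence intensity tables. This vignette explains
the models and the methodological choices; the README shows the
end-to-end usage.

## The two signaling models

### MOMP (pore formation)

Mitochondrial outer membrane permeabilization is modeled as a mass-action
network over one BH3-only "stress" species S, the effectors BAK and BAX,
and the anti-apoptotic proteins BCL2, BCL(X)L and MCL1:

* catalytic activation `S + E_k -> S + E*_k` at rate `k_act·[S][E_k]`
  (stress is a catalyst, not consumed — this makes the "dose" a
  well-defined control parameter for bisection);
* reversible sequestration `A_j + S <-> A_j·S` and
  `A_j + E*_k <-> A_j·E*_k` with on-rate `k_on` and off-rate
  `k_on·Kd`;
* irreversible dimerization `2 E*_k -> P_k` at rate `k_pore·[E*_k]²`.

The readout is `pore% (t) = 100·2([P_BAK]+[P_BAX]) / ([BAK]_0+[BAX]_0)`,
i.e. the fraction of effector molecules locked in pores. Pore formation
is irreversible, so the maximum over the horizon equals the value at
`t_end`. A cell is called **low sensitivity for MOMP** when pore% at the
reference stress dose of 200 nM stays strictly below 10%. The
**required stress dose** is the smallest dose reaching 10%, found by
bisection on `[0, 10 µM]` to 1 nM; profiles that cannot be permeabilized
within the bracket return `Inf`.

Kinetic defaults (`momp_parameters()`): `k_on = 1`, `k_act = 0.1`,
`k_pore = 0.05` (µM⁻¹ s⁻¹), `t_end = 3 h`. The Kd matrix encodes
canonical BCL2-family selectivity — BCL2 neutralizes activated BAX but
barely BAK, MCL1 the converse, BCL(X)L both, and all three bind stress at
0.01 µM. The *tight* Kd is 0.002 µM. This value matters: because the
pore sink is irreversible, a looser tight-Kd (say 0.02 µM) lets
sequestered effectors leak into pores over three hours for essentially
any physiological profile, every cell classifies "high", and the readout
degenerates. At 0.002 µM the free activated-effector concentration in an
anti-apoptotic-dominated cell is low enough that quadratic dimerization
stalls, producing a genuine sequestration threshold: cells with
`effectors + stress` exceeding their anti-apoptotic pool permeabilize,
others do not. All constants are configuration entries, so measured
values can be substituted without touching code.

### Caspase activation

Downstream of MOMP, cytochrome c is taken as saturating at `t = 0`, so
apoptosome formation is limited by APAF1 alone (fixed input, 0.123 µM):
`APAF1 -> Apop` (`k_apop = 0.01 s⁻¹`), `Apop + PC9 <-> Apop·C9`
(the active caspase-9 unit), catalytic `PC3 -> C3` by Apop·C9, XIAP
binding of both C3 (Kd 0.002 µM) and Apop·C9 (0.002 µM) with
XIAP-mediated C3 degradation (`k_deg3 = 1e-3 s⁻¹`), SMAC neutralizing
XIAP (0.001 µM, fully cytosolic at `t = 0`), and cleavage of a substrate
pool normalized to 1. The readout is `SC% = 100·cleavedSub` at
`t_sc = 60 min`; **high caspase activity** is `SC% >= 25`.

Two parameters deserve flags. The reversible apoptosome-PC9 recruitment
step needs a dissociation constant: `kd_apop9 = 0.001 µM` closes it and
is documented as a package default. And neither the 60-minute readout
time nor the 25% cutoff is an established constant — both are prominent
configuration entries chosen to give switch-like behavior over the
physiological 0.01-1 µM input range; analyses with measured calibrations
should revisit them.

Both right-hand sides are compiled C (under `src/`) driven through
`deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`; mass conservation of
every protein family is enforced by construction and verified to 1e-6 µM
in the tests. Combining the two binary readouts yields the pathway
quadrants (`both_high`, `momp_only`, `caspase_only`, `both_low`).

## Batch correction

Slide batch effects are removed in three steps, all per marker:

1. **Upper-quantile normalization** per (marker, slide): each group is
   scaled so its 75th percentile equals the geometric mean of the group
   quantiles for that marker (a scale-balanced target — the arithmetic
   mean would weight bright slides more).
2. **Rankit-affine alignment**: within each slide, the ordered reference
   intensities are regressed on rankits
   `qnorm((i - 3/8) / (n + 1/4))` (the standard order-statistic
   approximation; the exact formula is a package choice). The reference
   population is regulatory plus helper T cells, excluding cells within
   5% of the image margins; at least 50 reference cells per slide are
   required. The fitted intercept/slope `(a, b)` standardize every
   cell's value as `z = (x - a)/b`, putting the reference
   quantile-rankit line on the main diagonal for all slides. `b > 0` is
   enforced, so the correction never reorders cells within a slide.
3. **Restoration**: one pooled regression per marker of the normalized
   intensities on `z` across all slides maps the corrected values back
   to a common intensity scale, floored at 0 (intensities are
   non-negative; floored counts are logged). Per-slide restoration would
   re-introduce exactly the differences the affine step removed, hence
   pooled.

The per-(slide, marker) affine fit (rather than one joint matrix across
markers) keeps each marker's correction independent and auditable.

## Cell typing

Gating hierarchy, in order of precedence: AE1-or-PCK26-positive cells
are cancer; CD3-positive cells split by FOXP3 (regulatory), CD8
(cytotoxic), then CD4 (helper), else other immune; CD3-negative cells
positive for CD4, CD45 or CD8 are other immune; cells below every gate
are stroma. FOXP3 outranks CD4 so FOXP3+CD4+ cells are regulatory;
epithelial/CD3 double positives resolve to cancer and are flagged.
Positivity thresholds default to an Otsu split (maximum between-class
variance) of the log1p intensity histogram, excluding exact zeros —
restoration floors some values at 0, and that spike would otherwise
dominate the split.

A 2000-tree random forest (package `randomForest`) is trained on a
subset (0.6% of cells by default, mirroring a realistic manual-annotation
workload; tests use larger fractions on small cohorts) and classifies
all cells; the out-of-bag per-class error is the reported per-class
false-negative rate.

One wiring decision: `run_pipeline()` derives gates and annotation
labels on the *uncorrected* intensities and trains the forest on the
*corrected* features. Annotation is the in-silico analogue of manual
labeling on raw images; empirically, gating the corrected scale is
fragile for exactly the markers whose reference population is positive
(CD3, CD4, FOXP3) because the T-cell-anchored affine compresses the
negative mode. The forest, by contrast, benefits from the cross-slide
comparability of corrected features.

## Calibration to molar concentrations

MOMP proteins: `conc = intensity / HeLa_mean_intensity ×
HeLa_concentration`, per marker. Caspase proteins: the linear map
sending the cohort's intensity (median, IQR) onto a reference cohort's
(median µM, IQR µM), fitted cohort-globally (`fit_caspase_alignment()`),
with negatives floored and counted. Per-core profiles aggregate
intensities by median first and convert afterwards
(aggregate-then-convert); passing the cell-level alignment to the
aggregation keeps per-core and per-cell modes coherent (a homogeneous
core yields identical results in both modes).

The shipped `reference_standards()` table is a synthetic example on the
bundled generator's intensity scale. Its concentrations sit in the
physiological 0.01-1 µM range and were chosen once so that the default
cohort straddles the decision thresholds — the cancer compartment lies
near the MOMP boundary, immune cells are BCL2-protected (mostly low
MOMP sensitivity) yet caspase-competent. Real analyses must supply
measured standards; every number here is swappable configuration.

## Heterogeneity statistics

* **Quartile COD** `(Q3 - Q1)/(Q3 + Q1)` with linear-interpolation
  quartiles (`quantile` type 7) — scale-invariant by construction.
* **Shannon entropy**: binary model classes in bits
  (`-Σ (p + ε) log2(p + ε)`, `ε = 1e-10` guarding `log 0`); protein
  levels z-scored and binned at 0.1 SD, entropy in nats.
* **Moran's I** `(N/W)·Σ w_ij z_i z_j / Σ z_i²` with inverse-distance
  weights `1/min(d, 2000 px)` and zero diagonal; binary rook adjacency is
  available for analytic lattice patterns (checkerboard = exactly -1,
  left/right split near +1, random near `-1/(N-1)`). Outliers are removed
  per core by Tukey fences (1.5×IQR) before computation — a documented
  package reading of "without outliers" — and populations under 100 cells
  return a sentinel rather than a value. The ≥100 rule is inclusive at
  the boundary (`filter_population(inclusive = FALSE)` gives the strict
  variant).
* **Composition bootstrap**: the observed statistic is the mean
  within-patient pairwise Euclidean distance between core cell-type
  composition vectors; the null re-pairs cores at random preserving group
  sizes, 100,000 times, seed 42; the p-value is the fraction of null
  values at or below the observed (Jensen-Shannon distance is available
  as an alternative metric).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes: per-core cell counts from a truncated Normal(6492, 1228);
per-core Dirichlet mixtures over six cell types with an immune share
under 20% on average; lognormal marker intensities per cell type
(non-negative and right-skewed, as immunofluorescence intensities are),
with lineage-marker modes separated by several log-SDs and apoptosis
markers encoding BCL2-up-in-immune / BAK-XIAP-SMAC-up-in-cancer /
MCL1-low directions; Beta(14, 1) QC scores (median ≈ 0.95); per-slide
affine gain/offset distortions recorded in the ground truth; and spatial
layouts with Gaussian-nest cancer clusters and dispersed immune cells,
plus analytic checkerboard/split/random lattices for the spatial
statistics.

What it does **not** emulate — and hence what passing tests cannot show
about real data: segmentation errors and spillover between neighboring
cells, spatially correlated staining artifacts, the true joint
correlation structure of the nine apoptosis proteins (an optional
correlated-sampling mode would be needed to mimic observed
protein-protein correlations), cell-morphology features, and any
clinical-outcome structure. Recovery results on this generator validate
the *mechanics* of the pipeline, not biological accuracy of the default
constants.

## Numerical choices and degenerate inputs

* Margins are two-sided per imaging position, coordinates 0-based;
  margins at or beyond half the image dimension are rejected.
* Zero total effector makes pore% undefined (error); zero stress gives
  pore% = 0 exactly. Constant intensity vectors are errors where a
  spread is required (upper-quantile groups, caspase alignment IQR,
  binned entropy SD, Moran's I variance).
* Bisection returns the upper end of the final bracket, so the reported
  dose always reaches the threshold; tolerance 1 nM.
* Boundary conventions: MOMP low is strict (`< 10%`), caspase high is
  closed (`>= 25%`), population gate inclusive (`>= 100`).
* All randomness flows from explicit seeds; `run_pipeline()` derives
  fixed per-stage substreams from its root seed, so a rerun is
  bit-identical.

Problem sizes: the shipped tests run cohorts of roughly 1-5 thousand
cells (4-8 patients, 150-700 cells per core) and about 10³ ODE profiles
in the property suites — sizes chosen so the whole suite completes in
about a minute while keeping every statistical check at 3-SE strength.
The generator's cell-count default remains the full-scale
Normal(6492, 1228) per core.

## Known limitations

* Kinetic constants are plausible defaults, not fitted values; absolute
  pore% and SC% levels (and therefore the low/high fractions) shift with
  the calibration standards.
* BH3-only subtype identity, phosphorylation states and subcellular
  localization are outside the model scope; caspase-3 feedback cleavage
  of procaspase-9 is omitted from the minimal network.
* The caspase alignment is cohort-global; slide-level alignment would
  confound with the batch correction.
* Position-level exclusion lists (e.g. staining-loss positions) are
  accepted as input, not detected.
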