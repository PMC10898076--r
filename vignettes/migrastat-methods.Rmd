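---
title: "Methods and design of migrastat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of migrastat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrastat)
```

migrastat implements the quantitative layer of a combined in vitro / in vivo
study of cell migration and adhesion: single-cell trajectory statistics,
collective wound-front statistics, border-cell cluster morphometrics, ECM
adhesion-array profiling, and differential-expression set logic. Every input
class has a seeded synthetic generator with known ground truth, so each
statistic can be validated by parameter recovery rather than against
unavailable raw imaging data. This vignette explains the models behind each
statistic, the tunable parameters and their defaults, what the generators do
and do not emulate, and the numerical choices made where the methods
literature leaves room.

## Single-cell trajectory statistics

A track is a time-ordered series of 2D positions (µm) at a uniform frame
interval. The defaults throughout emulate a 24 h time-lapse imaged every
10 minutes: 145 frames at 1/6 h, frame 0 at barrier removal.

* **Travelled distance** is the sum of Euclidean distances between
  consecutive frames; **instantaneous speed** is step length over step
  duration; **straightness** is net displacement over travelled distance
  (1 for directed motion, near 0 for disoriented movement). Tracks with
  gaps should be split at the gaps rather than interpolated — interpolation
  fabricates displacements and biases speed downwards.
* **MSD** is the time-averaged mean-squared displacement over all
  overlapping frame pairs at each integer lag, reported up to
  `max_lag_fraction` (default 0.5) of the track duration. Time-averaging
  with overlapping pairs is the standard spreadsheet-macro behaviour and
  uses every available displacement pair; the trade-off is correlation
  between lags, which is why the diffusion fit is restricted to short lags.
  Per-track curves are pooled into an ensemble curve by a pair-count-
  weighted mean.
* **Diffusion** uses the 2D relation MSD = 4Dτ: a through-origin
  least-squares fit of ensemble MSD against lag over the first
  `fit_fraction` (default 0.25) of lags, with D = slope / 4. Short-lag
  fitting minimises MSD estimator variance, which grows roughly with the
  lag-to-duration ratio. A negative fitted slope (possible for confined or
  nearly stationary cells) is clamped to D = 0 and flagged rather than
  reported negative. Goodness is the uncentred R² of the through-origin
  fit; for ballistic (noise-free directed) motion the MSD is quadratic in
  lag, the linear fit degrades, and the log–log slope approaches 2 — this
  is reported, not suppressed.

The **Brownian generator** draws independent zero-mean Gaussian per-axis
steps with variance 2DΔt. The **persistent random walk** advances at
constant speed with wrapped-Gaussian heading increments of variance 2Δt/P
(P = persistence time) after relaxing a fraction `bias_strength` ∈ [0, 1]
of the angular gap toward a fixed bias direction. The study system has no
published motility model; this one was chosen because its two knobs map
directly onto the phenotypes of interest — persistence/bias tunes
straightness continuously from uncorrelated (diffusive long-lag MSD,
exponent 1) to perfectly directed (straightness 1) — not because it is a
fitted description of the cells. Parameter-recovery tests therefore show
estimator correctness, not biological fidelity.

## Wound-front statistics

The substrate is a binary mask stack (T × H × W) with pixel size and frame
interval metadata; the gap is a vertical band and fronts advance along x,
with image rows indexing positions along the wound. Statistics:

* **Gap area**: background pixel count × pixel size²; **closure rate**:
  (A₀ − Aₙ)/A₀ × 100. Retraction (Aₙ > A₀) yields a negative percentage
  with a warning rather than an error.
* **Time to fractional closure**: first crossing of the closure-percentage
  series, linearly interpolated between the bracketing frames.
* **Front velocity**: finite-difference rate of closed area; mean edge
  advance is the area rate divided by twice the wound length (two fronts).
  The default stencil is a centred difference (with one-sided ends), which
  is the least-biased pointwise estimate; the `trailing` option telescopes
  exactly, so summed trailing rates × Δt reproduce the total closed area —
  the discrete fundamental theorem holds exactly only for that alignment.
* **Leading edge extraction**: per row, the boundary between the last
  foreground pixel and the first gap pixel, so a front flush after pixel k
  sits at k × pixel size. Rows where the gap is locally closed are flagged
  and excluded (a distance to the front is undefined after contact). No
  hole-filling or smoothing is applied by default, keeping the statistic a
  pure function of the mask.
* **Edge regularity** is the sample variance (n − 1 denominator), across
  rows, of the unsigned distance between the front at the evaluated time
  and the initial edge, in µm². The dispersion is computed per side and
  averaged over the two fronts; per-side values are attached for workflows
  that follow a single edge. Reporting in µm² fixes the dispersion measure
  as a variance rather than a standard deviation. The default evaluation
  time is 6 h after barrier removal, the usual reporting point for this
  statistic; it is configurable.

The **wound generator** advances two fronts at `front_speed` each and adds,
on every frame after the first, an independent Gaussian per-row offset with
variance `roughness_variance`, redrawn each frame. Frame 0 is the straight
barrier edge. Under this construction the edge-travel distance per row at
any later frame is (deterministic advance) + (one Gaussian offset), so the
expectation of the regularity statistic equals `roughness_variance` exactly,
which is what makes the planted value recoverable. Two consequences are
worth stating plainly. First, redrawing offsets per frame means the gap
area is non-increasing only in expectation: when the per-frame front
advance is small relative to the offset SD, individual frames can
transiently re-open pixels. All shipped defaults and test configurations
keep the advance comfortably above the offset fluctuations, where the area
sequence is monotone with overwhelming probability; the zero-roughness case
is exactly monotone. Second, recovery tests choose the front speed so that
the mean edge travel at the evaluation time is at least ~4.5 offset SDs;
otherwise the unsigned distance folds at zero and biases the variance.
Pixelisation adds quantisation variance of pixel²/12 (0.33 µm² at 2 µm
pixels), negligible against the planted values (≥ ~1000 µm²).

## Cluster morphometrics

* **Migration index**: 100 × (centroid − anterior)/(oocyte − anterior),
  clamped to [0, 100] with a flag. The cluster is located by its voxel
  centroid; a front-most-point convention differs for elongated clusters,
  and which landmark terminates the normalisation (oocyte boundary versus
  nurse-cell boundary) is caller-supplied, so the landmarks are explicit
  arguments rather than derived.
* **Length/width/height** are extents of the foreground voxel cloud along
  its principal axes (eigenvectors of the coordinate covariance), sorted
  descending, with one mean voxel edge added to the centre-to-centre range.
  Principal axes rather than the bounding box because clusters sit at
  arbitrary orientations; an axis-aligned option exists.
* **Volume** is voxel count × voxel volume. **Surface area** comes from a
  marching-tetrahedra isosurface at the 0.5 level: each lattice cell is
  split into the six tetrahedra sharing the main diagonal and the crossing
  polygons are accumulated. Face counting was rejected (it overestimates
  oblique surfaces by up to ~50%), and meshing a raw binary volume still
  overestimates a sphere's area by ~27% because the isosurface is faceted
  at voxel scale. One 3×3×3 mean-filter pass (the default `smooth = 1`)
  band-limits the volume first and brings a radius-20-voxel sphere within
  1% of 4πr². The cost is rounding of genuinely sharp corners and
  unreliable areas for structures one or two voxels thick (where the code
  falls back to the unsmoothed mesh); cluster-scale objects are many voxels
  across, so the default favours the sphere-accurate setting.
* **Sphericity** is Wadell's ratio Ψ = π^(1/3)(6V)^(2/3)/A — the standard
  definition used by 3D morphometry software — computed from the mesh area
  and voxel volume; Ψ = 1 only for spheres, and stretching the generator's
  ellipsoid along one axis strictly increases length and decreases Ψ.

The **egg-chamber generator** voxelizes an axis-aligned ellipsoid at a
known fractional position between two landmarks. It is a geometry-only
stand-in: real clusters are lobed, protrusive and surrounded by other
tissue, so passing recovery tests validates the measurement chain, not
segmentation.

## ECM adhesion profiling

Input is a long-format table of attached-cell counts per (condition,
composition, replicate). The default panel is 36 compositions over nine
proteins (collagens I/III/IV/V/VI, laminin, fibronectin, vitronectin,
tropoelastin): the nine singletons plus 27 curated pairwise/triple mixes.
The published material names the nine proteins and seven compositions with
condition-specific differences but not the remaining printed mixes, so the
rest of the panel is a documented in-package choice; the seven named
compositions are all present, and analyses are panel-agnostic.

* **Profile means** average replicates per cell of the condition ×
  composition grid.
* **Reference normalisation** divides each condition's mean profile by the
  reference (wild-type) profile per composition; zero-reference
  compositions are flagged NA, not divided.
* **Similarity** is the Pearson correlation r between condition profiles
  across the panel, computed on replicate-mean raw counts (no transform is
  stated for the published analysis; a log1p variant is a caller-side
  transform of the means). Distance is 1 − r ∈ [0, 2]; **scaled distance**
  rescales by the largest off-diagonal distance among the compared
  conditions so the most dissimilar pair scores 1 — the printed "scaled
  distance" is not defined in the source methods, and this max-normalised
  reading is flagged as an inference.
* **Per-composition tests** are two-sided Welch t-tests of condition vs
  reference replicates with significance at p ≤ 0.05, matching the stated
  per-test criterion; no multiple-testing adjustment is applied by default
  because none is indicated for the published panel figure. A BH option
  changes flags only, never p-values, and BH q-values are always reported
  alongside.

The **array generator** draws Poisson counts around a condition ×
composition propensity table — adequate for spot-count data, though real
arrays also carry spot-to-spot printing variability (overdispersion) that
the recovery tests do not probe.

## Expression set logic

* **TPM**: per sample, count / length(kb), normalised to sum to 10⁶.
* **Signed fold change**: r = mean_B/mean_A on the symmetric scale (r if
  r ≥ 1, else −1/r), so +2 is a doubling and −2 a halving and the statistic
  is antisymmetric under swapping groups. A pseudocount of 0.5 raw-count
  units enters only when a group mean is zero, keeping the statistic finite
  without perturbing well-measured genes; two zero means give 1, flagged
  uninformative by construction.
* **DEG calling**: per-gene two-sided Welch t on log2(TPM + 1), BH-FDR
  across all tested genes (no independent filtering), and the filter rule
  |FC| ≥ 2 with q ≤ 0.05. The reference analysis used a negative-binomial
  GLM with dispersion shared across genes; that inference is deliberately
  not re-implemented here, and the gene-wise Welch t is an intentionally
  simple substitution that preserves the filtering rule, not the power.
  This matters quantitatively: with 3 samples per group a gene-wise t has
  ~4 degrees of freedom, and BH at rank 50 of 2000 genes demands
  p ≤ 1.25 × 10⁻³, which a 4-df t-statistic rarely attains even at
  noncentrality ~5 (|FC| = 4 at NB dispersion 0.1). The caller's measured
  sensitivity under those conditions is accordingly near zero — a property
  of the test at n = 3, reported as such, with fold changes themselves
  recovered accurately (median |FC| ≈ 4). Sensitivity comparable to
  moderated pipelines requires sharing variance across genes, which is out
  of scope here. Null calibration is honest: with no planted effects the
  flagged fraction stays far below the nominal 0.05.
* **Annotation filter and Venn partition**: unannotated genes are removed
  before partitioning (matching the published order of operations), and the
  partition (a∖b, b∖a, a∩b) is disjoint and conserves the union by
  construction.

The **count generator** plants signed fold changes by scaling the second
group's NB mean; baseline mean 100 and dispersion 0.1 are typical bulk
RNA-seq magnitudes. It does not emulate library-size differences or
gene-length-dependent sampling, both of which TPM is designed to absorb.

## Problem sizes, seeds and numerics

All generators take an explicit integer seed, restore the caller's RNG
state, and are bytewise deterministic given one. The validation suite uses
1000 tracks × 145 frames for diffusion recovery (relative error of the
recovered 4D slope well under 5%), 2000 rows for regularity recovery (the
2-SD sampling band of a variance at n = 2000 is ±6.3%, tightened further by
averaging the two fronts), 20-replicate simulations for null calibrations,
and radius-20-voxel spheres for mesh accuracy; these sizes put sampling
error comfortably inside the asserted tolerances while the full suite runs
in well under a minute. Ties and degenerate inputs are resolved
conservatively throughout: zero-variance profiles, zero-reference
compositions, never-reached closure fractions, stationary tracks and
untestable genes are flagged (NA + warning) rather than imputed.

## Known limitations

Synthetic inputs are pre-segmented by construction: nothing here validates
segmentation, tracking or imaging artefacts. The motility and roughness
models are chosen for testability, with per-frame-independent roughness
trading strict area monotonicity for an unbiased regularity expectation.
The surface-area default is tuned for blob-like clusters, not thin sheets.
The DEG caller's power at n = 3 is intrinsically low, as quantified above;
its outputs are best read as fold-change screens with calibrated false
positives rather than high-sensitivity detectors.
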