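# migrastat

Quantitative statistics for cell-migration studies that combine single-cell
tracking, collective gap-closure (wound-healing) assays, in vivo
border-cell migration, ECM adhesion arrays and RNA-seq screening — the
measurement layer used to tell apart migration phenotypes such as those of
disease-associated E-cadherin missense variants (directed, fast, matrix-
adaptable movement versus slow, disoriented movement).

The package is aimed at quantitative cell biologists and image analysts who
already have segmented/tracked data (trajectory tables, binary mask movies,
labelled 3D volumes, spot-count tables, count matrices) and need the
downstream statistics, plus seeded synthetic generators of every input
class so each statistic is validated by recovery of known ground truth.

## What it computes

* **Single-cell trajectories** — travelled distance, instantaneous speed,
  straightness, time-averaged MSD with ensemble pooling, and the diffusion
  coefficient from the 2D relation **MSD = 4Dτ** (through-origin short-lag
  fit, D = slope/4).
* **Wound fronts** — gap area, closure rate **(A₀ − Aₙ)/A₀ × 100**, time to
  fractional closure (interpolated), front velocity, leading-edge
  extraction, and the edge-regularity statistic: the variance (µm²) across
  the wound of the distance between the current front and the initial
  edge.
* **Cluster morphometrics** — border-cell migration index (% of the
  anterior→oocyte span), principal-axis length/width/height, marching-
  tetrahedra surface area, volume, and Wadell sphericity
  Ψ = π^(1/3)(6V)^(2/3)/A.
* **ECM adhesion arrays** — replicate-mean adhesion profiles over a
  36-composition, nine-protein panel, wild-type-normalised effects,
  Pearson-correlation similarity/distance/scaled distance, and
  per-composition Welch tests.
* **DEG set logic** — TPM, symmetric signed fold change, Welch t +
  Benjamini–Hochberg calling at |FC| ≥ 2 and FDR ≤ 0.05, annotation
  filtering, and the exclusive/common Venn partition of two contexts.
* **Synthetic data** — Brownian and persistent/biased random-walk tracks,
  rough-front wound movies, Poisson adhesion arrays, negative-binomial
  count matrices with planted fold changes, and voxelized egg-chamber
  clusters, all with explicit seeds and emitted ground truth.

## Worked example

```r
library(migrastat)

## single-cell statistics on simulated Brownian cells (D = 1.5 um^2/h)
trk <- simulate_brownian(n_tracks = 200, diffusion = 1.5, seed = 7)
ens <- ensemble_msd(lapply(split_tracks(trk), compute_msd))
estimate_diffusion(ens, fit_fraction = 0.25)
#> Diffusion estimate: D = 1.486 um^2/h (MSD = 4 D t)
#>   fit window: 0.167-3 h, R^2 = 1.0000

head(track_metrics(trk[trk$track_id %in% 1:3, ]), 3)
#>   track_id travelled_um net_um straightness D_um2_per_h fit_r2
#> 1        1          125  19.46       0.1554        1.53  1.000
#> 2        2          143  17.10       0.1195        1.90  0.999
#> 3        3          127   8.97       0.0705        1.36  0.990

## a 24 h wound movie: 600 um gap, fronts at 15 um/h, rough edges
sim <- simulate_wound(front_speed = 15, roughness_variance = 1174.5,
                      initial_gap = 600, width_px = 700, n_frames = 145,
                      seed = 7)
cs <- closure_series(sim$stack)
cs$closed_pct[37]                        # closure 6 h after barrier removal
#> 29.7
time_to_fraction(cs, 50)                 # hours to close half the gap
#> 9.96
as.numeric(wound_regularity(sim$stack, at_time = 6))  # planted: 1174.5 um^2
#> 1243.7
```

The recovered diffusion coefficient sits within a few percent of the
planted 1.5 µm²/h (the fitted MSD slope divided by 4), the low straightness
values are the signature of undirected Brownian motion, the movie closes
half of its 600 µm gap in ~10 h (the flat-front prediction is
600/2/(2·15) = 10 h), and the 6 h edge-regularity variance recovers the
planted per-column roughness within its sampling band.

## Layout

* `R/` — implementation; `vignettes/migrastat-methods.Rmd` — models,
  parameter choices, numerical decisions and limitations.
* `tests/testthat/` — unit, property and acceptance suites (hand-computed
  cases, brute-force oracles, parameter-recovery simulations).
* `scripts/acceptance.R` — the recovery battery above.
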