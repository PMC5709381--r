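# memcrowd

Trajectory analysis for coarse-grained simulations of protein-crowded
membranes — the kind of system where a hundred-plus copies of an inwardly
rectifying potassium (Kir) channel sit in a multi-component plasma-membrane
bilayer and one wants to know how the channels cluster, how fast and how
anomalously everything diffuses, and how much the bilayer undulates.

For whom: simulation groups extracting these observables from their own
coarse-grained membrane runs, and method developers who need estimators
with exact synthetic ground truth attached.

## What it computes

* **Protein clustering.** Channels are in contact when the lateral
  minimum-image distance between their cytoplasmic-domain centroids is
  ≤ 8.2 nm (configurable); clusters are connected components of the
  contact graph. Per-frame size labels, number/weight-average cluster
  size, neighbour-count fractions (1, 2, >2) with bootstrap standard
  errors (resampling proteins, 1000 iterations), pair-displacement maps,
  and residue-level contact frequencies at a 0.7 nm centroid cutoff.
* **Anomalous diffusion.** Time- and ensemble-averaged lateral MSD (FFT
  sliding-origin estimator, 1 ns grid, first 50 ns discarded), fitted with

      MSD(Δt) = 4 D_α Δt^α,   Δt ∈ [1 ns, 2 µs]

  by Levenberg–Marquardt least squares; `fit_anomalous()` returns a
  classed model object with `print`/`summary`/`coef`/`predict`/
  `residuals`/`plot`/`simulate` methods. `alpha_profile()` gives the
  lag-dependent exponent α(Δt) from windowed log-log slopes.
* **Bilayer undulations.** Phosphate-bead height fields on a 0.5 nm grid,
  leaflet assignment robust to undulations larger than the leaflet
  separation, radially averaged power spectra ⟨|h(q)|²⟩ with an exact
  Parseval identity, and normalized z-density profiles.
* **Lateral RDFs.** 2D, per-leaflet g(r) of lipid headgroups around
  protein centroids (or around arbitrary bead selections).
* **Synthetic generators with known truth.** Exact fractional Gaussian
  noise (Davies–Harte circulant embedding) for 2D walkers at prescribed
  (D_α, α); adhesive crowded-disk dynamics; spectrally prescribed
  undulating bilayers; cluster fixtures with unambiguous ground-truth
  partitions. A preset registry carries published diffusion coefficients
  (e.g. 37 for PC lipids, 10/13 for POPE variants, 4/1.1/0.4 for
  proteins, on the nm²/ns^α scale) so parameter recovery targets real
  reported values.

Input formats: GRO, PDB (via bio3d) and an internal lossless container;
everything internal is nm and ns on orthorhombic boxes.

## Worked example

Generate lipid trajectories at a published plasma-membrane diffusion
coefficient, then recover it:

```r
library(memcrowd)

preset <- preset_registry("PM_s-POPE")   # D_alpha = 10, alpha = 1
traj <- generate_diffusive_trajectory(preset, n_frames = 2048L, seed = 7)
traj <- remove_com_motion(traj)
msd  <- compute_msd(traj, discard_initial = 50)
fit  <- fit_anomalous(msd, fit_min = 1, fit_max = 500)
fit
#> Anomalous diffusion fit: MSD = 4 * D_alpha * dt^alpha
#>   species:   POPE-lipid
#>   fit range: 1 to 500 ns (134 points)
#>   D_alpha = 9.765 (sd 0.0093) nm^2/ns^alpha
#>   alpha   = 1.004 (sd 0.00017)
```

The fitted `D_alpha` is within ~2% of the generator's 10 and the motion is
diagnosed as normal (α ≈ 1). Cluster analysis on a fixture with known
partition:

```r
fix <- sample_cluster_configuration(
  40, data.frame(size = c(1, 4), weight = c(0.5, 0.5)),
  spacing = 7, box = c(137, 137, 10), seed = 42)
cs <- cluster_size_series(fix$trajectory, cutoff = 8.2)
cs
#> <cluster_series> 1 frames, 40 proteins, cutoff 8.20 nm
#>   mean cluster size (number-average): 2.11 (final frame 2.11)
#>   max cluster size: 4

neighbor_fractions(cs, n_boot = 1000, seed = 1)
#>   neighbors fraction    se_boot
#> 1         0    0.300 0.07145716
#> 2         1    0.375 0.07196335
#> 3         2    0.300 0.07075921
#> 4        >2    0.025 0.02467150
```

30% of proteins are singletons, and the 37.5%/30% split between one- and
two-neighbour proteins reflects the branched size-4 trees the fixture
generator grew; the standard errors are protein-resampling bootstrap
estimates.

A thin CLI over the same pipeline lives at `inst/scripts/memcrowd.R`:

```sh
Rscript inst/scripts/memcrowd.R run --preset free-Brownian --out out/ --seed 1
```

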