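---
title: "Quantifying clustering, anomalous diffusion and undulations in crowded membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clustering, anomalous diffusion and undulations in crowded membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcrowd)
```

## The problem

Coarse-grained simulations of protein-crowded plasma membranes — for
example tens to hundreds of copies of an inwardly rectifying potassium
(Kir) channel in a multi-component bilayer — produce microsecond-scale
trajectories from which several quantities are routinely extracted:

* which channels are in contact, and how the resulting clusters grow and
  branch over time;
* how fast proteins and each lipid species diffuse laterally, and whether
  their motion is subdiffusive (`MSD ~ dt^alpha` with `alpha < 1`);
* how strongly the bilayer undulates, summarized by the radially averaged
  power spectrum of its height field and by the phosphate z-density;
* how lipids distribute radially around the embedded proteins.

memcrowd implements that analysis stack on a single trajectory container,
together with synthetic generators whose ground truth is known exactly.
Raw multi-microsecond coarse-grained trajectories are far too large to
ship or regenerate routinely, so every analysis here is validated by
parameter recovery against the generators rather than against archived
simulation output; the preset registry carries published diffusion
coefficients so the recovery targets are the numbers a practitioner would
recognize.

## Data model and conventions

Everything runs on `mc_trajectory`: a frames × particles × 3 array in nm,
a per-frame orthorhombic box, a constant frame spacing in ns, and a
topology labelling each particle with species, molecule, 1-based residue
id, bead role (protein bead, headgroup, phosphate, tail, other) and
leaflet. Units are nm and ns throughout; file readers convert at the
boundary. Triclinic boxes are rejected explicitly — the systems this
package targets are rectangular.

Periodic boundaries are handled by the minimum-image convention. Contact
tests, pair maps and RDFs use *lateral* (x, y) distances: transmembrane
proteins share the bilayer plane, and using 3D distances would let large
vertical undulations corrupt contact calls. Unwrapping accumulates
minimum-image steps between consecutive frames, which is exact provided no
particle moves half a box edge per frame; near-ambiguous steps trigger a
warning naming the particle and frame.

Centre-of-mass removal translates each frame by the drift of one global
selection (all particles by default, i.e. proteins and lipids together
rather than per species or per leaflet); it is idempotent, and
displacement-based analyses expect it to have been applied.

## Cluster analysis

Two channels are "interacting" when the lateral minimum-image distance
between the centroids of their cytoplasmic domains is at most the contact
cutoff, 8.2 nm by default; the boundary distance counts. For Kir2.2-like
channels the cytoplasmic domain is conventionally residues 1–45 and
141–377, passed as `residue_range`. Clusters are connected components of
the resulting contact graph (via igraph). Per frame the package records
each protein's cluster-size label and degree, the raw material for
cluster-evolution maps.

Choices worth knowing about:

* *Mean cluster size* averages over clusters, singletons included
  (number average). The protein-weighted average — the mean cluster size a
  protein finds itself in — is available via `mean_type = "weight"`.
* Whether the published 8.2 nm test was 2D or 3D is not stated where this
  convention originates; lateral is the default here for the reason above.
* `neighbor_fractions()` reports the fractions of proteins with 1, 2 or
  more than 2 neighbours; proteins with none are reported separately so
  the three fractions match "proportion of all channels" reporting.
  Standard errors are bootstrap estimates, resampling *proteins* with
  replacement (1000 iterations by default) — resampling frames would
  mostly measure temporal autocorrelation instead of population spread.
* Residue-level contacts use 0.7 nm between residue centroids (all beads
  of the residue), pooled over protein copies by residue id and normalized
  by the total interaction count. The same 0.7 nm default is reused for
  lipid-headgroup contacts because no separate value is conventional; it
  is configurable.
* Pair-displacement maps accumulate raw minimum-image displacement
  vectors of protein pairs into a histogram normalized to a maximum of 1.
  Bins are centred on multiples of the bin width so the map is exactly
  inversion symmetric. No orientation alignment is applied.

```{r cluster-demo}
fix <- sample_cluster_configuration(
  40, data.frame(size = c(1, 4), weight = c(0.5, 0.5)),
  spacing = 7, box = c(137, 137, 10), seed = 42)
cs <- cluster_size_series(fix$trajectory, cutoff = 8.2)
cs$stats
neighbor_fractions(cs, n_boot = 1000, seed = 1)
```

The fixture generator grows clusters as random trees with bond length
`spacing` and places them with bead-to-bead gaps above twice the cutoff,
which makes the generated partition the unique correct answer for any
contact cutoff between `spacing` and `cutoff` — that is what "exact
agreement with ground truth" means in the tests.

## Diffusion analysis

`compute_msd()` evaluates the time- and ensemble-averaged lateral MSD on
the frame grid (1 ns by default), using every sliding time origin; the
sliding-origin sums are computed with the FFT autocorrelation identity, so
the full lag range costs `O(T log T)` per particle. The first 50 ns are
discarded as equilibration. Lags are kept densely up to 100 frames and
log-thinned beyond (about 50 per decade, endpoint always kept) — the
estimator is computed at every lag; thinning only reduces the stored
curve.

The transport model is the 2D anomalous diffusion law

    MSD(dt) = 4 * D_alpha * dt^alpha

fitted by Levenberg–Marquardt nonlinear least squares over 1 ns – 2 µs
(clamped to the data with a warning when the trajectory is shorter),
initialized from the log-log regression, unweighted by default (a weighted
option exists; unweighted is the simplest defensible convention when no
per-point variance model is claimed). `fit_anomalous()` returns a classed
model object with `print`, `summary`, `coef`, `predict`, `residuals`,
`plot` and `simulate` methods — `simulate()` regenerates synthetic
trajectories at the fitted parameters, a parametric bootstrap of the
fitted law.

`alpha_profile()` reports the local log-log slope in windows of 0.5
decades stepped every 0.1 decade. That window resolves the regimes seen in
crowded membranes — a dip to `alpha ~ 0.5` at 10–100 ns and recovery
toward 1 at microseconds — while averaging enough lag points per window to
be stable.

```{r diffusion-demo}
preset <- preset_registry("PM_s-POPE")
traj <- generate_diffusive_trajectory(preset, n_frames = 2048L, seed = 7)
traj <- remove_com_motion(traj)
msd <- compute_msd(traj, discard_initial = 50)
fit <- fit_anomalous(msd, fit_min = 1, fit_max = 500)
fit
```

## The synthetic generators

The generators are first-class, tested code: they define the conditions
under which every recovery claim holds.

**Diffusive trajectories.** Each species is a set of independent 2D
walkers whose increments are exact fractional Gaussian noise with Hurst
index `alpha/2`, synthesized by Davies–Harte circulant embedding — the
target autocovariance is met exactly in distribution, not approximately.
`alpha = 1` (white noise) and `alpha = 2` (frozen velocity) are
special-cased. The per-dimension step scale is `sqrt(2 D dt^alpha)`, so
the ensemble MSD equals `4 D dt^alpha` at every lag by construction.
Published diffusion coefficients are used as numeric values on the
nm²/ns^α scale (the printed unit in the source tables is dimensionally
irregular, so the numbers — 37 for PC lipids, 10 and 13 for POPE, 4, 1.1
and 0.4 for proteins — are treated as scale-free recovery targets).
Presets use 1000 particles for lipids, 500 for proteins, and 8192 frames
at 1 ns (16384 for the free-Brownian reference), sizes at which the
recovery spread of `D` is a few percent while a preset generates and fits
in well under two minutes on one core.

**Crowded adhesive disks.** A Metropolis-style scheme: Gaussian trial
steps, hard-core rejection, and rejection with probability
`adhesion_prob` of any move that would break a contact. It is a generator
of clustering phenomenology with tunable stickiness, not a force model;
its role is to produce coalescence-dominated dynamics (at
`adhesion_prob = 1` cluster sizes can only grow) for exercising the
cluster machinery on moving data.

**Undulating bilayers.** Per frame, independent Gaussian Fourier
amplitudes with `<|h_q|^2> = S(q) = A q^-p` (q = 0 excluded), inverse
transformed to a height field; phosphates are scattered uniformly in
plane, displaced by ± half the leaflet separation and per-particle
Gaussian z-noise. The generator and the analysis share one Fourier
convention (forward transform divided by the cell count), so target and
recovered spectra are directly comparable and the field variance equals
the spectral sum (Parseval).

What the generators deliberately do **not** emulate: correlated motion
within clusters, hydrodynamics, lipid chemistry, leaflet asymmetry
thermodynamics, protein–undulation coupling. Passing recovery tests
therefore demonstrates the correctness of the estimators, not the realism
of any particular membrane model.

## Surfaces, spectra and densities

The bilayer surface is built by projecting phosphate beads onto a 0.5 nm
grid and recording per-cell mean heights. Empty cells are filled by
iterative nearest-neighbour averaging (periodic) and flagged — a
deterministic, convention-free choice that is easy to audit, in contrast
to spline interpolation. The default spectral input is the midplane (mean
of the two leaflet fields), with per-leaflet and pooled fields available;
undulations are bilayer-collective, and the midplane also cancels
leaflet-antisymmetric noise.

Leaflet assignment bootstraps from the pooled per-cell mean height (a
midplane estimate valid at any undulation amplitude), then iterates:
grid each provisional leaflet, fill, and reassign each bead to the nearer
leaflet field. Assigning to the *nearer field* rather than by sign against
the midplane breaks the ties that occur in cells momentarily occupied by
one leaflet only. Two refinement passes on a 1 nm grid label better than
99% of beads correctly even when undulation amplitudes are twice the
leaflet separation.

The spectrum estimator mean-subtracts each field, takes the 2D FFT with
the forward transform divided by the number of cells, and radially
averages `|h_q|^2` into bins of width `2 pi / L` — one fundamental mode,
the natural resolution of a periodic box. With this normalization the
total spectral power equals the real-space variance exactly, per frame;
that identity is asserted in the tests at `1e-12`, and radial binning
conserves total power by construction. Bending-modulus estimation from
these spectra is deliberately out of scope.

`z_density_profile()` histograms bead heights over a frame window and
normalizes to unit integral (density per nm).

## Lateral RDF

`lateral_rdf()` computes a 2D radial distribution function: annulus
counts around each reference divided by the mean lateral target density,
minimum-image, averaged over references and frames, optionally restricted
to one leaflet. The 2D per-leaflet convention is chosen over 3D spherical
shells because headgroups and proteins are leaflet-confined, and a 3D
tool conflates the monolayers. The default reference is the protein
centroid (consistent with the cluster analysis); a bead-selection
reference is available since the centroid-versus-surface convention
differs between studies. No excluded-area correction is applied for the
protein footprint, so `g(r)` is biased low below the protein radius —
documented, and matching common practice.

## Pipeline and determinism

`run_pipeline()` executes generate/read → cluster → diffusion →
undulations → RDF → contacts from one validated config.
`validate_config()` injects the documented defaults (8.2 nm, 0.7 nm,
0.5 nm grid, 1000 bootstrap iterations, 1–2000 ns fit, 50 ns discard),
rejects unknown keys with a closest-match suggestion, and reports all
violations at once. Every random draw flows from the config seed, so a
rerun with an identical config is bitwise identical — including the JSON
summary, which embeds the package version and the normalized config
(minus the output directory, which is a location rather than a
parameter). A stage failure aborts with the stage name; outputs already
written are left in place.

## Numerical choices and limitations

* Exact-boundary contacts count (`distance <= cutoff`); cutoffs above
  half the smallest lateral box edge are rejected rather than silently
  mis-imaged.
* The anomalous fit requires at least 5 positive MSD points in range;
  non-positive values in range are a domain error rather than being
  dropped silently.
* The fGn embedding clips eigenvalues below zero at machine-precision
  magnitude only (the fGn circulant is nonnegative definite in theory).
* Test and validation problem sizes — 500–1000 walkers × 4096–16384
  frames for diffusion recovery, 100 frames of a 256² grid for spectral
  recovery, 100 cluster fixtures up to n = 144 — were chosen so each
  recovery statistic sits several standard errors inside its tolerance
  while a full validation run stays at desk scale.
* Known limitations: no velocity/force handling, no triclinic boxes, no
  cluster lifetime/merger tracking, no ergodicity-breaking statistics, no
  finite-size hydrodynamic corrections, no bending-modulus fit, and the
  GROMACS binary trajectory formats (XTC/TRR) are not read directly —
  convert to GRO frames or the internal container first.
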