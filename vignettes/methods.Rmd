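---
title: "Matching dynamic network representations to source-space brain responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching dynamic network representations to source-space brain responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrsa)
```

## The scientific problem

Automatic speech recognition networks and human listeners solve the same
problem — recovering word identities from sound — with very different
machinery. Representational similarity analysis (RSA) makes the two
comparable by abstracting both into representational dissimilarity matrices
(RDMs): square symmetric matrices whose entry (i, j) is the dissimilarity
(here Pearson's correlation distance, 1 − r) between the responses evoked by
stimulus words i and j. If a network layer and a patch of cortex carry
similar stimulus geometry, their RDMs are rank-correlated even though the
underlying response formats are incommensurable.

`ssrsa` implements this comparison as a pipeline:

1. **Model timelines.** Per-layer activation vectors on the standard
   25 ms / 10 ms speech frame grid become a *dynamic* RDM stream: one RDM
   per frame index, using only the frames available for every word (frames
   t with 10·t + 25 ≤ shortest duration; 27 frames for a 285 ms shortest
   word). Input-layer streams use the bare 40 log-mel filterbank values of
   the central window; hidden-layer inputs are reconstructed by delta
   augmentation (40 → 80) and 9-frame context stacking (80 → 720), giving a
   125 ms receptive field.
2. **Brain timelines.** Source-space recordings at 1 ms resolution are
   scanned with a spatiotemporal searchlight: a 20 mm patch of mesh
   vertices and a 25 ms window stepping by 10 ms through a [0, 540] ms
   epoch. Each (vertex, window) yields a condition-by-condition RDM from
   the concatenated patch × sample response vectors.
3. **Latency matching.** Cortical responses lag the stimulus, so the model
   RDM at stimulus time τ is compared (Spearman's ρ, mid-ranks) with the
   brain RDM at epoch time τ + k, for hypothesized processing latencies
   k = 0, 10, …, 250 ms. Averaging ρ over τ gives one value per
   (vertex, latency) per subject.
4. **Group inference.** Per-subject ρ-maps are combined with a one-sample
   t-test per cell, enhanced with threshold-free cluster enhancement
   (TFCE), and referred to map-maximum null distributions obtained by
   randomly flipping the sign of each subject's ρ-map (1,000 permutations
   at full scale; separate nulls per hemisphere; corrected threshold
   p < 0.01).
5. **Clustering evaluation.** Independently of the brain data, layer
   representational spaces are scored against phonetic and articulatory
   labellings (phone, place, manner, frontness, closeness) with the
   Davies–Bouldin index on segment-averaged activations, with a
   5,000-permutation label-shuffle null, and visualized with Sammon
   mapping.

## Key conventions and their rationale

**Frame reservation.** The reservation rule is the inequality
10·t + 25 ≤ D (shortest duration D), which yields exactly 27 usable frames
at D = 285 ms; the alternative strict-inequality reading would give 26 and
is rejected because it contradicts the printed frame count.

**Delta features.** "First-order differentials" is realized as the central
difference (o[t+1] − o[t−1])/2 with duplicated boundary frames. The
±1-frame support is the unique choice that makes a 9-frame stack span
125 ms of audio (9 frames cover 105 ms; one extra frame each side adds
20 ms).

**Searchlight geometry.** Patch membership is Euclidean distance in 3-D
vertex coordinates, restricted to the center's hemisphere; windows are
half-open [t, t + 25), i.e. 25 one-millisecond samples. Geodesic distance
would differ on highly folded cortex but is not needed for the synthetic
spherical meshes the package ships.

**Per-subject versus averaged RDMs.** Averaging searchlight RDMs across
subjects before correlation produces a single fixed-effects map with no
valid permutation test; the random-effects sign-flip scheme needs
per-subject ρ values. The package computes per-subject maps by default and
offers `averaged_rho_map()` as the descriptive alternative.

**t-statistic edge case.** If all subjects produce identical ρ at a cell,
the t statistic is ±100 with the sign of the mean (0 if the mean is 0),
flagged in an attribute. A literal ±Inf would make the TFCE threshold loop
unbounded; 100 exceeds any t attainable at realistic scales. This never
triggers with continuous noise.

**TFCE.** The discrete sum Σ (iΔh)²·e(iΔh) over i ≥ 1 with iΔh ≤ t is
evaluated literally, with Δh = 0.1 and no Riemann Δh factor: the missing
constant is a uniform monotone scale, so maxima, cluster shapes and
permutation p-values are unchanged. Enhancement is one-sided (negative t
maps to 0) because the hypothesis is positive correlation. Spatiotemporal
connectivity is mesh adjacency at equal latency plus same-vertex links
between consecutive latencies; no diagonal links. `isocontour_check()`
verifies order preservation along graph edges — a property the transform
satisfies exactly, and which implies local maxima cannot move. (The
stronger claim that the *global* argmax of every connected region is
preserved is false for TFCE in general: a narrow spike and a broad low
blob joined at a low threshold can trade places.)

**p-value conventions.** Both permutation tests use
p = (1 + #{null strictly more extreme}) / n_perm, clamped to 1, with ties
not counted as more extreme. With 5,000 label permutations and an observed
Davies–Bouldin index below every null this gives exactly p = 0.0002; with
1,000 sign flips and an observed TFCE value above every null maximum,
p = 0.001. Map-maximum nulls are collected per hemisphere, so family-wise
error is controlled *within* hemisphere — the whole-brain rate of any
suprathreshold cell is approximately 2α by construction, and the
calibration test accordingly counts hemisphere families.

**Davies–Bouldin.** Euclidean geometry throughout (centroids, scatters,
centroid distances); the "closest neighbouring cluster" is the
ratio-maximizing partner, the standard operative definition. Coincident
centroids and single-label inputs are errors rather than silent NaNs,
because NaNs would poison permutation nulls.

**Sammon mapping.** The embedding is delegated to `MASS::sammon`
(step-halving gradient descent on Sammon stress) from a seeded random
initial configuration, making results reproducible without privileging a
PCA direction.

## The synthetic world

All inputs can be generated with planted structure, so every downstream
stage is testable without recordings:

* **Mesh** — Fibonacci-spiral vertices on two spheres (default 160 per
  hemisphere, radius 50 mm, hemispheres 250 mm apart), adjacency from a
  symmetrized 6-nearest-neighbour graph with a connectivity repair pass.
  No convex-hull triangulation library is assumed; the neighbour graph
  provides the same connectivity role. Degree ≥ 3 and hemisphere
  separation are validated on construction.
* **Segments and activations** — each condition (default 40, shortest
  pinned at 285 ms, others drawn on a 5 ms grid up to 540 ms) is tiled
  with 40–120 ms phone segments from a 33-phone inventory. Frames take a
  label-specific centroid (unit random direction × `cluster_separation`)
  plus isotropic Gaussian noise; draws are arranged so that raising the
  separation at a fixed seed only rescales the same deviates, making
  cluster quality monotone in the separation. The shipped phone → feature
  table is a synthetic stand-in, not measured data.
* **Epochs** — Gaussian noise everywhere (the real noise structure of
  source estimates is unknown; independent Gaussian is a stated
  simplification), plus, at a 20 mm patch of "effect" vertices around a
  seeded left-hemisphere center, a shared signal starting at the planted
  latency (default 70 ms) whose 25 ms window slices realize the target
  model RDM stream, mixed as
  `effect_size · signal + (1 − effect_size) · noise`.

**Planted-signal construction.** Because consecutive windows overlap by
15 ms, windowed correlations cannot be prescribed independently. The
signal is built in 5 ms blocks (the gcd of window and step) whose rows are
zero-mean, so each window's Gram matrix is the *sum* of its blocks' Gram
matrices. Finding block Grams whose banded sums match the target
correlation matrices — up to a free multiple of the identity per window —
is a convex feasibility problem solved by alternating projections between
the affine constraint set and the PSD cone; each block is then realized
exactly from its Gram on an orthonormal zero-mean basis. The identity
slack shrinks all off-diagonal correlations of a window by one positive
factor, which leaves their rank order — all that Spearman matching sees —
untouched. Two small residuals remain: finite iterations (default 150),
and rank truncation when a block Gram's rank exceeds
(vertices × 5 ms − 1). At the default scales the realized slices correlate
with their targets at Spearman ρ ≈ 0.99, so the noise-free recovery tests
assert ρ ≥ 0.9 at the planted cell and exact argmax recovery rather than
ρ = 1; the attainable ceiling is reported by the `signal_residual`
attribute of the generated epochs.

**What a green test establishes.** The generator emulates the *geometry*
of the analysis (planted latency, planted location, planted cluster
structure, null symmetry) but not the physics of the measurement: no
forward-model point spread, no 1/f or phase-locked noise, no
inter-subject anatomical variability, no condition-correlated artifacts.
Passing tests certify that the pipeline recovers what it is pointed at and
that its error control is calibrated under its own null model — not that
real recordings satisfy that null model.

## Desk-scale defaults and budgets

The shipped testing world uses 40 conditions, 160 vertices per hemisphere,
6 subjects, effect size 0.8, unit noise, planted latency 70 ms, and 200
sign-flip permutations — small enough that the full acceptance suite runs
on one CPU in minutes, while keeping every constant of the full-scale
analysis (frame grid, searchlight geometry, latency grid, Δh, p-value
conventions) at its stated value. Permutation counts are the only scaled
constants; they enter only the resolution of p-values, not their
convention.

## A worked desk-scale run

```{r example, eval = FALSE}
config <- run_config(
  synth = synth_config(n_conditions = 40, n_subjects = 6, seed = 7),
  n_perm_signflip = 200)
res <- run_pipeline(config, "ssrsa-demo")

# where and when does the model explain the simulated cortex?
res$manifest$peak
#> $vertex
#> [1] 101
#> $latency_ms
#> [1] 70
#> $mean_rho
#> [1] 0.8589675
res$report$clusters
#>   cluster hemisphere n_cells peak_value peak_latency
#> 1       1          L       1 1832944715           70
```

The run recovers the planted effect: the group-mean map peaks at the
planted vertex and exactly the 70 ms planted latency, and inference marks
one left-hemisphere cluster there at corrected p = 0.005 (with 200
permutations and the default corrected threshold p < 0.01, only cells
above every null map maximum survive, so the cluster is the peak cell).
The `clustering_indices.tsv` artifact scores each layer × labelling
scheme with its Davies–Bouldin index and permutation p.

## Known limitations

* The Gaussian noise model and spherical meshes are stand-ins; effect
  sizes calibrated here do not transfer to real source estimates.
* The planted-signal ceiling (ρ ≈ 0.99, not 1) reflects window overlap
  and rank truncation, documented above.
* Only Pearson correlation distance RDMs and Spearman model-brain
  comparison are implemented; crossnobis/Mahalanobis distances and
  partial-correlation model competition are out of scope.
* `averaged_rho_map()` recomputes per-vertex streams compositionally and
  is quadratic-slow; it is meant for small descriptive checks.
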