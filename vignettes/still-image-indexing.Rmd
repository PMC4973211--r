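---
title: "Indexing still-shot diffraction images from inter-spot vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing still-shot diffraction images from inter-spot vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillindex)
```

## The problem

Serial crystallography (at XFELs and increasingly at synchrotrons) records
one still diffraction pattern per crystal: no rotation, no rocking curve,
often only a few dozen Bragg spots. Classical indexing methods that detect
the lattice repeat by Fourier analysis of the full reciprocal-space point
set need the three-dimensional sampling that rotation provides; on sparse
stills they struggle, and every unindexed hit is wasted sample and beam
time.

When the unit cell and space group are already known — the usual situation
in a serial experiment — far weaker information suffices. This package
determines per-image crystal orientation matrices from the *difference
vectors between spots*:

1. Each centroid is back-projected onto the Ewald sphere, giving a
   reciprocal-space coordinate ("observed space").
2. All inter-spot difference vectors up to a length `d_max` are computed.
   A difference vector between two spots of the same lattice equals, up to
   rotation and noise, an inter-reflection vector of the known lattice
   ("theoretical space"), so each observed vector is matched by length to
   the table of allowed lattice vectors.
3. Two matched vectors that are not collinear fix an orientation: the
   rotation aligning the observed pair onto its theoretical assignment is
   constructed in closed form (two successive axis–angle rotations), and
   its transpose is the crystal-setting matrix **U** in the Busing–Levy
   factorisation **R** = **U**·**B**.
4. Candidate orientations from many pairs are reconciled either by
   clustering (the solution with the most neighbours within an 8°
   radius wins) or by growing a *network* of vectors that all agree with
   one orientation; a network bigger than a threshold (default 20) is an
   indexing solution.

Orientation similarity is always judged by the symmetry-aware metric

$$ \Delta(P, Q) = \min_s \lVert P - Q\,O_s \rVert_F , $$

the minimum over point-group rotations $O_s$ of the Frobenius norm of the
matrix difference. For a pure relative rotation by $\theta$ this equals
$2\sqrt2\,\sin(\theta/2)$, so the duplicate threshold 0.25 corresponds to
10°, and angular radii (1° pair screen, 8° admission) are converted with
`angle_threshold_to_metric()`.

## Allowed difference vectors and centring

Lattice centring forbids entire classes of reflections, and therefore of
difference vectors: an I-centred lattice only ever produces inter-spot
vectors with $h+k+l$ even, an F-centred one only all-even/all-odd triples.
`enumerate_theoretical_vectors()` applies centring rules only — axial
(screw-axis) absences affect single axial reflections but not general
difference vectors, so they are deliberately ignored. Both $\pm$dhkl are
stored as separate candidates, which removes all sign bookkeeping from the
orientation construction at the cost of a factor two in table size.

A subtlety specific to difference-vector indexing: spot *positions* are
invariant under the rotation group of the *lattice*, which can be larger
than the crystal's point group. For point group 23 on a cubic lattice the
lattice admits 432, so every solution has a twin (rotated 90° about a cube
axis) that predicts identical spot positions and can only be told apart
with intensities. Internally, duplicate rejection and solution evaluation
therefore use the lattice rotation group
(`rotational_symmetry_ops(..., lattice = TRUE)`); user-facing symmetry
(e.g. the six images of the (1,0,0) axis under I23) uses the crystal point
group.

## Tolerances

Two spots of finite-size reciprocal-lattice points, sitting on opposite
extremes of the nest of Ewald spheres spanned by the bandwidth, can differ
in apparent separation by up to

$$ \mathrm{tol}(d) = 2\,r_\mathrm{rlp} + d\,\frac{\Delta\lambda}{\lambda}, $$

which is the "variable" tolerance model; a constant tolerance (default
$5\times10^{-4}\,\mathrm{Å}^{-1}$, a typical value for real experiments)
is the default. The same tolerance is used for observed-to-theory length
matching and for the neighbour predicate of the optional pre-filter.

Key parameters, with defaults chosen for the bundled cubic toy experiment
(106.1 Å I23 cell, λ = 1.46 Å, 0.11 mm pixels, 101.2 mm detector
distance):

| parameter | default | meaning |
|---|---|---|
| `d_max` | 0.08 Å⁻¹ (toy), up to 0.19 Å⁻¹ for real cubic data | longest inter-spot vector used |
| `pair_angle_tol` | 1° | observed vs theoretical inter-vector angle agreement |
| `neighbour_radius` | 8° | cluster neighbourhood / network admission radius |
| `network_threshold` | 20 | minimum network size accepted as a solution |
| `duplicate_metric_threshold` | 0.25 (≈10°) | symmetry-duplicate rejection |
| `sigma_t` | 0.08 Å | acceptance limit on the Ewald-wavelength spread |
| `accept_d_min` | 0.1 Å⁻¹ | low-resolution cut for the acceptance statistic |

`d_max` trades information against ambiguity: longer vectors have
proportionately smaller angular errors, but at long lengths the allowed
lengths crowd within the tolerance and each observed vector acquires many
candidate assignments. For a 106.1 Å cubic cell, 0.08 Å⁻¹ keeps the
assignment lists short while leaving hundreds of usable vectors per image.

## Acceptance of a solution

Every reciprocal point of a candidate orientation lies on an Ewald sphere
of *some* wavelength, $\lambda_i = -2 q_z / |q|^2$ in the beam-along-z
frame. For a correct orientation the modelled positions of the observed
spots back-compute to wavelengths tightly grouped around the beam value;
for a wrong orientation they scatter. A solution is accepted when the
standard deviation of these per-spot wavelengths is at most `sigma_t`, or
when the wavelength histogram has a peak of at least `min_peak` counts.

Two numerical caveats shape the implementation. First, the inferred sphere
radius degrades as $1/\sin^2\theta$ at low scattering angle, so spots
below `accept_d_min` are excluded. Second, on multi-lattice images the
spots of *other* lattices would dominate the statistic; spots whose
nearest modelled reciprocal point is farther than `accept_assign_tol`
($10^{-3}\,\mathrm{Å}^{-1}$) are treated as not assigned to this lattice.
`sigma_t = 0.08` Å was calibrated on the synthetic toy: correct
orientations score below 0.05 Å even at 0.3 px centroid jitter, wrong
ones above 0.11 Å.

Additional lattices are found by predicting all spots of an accepted
solution, deleting observed spots within 2 px of a prediction, and
re-indexing the remainder; solutions equivalent (under the lattice group)
to an earlier one are rejected.

## The synthetic still-image generator

`simulate_image()` fabricates stills with exact ground truth. A uniform
random orientation (quaternion method) is drawn per lattice; every
centring-allowed reflection whose reciprocal point lies within
$r_\mathrm{rlp} + (\Delta\lambda/2\lambda)$ of the nominal Ewald sphere
(euclidean distance to the sphere surface — the standard partiality
picture of a finite rlp intersecting the nest of spheres) is projected to
the detector with the *same* forward model the spot predictor uses, so
prediction round-trips simulation exactly. Centroids are jittered by an
isotropic Gaussian (default σ = 0.3 px), uniform false-positive spots are
appended (default 16, about 10%), and the list is shuffled. Each image's
random stream is derived from (master seed, image index), so any image is
reproducible in isolation.

With the toy defaults this yields 140–180 reflections per image to 2.9 Å
at the panel edge — the sparse-still regime the method is designed for.

What the generator does *not* emulate: intensities and partiality profiles
(indexing uses positions only), detector point spread, multi-panel
metrology, mosaic-block substructure, and non-uniform noise (false
positives from a real spot finder cluster near powder rings and panel
edges). Passing tests therefore demonstrate correctness of the geometry,
matching and search machinery under realistic positional noise, not
performance on any particular real detector.

## Numerical and design choices

* **Alignment of the second vector**: the rotation angle β about the first
  theoretical vector is obtained in closed form as the signed angle
  between the projections of the rotated observed vector and its target
  onto the plane perpendicular to the axis, rather than by iterative
  minimisation. Exactly antiparallel first vectors use a deterministic
  perpendicular axis.
* **Degenerate pairs**: observed pairs within 10° of (anti)parallel are
  excluded; they determine the orientation too poorly.
* **Seed order**: network growth starts from vectors with the fewest
  theoretical assignments first (most length-specific), longest first
  within ties, since long vectors carry proportionately lower error.
* **Network growth** is implemented as repeated passes over the pool with
  an explicit membership set — equivalent to depth-first recursion but
  with bounded stack depth and a fixed, deterministic iteration order.
  Identical inputs always produce identical solution lists.
* **Work caps**: the matched pool is truncated deterministically (default
  400 vectors; when the multi-lattice pre-filter is on, vectors are kept
  in neighbour-score order, which concentrates the pool on intra-lattice
  vectors), and the number of seeds and assignment combinations tried per
  image is bounded. The caps are parameters, not hidden constants.
* **Pre-filter behaviour**: the neighbour-score filter retains the top
  $1/n$ fraction of vectors (inclusive of ties) for $n$ expected lattices,
  with $n = \mathrm{round}(s/l)$ from the spot count. Scores are only
  informative when repeated difference vectors actually repeat — on very
  sparse images most scores are zero and the filter (correctly)
  removes nothing; it earns its keep on dense, multi-lattice images.
* **Histogram conventions**: pseudo-powder bins are 2×10⁻⁴ Å⁻¹ wide;
  theoretical lengths are collated within 10⁻⁶ Å⁻¹; the powder fit score
  is the fraction of observed vector mass within a tolerance of any
  theoretical length — monotone, cheap, and sufficient to recover a 20 mm
  detector-distance error to ±1 mm from four images in the bundled tests.

## Problem sizes used in the test-suite

The validation suite runs entirely on the cubic toy: 100 single-lattice
images for the recovery-rate check (≥90% required), 50 three-lattice
images for multi-lattice recovery (≥80% of orientations, no duplicate
solutions), 4 images for the detector-distance scan, and 8 images × 5
distance offsets for the robustness profile. These sizes keep the full
suite under a few minutes on one core while holding the statistical
margins comfortably away from their thresholds.

## Known limitations

* Single flat panel orthogonal to the beam; no tilt or multi-panel
  metrology.
* Space-group knowledge is a small built-in table (P1, P212121, I23, F23,
  P6122) plus a generic centring-and-generators entry; no Hall-symbol
  machinery.
* The acceptance stage is a screen, not a refinement: accepted
  orientations are good to a degree or so and would normally be passed to
  a downstream orientation-matrix refinement before integration.
* Unit-cell parameters are priors, never refined here.

## A worked session

```{r example, eval = FALSE}
priors <- crystal_priors(unit_cell(106.1), "I23", d_max = 0.08)
spec <- simulation_spec(seed = 1)
sim <- simulate_image(spec, 1, priors)
params <- indexing_params(method = "network", d_max = 0.08)
sols <- network_index(sim$image, params, priors)
evaluate_solutions(sim$truth, sols, priors$lattice_ops)
```
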