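---
title: "Methods: shape descriptors, pocket scoring, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape descriptors, pocket scoring, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the mathematical model implemented by `zpocket`,
every tunable parameter with its unit and default, the numerical choices
made along the way and why, and the scope and limitations of the synthetic
benchmark. The code chunks are illustrative and not evaluated at build time;
the same computations run in the test suite and in `scripts/acceptance.R`.

## 1. The shape model

### 1.1 3D Zernike basis

A bounded shape is represented as a density `f(x)` supported on the unit
ball and expanded in the 3D Zernike basis

$$Z_{nlm}(r,\theta,\varphi) = R_{nl}(r)\, Y_{lm}(\theta,\varphi),$$

with integer indices $0 \le l \le n$, $n - l$ even, $|m| \le l$. The radial
factor is

$$R_{nl}(r) = \sqrt{2n+3}\; r^{l}\; P_s^{(0,\, l+1/2)}(2r^2 - 1),
  \qquad s = (n-l)/2,$$

a shifted Jacobi polynomial; with the $\sqrt{2n+3}$ prefactor the family is
orthonormal under the $r^2$ weight, $\int_0^1 R_{nl} R_{n'l}\, r^2 dr =
\delta_{nn'}$. `zernike_radial_coefficients()` expands this into explicit
monomial coefficients of $r^{n-2k}$; `radial_polynomial()` evaluates the
monomial form and an independent three-term-recurrence path
(`radial_jacobi`, used by the oracles) cross-checks it. The angular factor
$Y_{lm}$ is the orthonormal complex spherical harmonic with the
Condon–Shortley phase (built on `pracma::legendre`, which follows that
convention).

Moments and invariants:

$$C_{nlm} = \int f\,\overline{Z_{nlm}}\,dV, \qquad
  D_{nl} = \Big(\sum_{m=-l}^{l} |C_{nlm}|^2\Big)^{1/2}.$$

$D_{nl}$ is invariant under rotations because a rotation mixes the $C_{nlm}$
within fixed $(n,l)$ by a unitary Wigner matrix. For a real field the
moments obey $C_{nl,-m} = (-1)^m \overline{C_{nlm}}$ (tested). At the
default order $N = 10$ there are exactly 36 $(n,l)$ pairs.

Two oracles guard the basis:

* **Orthonormality** (`zernike_gram()`): Gram matrix of all basis functions
  up to order 10 by an exact separable product quadrature — Gauss–Legendre
  in $r$ and $\cos\theta$, uniform midpoints in $\varphi$. The integrands
  are polynomials in the quadrature variables, so the rule is exact up to
  rounding; the measured deviation from the identity is ~1e-13. A Cartesian
  Riemann sum over a $64^3$ lattice could not certify 1e-6 (its own
  discretization error dominates), which is why the oracle uses quadrature
  while moment computation itself stays on the lattice.
* **Naive equivalence** (`compute_moments_naive()`): a literal triple-loop
  Riemann sum over voxel centers, with the radial part evaluated by the
  independent recurrence route. It agrees with the vectorized
  `compute_moments()` to ~1e-15 (acceptance bound 1e-10).

### 1.2 Voxelization

`voxelize()` centers the points on their centroid, scales the farthest
point to radius `fill_fraction` (default **0.7**, leaving headroom against
truncation at the ball boundary), and deposits them on an `L³` lattice over
$[-1,1]^3$ (default `grid_side = 64` for whole surfaces, 32 in the patch
pipeline).

**Deposition is trilinear by default, not binary.** Classic binary-shell
occupancy (every voxel containing a point is set to 1) makes the voxelized
mass depend on the orientation of the surface relative to the lattice: a
plane cutting voxels diagonally occupies more of them than an axis-aligned
one. Measured on this code, binary-shell descriptors deviated by 1.8–5.7%
of descriptor magnitude under random rotations at $64^3$ — and the
deviation *grows* with sampling density — which breaks the 2%
rotation-invariance property the descriptors exist to provide. The default
is therefore a mass-preserving trilinear splat: each point spreads unit
mass over the 8 surrounding voxel centers, and the field is normalized to
unit integral so descriptors are independent of point count and grid
resolution. Rotational deviation drops to ≤ 0.04%. This was decided from
the invariance measurements before the acceptance tests were frozen;
`deposition = "binary"` is retained as an option and is exercised by the
contract tests. `mode = "solid"` additionally flood-fills the interior
(used for ligand blobs when only a shell cloud is available).

## 2. Surfaces, sites, and patches

* `build_surface()` approximates a solvent-excluded surface: each atom is
  inflated by the probe radius (default **1.4 Å**), candidate points are
  placed on a Fibonacci lattice (density default **3 points/Å²** of
  inflated sphere), points inside any other inflated sphere are removed,
  and survivors are retracted to the generating atom's van der Waals
  radius. Per-atom local frames are built equivariantly from the geometry
  (centroid and nearest-neighbor directions), so rebuilding after a
  rotation rotates the point set instead of re-sampling it; a seeded twist
  angle keeps the construction deterministic without touching the caller's
  RNG. `read_dms()` imports DMS-dialect surface files instead.
* `define_binding_site()`: residues whose Cα lies **strictly** within
  `cutoff` (default **6 Å**) of any ligand atom.
* `residue_centered_set()`: all residues with Cα strictly within `radius`
  (default **9 Å**) of a center residue's Cα.
* `generate_decoys()`: for each probe radius R ∈ {6, …, 20} Å (1 Å steps)
  it sizes residue-centered sets at every candidate center and picks the
  R* whose mean size is closest to the true site's size (ties to the
  smaller radius). Centers on binding-site residues are excluded; when a
  surface cloud is supplied, only surface-exposed residues (≥ 1 surface
  point) are candidates, since buried centers would give empty patches.

## 3. Complementarity scoring

* `manhattan_distance()`: $d(P, L) = \sum_{nl} |D_{nl}(P) - D_{nl}(L)|$.
* `zscore_table()`: per-complex standardization
  $Z_i = (x_i - \mu)/\sigma$ with the **population** standard deviation;
  mean 0 and sd 1 hold to machine precision by construction (tested to
  1e-9).
* `association_threshold()`: lower type-1 empirical quantile (default 5%)
  of a background distance distribution, no interpolation;
  `call_association()` is strict-below-threshold, with an optional
  per-residue quality gate (mean patch quality must not exceed the supplied
  first-quartile bound).
* Model-vs-experiment similarity: $S_s$ is the mean distance over
  corresponding patch pairs, $S_{ns}$ the mean over all *ordered*
  non-corresponding pairs (the two orders differ in general, hence
  $N(N-1)$ pairs), and the sensitivity $S_Z = S_{ns} - S_s$ exactly.

## 4. The synthetic benchmark

### 4.1 Generator

`make_toy_complex()` emulates a liganded structure at desk scale, with
single-atom (Cα-only) residues:

1. pack `n_residues` (default **280**) Cα centers into a ball of radius
   `protein_radius` (default **10.5 Å**) with a greedy 2.6 Å minimum
   spacing; residue names are drawn from natural amino-acid abundances;
2. place a ligand blob (≥ 12 carbon atoms in a ball chosen so the ligand's
   solvent surface has radius ≈ `ligand_radius`, default **3 Å**) at a
   center distance controlled by the `complementarity` dial `c`:
   `c = 1` buries the ligand to `pocket_depth` (default **2 Å**) below the
   protein surface, `c = 0` detaches it entirely (and no ground truth is
   recorded);
3. carve: remove every protein atom within (vdW + probe + `contact_gap`)
   of any ligand atom (default gap **0.5 Å**), producing a pocket whose
   wall is shaped by the ligand;
4. optionally add Gaussian coordinate noise (`noise_sd`, Å), then record
   the ground-truth site by the 6 Å rule.

The generator is a deterministic function of its spec, and every parameter
above is a package choice, not a measured corpus quantity.

An earlier prototype placed residues on a hollow jittered shell with
multi-atom radial chains. That design failed structurally: the carve step
removed the Cα of every pocket-wall residue (leaving a ring-shaped
"binding site" with no wall residues), and the large interior cavity
surface contaminated every patch descriptor. The solid-ball redesign keeps
the carve-and-fill contract, the complementarity dial, and the
ground-truth recording, while making the pocket wall Cα-bearing.

### 4.2 What the benchmark shows — and a caveat on patch size

Under the study condition (complementarity 1.0, noise 0.3 Å, 50 seeded
complexes, ~8 size-matched decoys each) the pooled BS-vs-decoy ROC gives
AUC ≈ 0.86 and the BS z-score is negative in 94% of complexes (means across
master seeds 1/5/42: AUC 0.86/0.82/0.81). The mean ligand–BS distance
decreases strictly monotonically in the complementarity dial (4 levels × 20
seeds).

One intuitive-sounding claim is deliberately **not** asserted: "at full
complementarity and zero noise, the BS patch has the minimum descriptor
distance among *all* residue-centered patches". It is false in this
implementation, and instructively so: 9 Å residue-centered patches are
systematically larger than the 6 Å-rule binding site, and since each patch
is scaled independently into the unit ball before description, patch
*size* confounds raw descriptor distance — larger wraps tend to sit closer
to the ligand descriptor regardless of pocket shape. This is precisely why
decoys are size-matched at all. The properties that do hold, and are
tested, are: (a) the BS beats size-matched decoys (the benchmark above),
and (b) descriptor distance to the ligand correlates with a patch center's
proximity to the ligand across residue-centered patches (Spearman ≈ 0.4–0.6
per complex).

## 5. Known limitations

* **Size-blindness of the scaling step.** Every patch is independently
  translated and scaled into the unit ball, so absolute patch size is
  invisible to the descriptor; comparisons are only meaningful between
  similarly sized regions (hence size-matched decoys).
* The internal surface builder is an SES approximation (no reentrant
  probe surface); for production geometry, import DMS output.
* Cα-only toy residues are a deliberate simplification; the benchmark
  numbers characterize the method on this generator, not on any real
  corpus.
* Descriptor resolution is bounded by the lattice: order 10 on $32^3$
  patch grids is the tested regime; orders above 20 trigger a warning
  because high-frequency radial polynomials are no longer resolved.
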