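---
title: "Learned density functionals and delta-corrected energy surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned density functionals and delta-corrected energy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densfunc)
```

## The model and its assumptions

`densfunc` learns molecular energy surfaces through the electron
density rather than directly from nuclear coordinates. The pipeline
has three stages.

**Descriptor.** The external nuclear potential is smeared into a sum
of atom-centered Gaussians of width $\gamma$, scaled by the per-atom
charge, and evaluated on a cubic grid. Charges default to valence
electron counts (H = 1, C = 4, O = 6), consistent with learning
valence densities under a frozen-core convention; full nuclear charges
are available via `full_z = TRUE`. Descriptors of different conformers
are comparable only on a shared, molecule-centered grid, so a dataset
fixes one grid on its aligned reference frame; conformer ensembles can
be brought into that frame with `align_to_reference()` (Kabsch
superposition on a chosen atom subset, typically the carbon skeleton).

**Density map.** The valence density is expanded in a real
trigonometric (Fourier) basis, orthonormal on the box, and one kernel
ridge regression per coefficient maps the potential descriptor to the
coefficient vector $\mathbf u$. Because the basis is orthonormal the
coefficient regressions are independent, and because they share the
training descriptors a single Cholesky factorization of the
regularized Gram matrix solves all of them at once
(`fit_hk_map()`). The expansion is grid-independent on the way out:
`reconstruct_density()` evaluates the continuous density anywhere in
the box, and `integrate_density()` reads the electron count off the
constant coefficient exactly.

**Energy maps.** A second Gaussian-kernel regression maps
$\mathbf u$ to an energy. Three label kinds are supported: the
low-level (DFT-like) energy, the high-level (coupled-cluster-like)
energy, and their difference. The difference ("delta") map always uses
a zero prior mean, so far from the training manifold the learned
correction decays to zero and the corrected total
$E_{\mathrm{low}} + \Delta E_{\mathrm{ML}}[\mathbf u]$ falls back on
the plain low-level result; direct maps use a train-mean prior so that
they revert to the dataset mean rather than to zero. Energy maps can
be trained on coefficients projected from reference densities or on
coefficients predicted by the density map; both routes are first-class
and differ negligibly when the density map is accurate.

The assumptions worth keeping in mind: energies must be smooth
functions of the density coefficients at the kernel's length scale;
the box must enclose every conformer with margin of at least
$3\gamma$ (and enough clearance for the density tails); and a model is
only as good as the region of configuration space its training set
covers — the zero-prior fallback makes failures graceful, not absent.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `gamma` | 0.6 | Å | Descriptor Gaussian width. In production use it is cross-validated jointly with the grid spacing and kernel width; 0.6 Å is a sensible center for the molecules bundled here. |
| `points_per_dim` | box/0.4 | — | Grid spacing of 0.4 Å resolves the bundled density widths (0.40–0.50 Å); finer grids change results below test tolerances. |
| `per_dim` | 7 (toy), 25 (reference) | — | 1D basis functions per axis, odd. The classic choice for production densities is 25 per dimension; the toy pipeline uses 7 with a total-frequency cutoff. |
| `mode` | `"tensor"` | — | `"tensor"` keeps all `per_dim`^3 products; `"ball"` applies a total-frequency cutoff to shrink the coefficient budget. A full tensor product at 25 per dimension has 15,625 functions, which is larger than the 12,500 sometimes quoted for 25-per-dimension bases; since the truncation behind such budgets is not standardized, both modes are provided and nothing in between is guessed. |
| `sigma` | CV | input distance | Kernel width; `fit_energy_map_cv()` searches a geometric grid, factors 1/8–8 around the median pairwise distance, by fivefold CV. |
| `lambda` | 1e-10 | — | Ridge term. Since k(x,x)=1, 1e-10 equals the scale-free jitter 1e-10·tr(K)/M and preserves near-interpolation. CV may select 1e-7 or 1e-4. |
| `dt` | 0.5 | fs | Integrator timestep. |
| `temperature` | 350 | K | Langevin target. |
| `friction` | 0.413 | fs⁻¹ | Langevin friction, equal to 0.01 atomic units. |
| `fd_epsilon` | 0.001 | Å | Central-difference displacement; force error is O(ε²). |
| `n_inner` | 3 | — | Inner (reference-force) steps per outer force correction in the RESPA integrator. |

## What the surrogate systems emulate

The generator replaces external electronic-structure codes with
analytic stand-ins so the full pipeline can be exercised with known
ground truth:

* **Two deterministic surfaces.** The low-level surface is a sum of
  harmonic bond and bend terms plus periodic torsion terms, zero at
  the template geometry by construction (the template's torsions sit
  at numerically located 1D minima, so it is a stationary point to
  machine precision). The high-level surface adds a smooth correction:
  on tagged bonds an odd, bounded function
  $a\tanh(d/w)\exp(-(d/2w)^2)$ of the displacement $d$ — compressed
  bonds destabilized, stretched bonds overstabilized — and on tagged
  torsions smooth periodic tilts that can reorder conformer minima
  between the levels. Labels carry no stochastic noise: like real
  electronic-structure labels they are deterministic functions of
  geometry.
* **Calibration.** Amplitudes are calibrated so the water ensemble
  reproduces the error regime of a semilocal functional against
  coupled cluster: mean unsigned difference ≈ 2.3–2.6 kcal/mol with
  extremes around 7–8, on an ensemble of random geometries whose
  low-level energies span on the order of 100 kcal/mol. With the
  correction length scale 0.8 Å the difference surface is nearly
  linear over the sampled range, with far smaller total variation than
  the total surface — this is precisely the regime in which the delta
  route pays off, and the package's delta-vs-direct comparison
  reproduces the expected ordering (a delta map trained on 10 samples
  beats a direct high-level map trained on 50) robustly across seeds.
* **Densities.** The "self-consistent-like" density (`bonded_density`)
  is a superposition of smooth molecular-width atomic Gaussians plus
  bond-midpoint Gaussians whose amplitude decreases smoothly with bond
  stretch, renormalized to the valence electron count — a density
  whose shape, not just position, follows the geometry. The cheap SAD
  variant (`sad_density`) uses the sharper isolated-atom peak widths
  (≈ 0.55× the molecular widths), which the shared default grid
  under-resolves slightly, exactly as cusped atomic densities are
  under-resolved by grids tuned for smooth pseudo-densities. This is
  what makes SAD-trained maps measurably worse than bond-aware-trained
  maps here — a signal-to-noise degradation of the representation, not
  label noise.
* **Conformer sampling.** `sample_conformers()` applies seeded
  Gaussian displacements to the Z-matrix internals; torsions
  registered as multi-well draw their center uniformly among the well
  positions first, so ensembles of multi-minimum systems cover all
  basins the way finite-temperature MD harvests do. Sampled energy
  distributions are positively skewed, as soft-mode ensembles are.
* **The three systems.** `toy_water()` (3 atoms, mirror symmetry,
  the delta-learning benchmark), `toy_ethanol()` (9 atoms; hydroxyl
  torsion with gauche/anti minima whose global ordering differs
  between the levels by ≈ 0.4–0.75 kcal/mol — the same phenomenon as
  MP2/PBE and CCSD(T) disagreeing about ethanol's global minimum),
  and `toy_ring()` in three variants: a benzenediol-like C2v molecule
  whose four planar hydroxyl-rotamer minima map onto one another under
  the order-4 skeleton group (the 1004 → 4004 bookkeeping), a
  phenol-like Cs fragment sharing the ring and hydroxyl coordinates,
  and a benzene-like D6h ring with a point group of order 24
  (1000 → 24,000 augmentation).

What passing tests on these surrogates do **not** show: that the
method reaches any particular accuracy on real molecules. Real
densities have cusps, shell structure and charge transfer that the
Gaussian surrogates lack; real DFT-vs-CC differences are not exactly
low-dimensional functions of a few internal coordinates; and real
label pipelines add basis-set and convergence noise. The surrogates
validate the machinery and the qualitative economics (delta beats
direct at small training budgets; accurate density inputs beat crude
ones; combined fragment data improves large-molecule maps), not
absolute chemical accuracy.

## Numerical choices

* **Quadrature.** Projections use the plain voxel Riemann sum on the
  uniform grid, which on a periodic box is exact for band-limited
  integrands; the grid must satisfy the Nyquist bound (max 1D
  frequency below half the points per dimension), and violations are
  errors, not warnings. Basis functions are ordered by total
  frequency, then lexicographically by 1D index — a deterministic
  ordering that serialization and tests rely on.
* **Linear algebra.** All KRR systems are solved by Cholesky
  factorization of $K+\lambda I$; a singular system (duplicate inputs
  at $\lambda=0$) is reported with the advice to set $\lambda>0$. The
  potential-to-density map factorizes once and back-solves all
  coefficient columns.
* **Cross-validation.** Folds are a seeded shuffle followed by
  contiguous blocks whose sizes differ by at most one; given the seed,
  results are reproducible bit for bit. All randomized operations
  (fold shuffles, k-means seeding, conformer sampling, Langevin noise)
  take explicit seeds and restore the caller's RNG state.
* **k-means selection.** Seeded k-means++ initialization, Lloyd
  iterations capped at 300, then the nearest dataset member per
  center; duplicate picks fall through to the next-nearest member and
  distance ties break toward the lowest index.
* **Symmetry detection.** Candidate operations are enumerated from
  pairs of reference atoms (any symmetry must map a non-collinear
  atom pair onto a compatible pair, and each image pair fixes one
  proper and one improper transform); surviving transforms are
  deduplicated and checked for group closure. Supported for rigid
  point groups up to 64 atoms; linear molecules (continuous axes) are
  rejected, and explicit operation lists can be supplied instead.
  Duplicate-geometry removal during augmentation compares
  species-matched point sets after centroid removal at 1e-4 Å, using
  sorted-coordinate signatures as a prefilter; duplicates with energy
  labels disagreeing beyond 1e-9 kcal/mol are an error.
* **Integrators.** NVE is velocity Verlet; the thermostat is BAOAB
  Langevin splitting (chosen for its configurational accuracy at
  0.5 fs; with zero friction it reduces exactly to velocity Verlet);
  the multiple-time-step integrator is impulse RESPA with symmetric
  half-kicks of the accurate-minus-reference force difference at
  outer boundaries, time-reversible by construction. Forces default
  to central finite differences (cost 6N energy calls); exact for
  quadratics, O(ε²) otherwise. Momentum is conserved to rounding on
  pair-potential surfaces, but only to O(ε²) per step when three-body
  (angle) terms are differentiated numerically — an inherent property
  of finite-difference forces worth knowing when monitoring drift.
* **Geometry optimization on learned surfaces.** BFGS on
  finite-difference gradients, declared converged at
  max|F| < `force_tol`. Kernel models extrapolate arbitrarily outside
  their training manifold, and an unconstrained descent will find and
  exploit such regions; `displacement_bound` switches to L-BFGS-B
  with a box around the start and is strongly recommended on learned
  surfaces. The bundled conformer-discrimination analysis optimizes
  each basin within a 0.15 Å box, which is ample for the sub-0.1 Å
  relaxations involved while keeping the search inside the model's
  validity region.

## Design decisions on genuinely open points

* **Internal units** are Å, kcal/mol, fs, amu throughout; bohr appears
  only in cube-file headers and atomic-unit friction only in the
  conversion helper. One constant table, covered by a unit test.
* **Energy references.** Dataset labels are stored relative to the
  lowest low-level energy in the set (the shift is retained for
  round-tripping); differences are shift-invariant.
* **Kernel distance over coefficients** is the plain Euclidean norm:
  with an orthonormal basis this is the L² distance between the
  band-limited densities, which is the natural functional-space
  metric. Descriptor distance over potentials is likewise unweighted,
  with voxel-volume factors absorbed into the cross-validated kernel
  width.
* **Evaluation protocol.** The repeated-shuffle protocol (40 shuffles
  by default, 50-sample training pools, k-means-selected subsets,
  out-of-sample remainder as test) is the stable way to estimate
  accuracy on ~100-sample datasets; `shuffle_evaluate()` implements it
  directly.
* **Model selection for gradient-driven use.** Fivefold CV selects
  the test-MAE-optimal kernel width, which on smooth targets can be
  very wide with enormous dual coefficients — accurate on the data
  manifold, wild off it. Surfaces meant for optimization or MD are
  therefore fit at the median-distance width with explicit
  regularization (the conformer-discrimination analysis uses
  λ = 1e-4), trading a little test MAE for bounded off-manifold
  behaviour.
* **Archives** use R's native serialization (`save_archive()` /
  `load_archive()`), storing models with their full hyperparameter
  provenance.

## Problem sizes

The bundled analyses are sized for interactive use on one CPU: 23³–34³
grids, 63-coefficient ball-truncated bases, 102-sample water datasets,
500-sample (mirror-doubled to 1000) ethanol datasets, 10⁴-step drift
runs, 10⁵-step thermostat runs, and 200-step trajectory comparisons.
Production-scale settings (125³ grids, 25-per-dimension bases,
1000-conformer training sets with 24-fold symmetry augmentation) use
the same code paths; only the constants change.

## Known limitations

Single rigid molecules in the gas phase only: no periodic systems, no
Ewald sums, no space groups, and no continuous symmetry axes. The
surrogate force fields are not chemically accurate force fields — they
exist to give the pipeline deterministic ground truth, not to model
real water or ethanol. Finite-difference forces cost 6N energy
evaluations per step, which is the honest price of a force-free
training set; analytic kernel gradients would be an optimization, not
a semantic change. Point-group detection assumes a rigid reference
geometry and will return only the identity for thermally distorted
conformers — detect on the template (or skeleton), then apply the
operations to the ensemble.
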