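# densfunc

Density-based kernel learning of coupled-cluster quality energy
surfaces for small gas-phase molecules.

Kohn–Sham density functional theory (DFT) with a semilocal functional
is cheap but typically 2–3 kcal/mol from the truth; coupled cluster
(CCSD(T)) is the gold standard but far too expensive for molecular
dynamics or geometry optimization. `densfunc` implements the machine
learning bridge between the two levels for users who can afford a few
dozen high-level single points but need thousands of high-level-quality
energies: computational chemists running gas-phase MD, conformer
searches, or benchmark studies on single molecules and small families
of related molecules.

## The model

The molecule's nuclear potential is represented by a sum of Gaussians
evaluated on a cubic grid,

    v(r) = sum_a Z_a exp(-||r - R_a||^2 / (2 gamma^2)),

and a kernel ridge regression (KRR) model — one independent regression
per coefficient, sharing a single Gram matrix — maps this descriptor to
the expansion coefficients **u** of the valence electron density in an
orthonormal Fourier basis,

    n[v](r) = sum_l u_l[v] phi_l(r),      u_l[v] = sum_i beta_i^(l) k[v, v_i],

a learned realization of the Hohenberg–Kohn potential-to-density
correspondence. A second KRR model with a Gaussian kernel maps the
coefficients to an energy,

    E_ML[n] = sum_i alpha_i k(u, u_i),

trained on low-level labels, high-level labels, or — the delta-learning
route — on the *difference* between the two, giving the corrected total

    E = E_low + Delta_E_ML[n].

The difference surface is far smoother than either total surface, so
the delta map reaches a given accuracy with an order of magnitude less
high-level training data, and its zero prior makes the correction decay
to zero away from the training set: the corrected model falls back on
plain DFT instead of extrapolating.

Around this core the package provides point-group detection and
symmetry augmentation of training sets (energies are invariants, so
each detected operation multiplies the effective training set for
free), Kabsch alignment, k-means training-point selection, fivefold
cross-validation for all kernel hyperparameters, finite-difference
forces, NVE / Langevin (BAOAB) / multiple-time-step (impulse RESPA)
integrators, and bounded geometry optimization on learned surfaces.

Because real electronic-structure back ends are outside its scope, the
package ships a family of analytic surrogate systems (`toy_water()`,
`toy_ethanol()`, `toy_ring()`) with two deterministic energy surfaces
differing by a smooth few-kcal/mol correction and analytic valence
densities, so the entire pipeline is exercised end to end with known
ground truth.

## Worked example

Train a delta map on 10 surrogate-water conformers and compare it with
a direct high-level map trained on 50:

```r
library(densfunc)

sys <- toy_water()
ds  <- make_dataset(sys, 102, seed = 11)     # conformers, densities, labels
print(ds)
#> density_dataset: 102 records of toy-water
#>   basis L = 63 ( ball ), grid 23 ^3, gamma = 0.6 , density = bonded
#>   E_low range 0 .. 91.08 kcal/mol; mean |delta| = 2.264

pool <- 1:50; test <- 51:102
ten  <- pool[kmeans_select(ds$u[pool, ], 10, seed = 1)]

delta10 <- fit_energy_map_cv(ds$u[ten, ],  ds$delta[ten],  "delta", ds$basis)
high50  <- fit_energy_map_cv(ds$u[pool, ], ds$E_high[pool], "high", ds$basis)

mae <- function(map, idx, y) mean(abs(predict_energy(map, ds$u[idx, ]) - y[idx]))
mae(delta10, test, ds$delta)   # 0.124  kcal/mol: corrected-total test error
mae(high50,  test, ds$E_high)  # 0.269  kcal/mol: direct map, 5x the data
```

The delta map at 10 high-level samples is already more accurate than
the direct high-level map at 50 — the central economy of delta
learning. (The corrected total `E_low + Delta_ML` inherits exactly the
delta map's error, since `E_low` is computed, not learned.)

Symmetry bookkeeping on a benzene-like ring:

```r
ring <- toy_ring("d6h")
g <- detect_point_group(ring$template)
g
#> symmetry_group: order 24 ( 12 proper, 12 improper ); closure verified
length(augment_dataset(sample_conformers(ring, 1000, seed = 3), g))
#> [1] 24000
```

A 100 fs constant-energy run with periodic high-level force
corrections every three steps:

```r
st <- md_state_from_conformer(sys$template)
st$positions[2, 1] <- st$positions[2, 1] + 0.06
traj <- respa_trajectory(function(x) low_level_energy(sys, x),
                         function(x) high_level_energy(sys, x),
                         st, integrator_params(dt = 0.5, n_inner = 3), 200)
traj
#> md_trajectory: 199 frames, 99 fs; E_tot drift -0.02076 kcal/mol
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/densfunc.R` (subcommands `gen-data`, `fit-energy`,
`predict`, `md`).

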