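---
title: "Discriminating local from global lateral fluidity with local stress in curved membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating local from global lateral fluidity with local stress in curved membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubestress)
```

## The scientific question

Lipid monolayers are fluid in the lateral direction: lipids diffuse freely in
the membrane plane, so a monolayer cannot sustain a *surface-integrated*
static lateral shear stress. How that fluidity enters depth-resolved
continuum elasticity is contested. Two assumptions about the depth-resolved
lateral shear modulus $\lambda_S(z)$ are in use:

* **Local fluidity**: $\lambda_S(z) = 0$ at every depth $z$. Every
  infinitesimal slab is itself fluid, and the local lateral stress is
  isotropic everywhere, in any geometry.
* **Global fluidity**: only the thickness integral vanishes,
  $\int_0^t \lambda_S(z)\,dz = 0$. Lipids relax shear only as whole
  molecules, so individual slabs may resist shear, with positive and
  negative contributions cancelling across the monolayer.

The two assumptions give different surface elastic moduli (Gaussian-curvature
and twist moduli vanish under local fluidity but not under global fluidity),
and — decisively — different local stress in a cylindrically bent membrane.
Bending a monolayer around an axis makes the azimuthal stretch depth
dependent while the axial stretch is uniform, so the difference between the
azimuthal and axial Green–Lagrange strains, $u_{xx}-u_{yy}$, cannot relax
even with free lateral redistribution of lipids. Local fluidity still
predicts an isotropic lateral stress ($\Sigma_{\theta\theta} = \Sigma_{zz}$);
global fluidity predicts a non-zero anisotropy
$A(r) = \Sigma_{\theta\theta} - \Sigma_{zz}$. Measuring $A(r)$ in a tube
therefore discriminates the models. This package implements the full chain:
local stress on grids, cylindrical analysis, uncertainty, the continuum
model, and synthetic ground-truth data.

## The elastic model

A monolayer is a transversely isotropic, incompressible 3D elastic body. In
a Cartesian frame with $z$ along the monolayer normal of the flat reference
state, the quadratic energy density is

$$w = \sigma_l (u_{xx}+u_{yy}) + \sigma_z u_{zz}
  + \tfrac{\lambda_1}{2}(u_{xx}+u_{yy})^2 + \tfrac{\lambda_2}{2} u_{zz}^2
  + \lambda_{12}(u_{xx}+u_{yy})u_{zz}
  + \tfrac{\lambda_S}{2}\left[(u_{xx}-u_{yy})^2 + 4u_{xy}^2\right]
  + 2\lambda_T (u_{xz}^2+u_{yz}^2),$$

with all moduli and pre-stresses functions of $z$ (`full_moduli`). With
linearized incompressibility $u_{zz} = -(u_{xx}+u_{yy})$ and no tilt this
reduces to the three-function form used throughout
(`elastic_profile`: $\sigma_0 = \sigma_l - \sigma_z$,
$E = \lambda_1+\lambda_2-2\lambda_{12}$, $\lambda_S$):

$$w = \sigma_0 (u_{xx}+u_{yy}) + \tfrac{E}{2}(u_{xx}+u_{yy})^2
 + \tfrac{\lambda_S}{2}\left[(u_{xx}-u_{yy})^2 + 4u_{xy}^2\right].$$

For laterally uniform principal-axis strains the tension-positive Cauchy
stress follows by differentiating $w$ with respect to the strain and
composing with the deformation, with a Lagrange-multiplier pressure $P$
carrying the incompressibility constraint:

$$\Sigma_{xx} = \left[\sigma_0 + E(u_{xx}+u_{yy})
  + \lambda_S(u_{xx}-u_{yy})\right](1+u_{xx}) + P,$$

and symmetrically for $\Sigma_{yy}$, with $\Sigma_{zz} = P$
(`cauchy_stress_planar`). The difference

$$\Sigma_{xx}-\Sigma_{yy} = \left[\sigma_0 + E(u_{xx}+u_{yy})
  + \lambda_S(2+u_{xx}+u_{yy})\right](u_{xx}-u_{yy})$$

(`lateral_stress_difference`) is the quantity the cylindrical measurement
probes: identically zero under local fluidity, generally non-zero under
global fluidity. Note the configurational factors $(1+u_{xx})$: the stress
is exact to first order in strain, consistent with the quadratic energy; a
finite-difference check in the test suite verifies the derivative part
independently of the hand-derived formula.

**Cylindrical bending.** The flat-to-cylinder map (`cylindrical_bend_map`)
sends reference depth $z_p$ (the pivotal surface) to radius $r_p$ with zero
azimuthal stretch there, applies a uniform axial stretch $\beta$ (default 1
— tube length fixed), and places every other depth by *exact* volume
conservation, $r(z)^2 = r_p^2 + 2 (r_p/\beta)\, s\,(z-z_p)$, so that
$\det F = 1$ holds identically rather than to first order. The azimuthal
strain is $u_{xx} = ((r/r_p)^2-1)/2$; the axial strain is
$(\beta^2-1)/2$. In a bilayer tube the two leaflets are curved in opposite
directions (`orientation = "inward"/"outward"`), which is why the measured
anisotropy changes sign at the midsurface.

**Radial equilibrium.** A cylindrically symmetric stress field must satisfy
$\partial_r (r\,\Sigma_{rr}) = \Sigma_{\theta\theta}$.
`solve_radial_equilibrium` integrates this by trapezoidal quadrature to fix
the Lagrange multiplier $P(r) = \Sigma_{rr}(r)$; `equilibrium_residual`
checks the same identity on measured profiles by central differences
(interior shells only — one-sided stencils would silently change the error
order). Both are second-order accurate; the test suite verifies empirical
order $\ge 1.9$ under shell halving.

**Inversion.** Given measured $A(r)$, the bend strains and the known
$\sigma_0, E$ at the matching depth, the shear modulus follows pointwise:
$\lambda_S = [A/(u_{xx}-u_{yy}) - \sigma_0 - E(u_{xx}+u_{yy})]/(2+u_{xx}+u_{yy})$
(`recover_lateral_shear_modulus`). Shells where $|u_{xx}-u_{yy}|$ is below a
strain tolerance (default 0.02 in `model_compare`; these cluster around the
pivotal radius, where the inversion is singular) are excluded and reported.

## Measuring local stress

The local stress is the Irving–Kirkwood–Noll tensor on a rectangular grid.
The package carries a desk-scale calculator for toy systems with pairwise
central forces (`kinetic_stress`, `virial_stress`, `compute_stress_grid`):
each particle spreads $-m\,v \otimes v$ trilinearly over the eight voxels
around it; each interacting pair discretizes the straight contour between
minimum-image partners into segments no longer than half the smallest voxel
edge and deposits $-(\text{segment}) \otimes f_{ij}$ at the segment
midpoints. Two properties anchor the implementation:

* **Conservation is exact for any segment count**: the voxel-integrated grid
  equals the global virial $-(\sum m\,v\otimes v + \sum r_{ij}\otimes
  f_{ij})/V$ to rounding (tested at $10^{-10}$ relative against an
  independent double-loop oracle).
* **Averages over regions containing whole contours are discretization
  independent.** Pointwise values do depend on the contour discretization —
  as pointwise local stress always depends on the contour/decomposition
  choice — but any spatial average over a region that contains the
  contributing contours is exact. The shell-average shear statistic over the
  4–6 nm shell is designed to sit in this regime.

Units are accumulated internally in kJ mol$^{-1}$ nm$^{-3}$ and converted to
bar once (1 kJ mol$^{-1}$ nm$^{-3}$ = 16.6054 bar). The sign convention is
tension-positive Cauchy stress everywhere (a fluid at pressure $P$ has
$\Sigma = -P I$); reporting functions accept a pressure-convention flag.

Grids from any grid-based local-stress code can enter through the portable
STRESSGRID v1 text/binary format (`read_stress_grid`, `write_stress_grid`),
which round-trips bit-exactly.

## The measurement pipeline

`rotate_to_cylindrical` conjugates every voxel tensor with the rotation by
the voxel's azimuth about the tube axis, $\Sigma' = A_\theta^T \Sigma
A_\theta$ (trace and eigenvalues preserved per voxel; the inverse rotation
restores the input exactly). `radial_bin` assigns voxels to 0.05 nm shells
by center radius with half-open intervals $[r - dr/2, r + dr/2)$ and takes
unweighted voxel means — voxels are equal-volume, so this matches
volume-weighted averaging. On a 40 nm transverse box the default layout is
400 shells with centers 0.00–19.95 nm. Derived profiles: the anisotropy
$A(r)$, the maximum lateral shear $s(r) = A(r)/2$ (verified internally
against an explicit $-\pi/4$ rotation of the shell tensor about the radial
axis), off-diagonal components (zero for a cylindrically symmetric system),
and the equilibrium residual. `decompose_contributions` forms the
monolayer–monolayer interaction term as total minus single-leaflet profiles,
exactly by construction. `planar_profiles` provides the slab-binned planar
analogue (lateral mean, lateral difference, normal component).

**Uncertainty.** Frames are split into 10 contiguous, near-equal blocks
(contiguity absorbs temporal correlation; the first `count mod 10` blocks
take the extra frame), block means are resampled 200 times with replacement,
and per-point intervals are read from the resample quantiles. The plain
percentile interval systematically under-covers with only 10 blocks (about
89% observed at a nominal 95%), so the default is the *expanded percentile*
interval (Hesterberg 2015): the quantile levels are widened to
$\Phi(-\sqrt{n/(n-1)}\, t_{n-1,\alpha/2})$, which restores near-nominal
coverage (about 94% measured over 500 Gaussian repeats) while remaining a
pure resampling interval. `expanded = FALSE` in `resampling_plan` gives the
plain percentile interval. What is resampled is blocks, not frames; bands
are percentile intervals, not BCa. All resampling is seeded and
reproducible, and leaves the caller's RNG stream untouched.

## Synthetic data: what it emulates and what it does not

No reference stress grids are distributed with the package, so every
analysis stage is exercised against generated fields whose ground truth is
stored next to the data (round-trip tests never re-derive truth from the
output):

* `gen_planar_grid`: a planar bilayer with a three-peak lateral profile per
  leaflet, mirrored about the midplane — a repulsive peak at the bilayer
  center (amplitude 150 bar, width 0.35 nm), an attractive trough in the
  hydrophobic–hydrophilic transition zone (−280 bar at ±1.4 nm), and a
  repulsive head-group peak (230 bar at ±2.2 nm) — zero normal stress, and
  i.i.d. Gaussian voxel noise (default 50 bar per frame, 50 frames). The
  peak placement and magnitudes are package choices of realistic order, not
  measured values.
* `gen_tube_grid`: a cylindrically symmetric bilayer field assembled in
  cylindrical components — $\Sigma_{\theta\theta}$ from a curve,
  $\Sigma_{zz} = \Sigma_{\theta\theta} - A(r)$, and $\Sigma_{rr}$ from
  `solve_radial_equilibrium`, so the field is equilibrated by construction —
  then rotated to the lab frame with the exact inverse of the analysis
  rotation (closing the loop on the transform) and degraded with symmetric
  Gaussian voxel noise per frame. The default anisotropy is a
  derivative-of-Gaussian: zero at the 6.5 nm midsurface, $+15$ bar extremum
  1 nm inside, $-15$ bar 1 nm outside — the qualitative shape and order of
  magnitude of a coarse-grained 6.5 nm tube, chosen once as package
  defaults.
* `gen_lj_fluid` / `gen_bonded_dimer`: particle fixtures for the
  Irving–Kirkwood calculator with closed-form global virials.
* `allocate_tube_lipids`: the pivotal-surface-area apportioning arithmetic
  (2570 lipids at $R = 6.5$ nm with the pivotal plane 1 nm from the
  midsurface give 1483 outer / 1087 inner; an exact half rounds down).

Desk-scale sizes: the default tube grid is one axial voxel and 0.1 nm
transverse voxels over a 20 nm box, 100 frames at 20 bar voxel noise —
roughly 190 voxels per 0.05 nm shell, giving ~0.2 bar standard errors on
shell means, comparable in *relative* precision to a long coarse-grained
run. What the generator deliberately does not emulate: thermal undulations
of the membrane shape (which smear stress radially), temporal correlation
between frames (the block machinery is still exercised, but blocks are
exchangeable here), lipid-level structure, and any force-field physics.
Passing tests demonstrate the correctness of the analysis chain, not the
values a particular lipid would produce.

The demonstration elastic profile (`demo_monolayer_profile`) uses
$\sigma_0(z) = -30\sin(\pi z/t)$ bar, $E(z) = 600\sin^2(\pi z/t)$ bar and
$\lambda_S(z) = 60\sin(2\pi z/t)$ bar over $t = 2$ nm. The shapes are
chosen so that (i) $\int \lambda_S\,dz = 0$ exactly (globally fluid),
(ii) all three functions vanish at both faces, making the predicted
anisotropy continuous at the membrane boundary, and (iii) the stretching
modulus has the right order of magnitude for a monolayer (peak 600 bar
$\approx$ 120 mN/m over 2 nm). The bend maps place the pivotal surfaces at
5.5 and 7.5 nm (1 nm from the midsurface on either side) with fixed tube
length.

## A worked run

```{r recovery, eval = FALSE}
study <- shear_recovery_study(seed = 1)
study$comparison
#> Fluidity model comparison
#>   informative shells: 81
#>   prediction inside measured band: global 79, local 11
#>   preferred model: global
#>   recovered integral of lambda_S dz (bar nm): inner -0.5, outer 1.39
round(100 * study$rms_rel, 1)   # relative RMS error of recovered lambda_S, %
#> [1] 4.4
round(100 * study$coverage, 1)  # truth inside the 95% band, % of shells
#> [1] 98.5
```

The loop behind those numbers: predict the global-fluidity anisotropy of the
demonstration profile, generate a noisy tube carrying that prediction,
measure it blind, and invert. The recovered $\lambda_S(z)$ agrees with the
truth within 5% RMS, the recovered thickness integral is consistent with
zero (global fluidity), and the global-model prediction falls inside the
measured band at 98% of informative shells while the local model (zero
anisotropy) fails at most of them.

Recovery is scored only at shells with $|u_{xx}-u_{yy}| \ge 0.02$ and depth
at least 0.05 nm from the monolayer faces: near the pivotal radius the
inversion divides by a vanishing strain difference, and the outermost shells
mix voxels from outside the membrane.

## Numerical choices and degenerate inputs

* Quadrature is trapezoidal, derivatives are central differences, grids are
  uniform; both are second order, and the tests pin the empirical order.
* Voxels are addressed 0-based with half-open extents; a voxel's position is
  its center. Shell assignment is half-open, so every radius lands in
  exactly one shell; the $r = 0$ shell is kept (it has few voxels and wide
  bands). A voxel exactly on the cylinder axis gets $\theta = 0$.
* Ties in `extremum_with_ci` go to the smaller radius; the lipid-allocation
  rounding sends an exact half down. Both rules are deterministic and
  documented rather than platform dependent.
* The bilayer midsurface radius defaults to the zero crossing of the
  measured anisotropy between its two extrema — the structural definition
  (mean position of terminal tail beads) is unavailable from stress grids
  alone; pass `midsurface` explicitly when lipid coordinates are available.
* Degenerate inputs fail loudly: non-finite tensors are rejected at
  construction and before writing; mismatched grids refuse to average or
  decompose; a pair at zero separation is a singularity error; a bend map
  that would push $r^2 \le 0$ is rejected.
* `stress_cylindrical` exposes both fluidity modes; in local mode the
  lateral stress is built from the area-stretch energy directly (isotropic
  by construction), not from the incompressible energy with $\lambda_S = 0$
  — the two differ at finite strain through the pre-stress coupling
  $\sigma_0 (u_{xx} - u_{yy})$, and the isotropic reading is the one the
  local-fluidity assumption asserts.

## Known limitations

* Tilt deformations ($u_{xz}, u_{yz}$, modulus $\lambda_T$) are stored and
  enter the full energy density but no stress or surface-moduli analysis
  uses them.
* Only pairwise central forces in the Irving–Kirkwood calculator; multi-body
  (angle/dihedral) decompositions are out of scope, as are electrostatics
  and neighbor-list performance guarantees.
* Per-shell confidence bands are estimated independently shell by shell;
  joint (simultaneous) bands are not provided.
* The synthetic noise model is i.i.d. Gaussian per voxel and frame; real
  trajectories carry temporal and spatial correlation that widens true
  uncertainties.
* Stability analysis of depth regions with negative $\lambda_S$ (which
  global fluidity requires somewhere in the monolayer) is not attempted.
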