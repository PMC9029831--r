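---
title: "Reconstructing adsorption free-energy surfaces from mean forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing adsorption free-energy surfaces from mean forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfsurf)
```

## The physical problem

A cellulose nanocrystal adsorbed at a water–oil interface can be
restrained to two collective coordinates: the distance `x` of its axis
from the interface (Å, negative on the water side) and its rotation
angle `theta` about that axis (degrees; the crystal cross-section is
twofold symmetric, so `theta` has period 180°).  At each configuration
`(x, theta)` a restrained simulation samples the instantaneous force
component `fx` and torque component `Tz` on the crystal.  By the
reversible-work theorem their time averages are minus the gradient of
the Helmholtz free energy,

    <fx> = -dF/dx,      <Tz> = -dF/dtheta,

so integrating the sampled mean-force field recovers the potential of
mean force `F(x, theta)`.  Its structure answers the emulsification
question: how strongly the crystal prefers water over oil (the transfer
free energy `dF_w2o`), where it adsorbs (local minima of the adsorption
free energy `dF(x, theta) = F - F(x_min)`), and how hard it is to move
between adsorbed states (barrier heights).

## From sampled series to a surface

**Time averaging.** `read_timeseries()` + `trim_equilibration()` +
`mean_and_sem()` turn a per-configuration series into a mean with a
block-averaged standard error.  Consecutive samples of `fx` and `Tz`
are strongly correlated, so the naive `sd/sqrt(n)` underestimates the
uncertainty; non-overlapping block means (default block size 100)
decorrelate it.  The equilibration cutoff is a configuration value
(default 1 ns) because the transient is identified by inspection, not
by rule.  Internally everything is in kcal/mol, Å, radians and ps; SI
tags (`"N"`, `"N*m"`, `"m^2/s"`) are converted only at I/O boundaries
(`convert_units()`, using 1 kcal/mol = 6.947695e-21 J per entity).

**Boundary integration.** On the coarse grid (13 × 12 nodes covering
-30 ≤ x ≤ 30 Å, 0 ≤ theta < 180°), `line_integrate_x()` integrates
`-<fx>` along each theta row with the trapezoid rule, starting from
`F(x_min, theta) = 0` (bulk water).  For ideal data every row would end
at the same value; statistical noise leaves a scatter, and
`set_boundaries()` takes the row mean as the transfer free energy and
imposes it on the whole `x_max` edge (bulk oil).  Far from the
interface the torque vanishes, which justifies a theta-independent
reference plane.

**Relaxation.** With both x edges fixed, `fes()` repeatedly replaces
each interior node by the mean of the four values its neighbours
predict through trapezoidal work terms,

    4 F[i,j] <- F[i-1,j] + F[i+1,j] + F[i,j-1] + F[i,j+1]
                + (dx/2)  (-fx[i-1,j] + fx[i+1,j])
                + (dth/2) (-Tz[i,j-1] + Tz[i,j+1]),

until the largest update in a pass falls below `tol`.  This is
Gauss–Seidel relaxation of a discrete Poisson-type system; for noisy
(non-integrable) fields its fixed point is the least-squares-consistent
surface, and it is independent of the sweep order, which is why a
seeded random sweep (the reference procedure) and the deterministic
ordered sweep give the same answer.  `solve_fes_exact()` assembles the
same stationarity conditions as a sparse linear system and solves them
directly; the test suite checks node-wise agreement below 1e-8 kcal/mol
on every grid it uses.

Numerical choices worth stating explicitly:

* **Radians in the torque terms.**  Energy = torque × angle only in
  radians; grids are specified in degrees and converted inside the
  solver.  Mixing the two is the classic failure mode of this
  reconstruction.
* **Trapezoid everywhere.**  The update formula above is the
  stationarity condition of trapezoidal edge works, so line integrals,
  the relaxation stencil, and the direct solver all use the same rule;
  mixing quadratures would make the routes disagree at their own
  tolerance.
* **Theta topology.**  The coarse ring (12 nodes over one 180° period)
  is treated as periodic; the fine grid is an open patch with Dirichlet
  edges.  Both behaviours sit behind `theta_periodic`, and degree-3
  (open-edge) and degree-2 (single-row) nodes are handled by the same
  neighbour-mean update.
* **Convergence.**  `tol = 1e-10` kcal/mol on the per-sweep update,
  `max_iter = 1e6` single-node updates.  For these grid sizes the
  remaining true error at that tolerance is well below the 1e-8
  agreement the tests demand.  Non-convergence returns the surface with
  a warning and the residual rather than failing.

**Fine refinement.** `refine_fes()` re-solves on a 16 × 16 patch
(-25 ≤ x ≤ -10 Å, 75 ≤ theta ≤ 150°, dx = 1 Å, dth = 5°) whose four
edges are Dirichlet data taken from the coarse fit.  At boundary nodes
shared with the coarse grid the coarse values are used directly.
Between anchors we do *not* interpolate the coarse surface bilinearly:
the adsorption wells are narrower than the coarse spacing, so bilinear
boundary values would transmit O(well depth) errors into the patch.
Instead the fine field itself is integrated along the edge between
consecutive anchors, and the closure defect of each span is spread
linearly (standard thermodynamic-integration stitching).  For
noise-free consistent data this is exact; with noise it adds only the
integrated edge noise.  When an edge shares fewer than two nodes with
the coarse grid the code falls back to bilinear interpolation.

**Analysis.** `find_local_minima()` reports strict minima (a node tied
with a neighbour is not a minimum, so flat noise never produces
duplicate states) under 4-connectivity by default, matching the solver
stencil.  `barrier_height()` defines the saddle between two states as
the minimax over 8-connected grid paths of the path maximum, computed
exactly with a widest-path variant of Dijkstra's algorithm, and reports
the barrier from both wells; the minimax-path definition is our
operationalisation of "barrier height read off the contour map", and
the tests verify it against exhaustive path enumeration.

## What the synthetic generators emulate

Reference MD trajectories for this system are not publicly deposited
and cannot be regenerated at desk scale, so every validation input is
generated with planted ground truth.

**Benchmark surface** (`cnc_surface_spec()`): three Gaussian wells at
(-18 Å, 95°), (-21 Å, 85°) and (-17 Å, 135°) with depths -3.586,
-3.460 and -2.384 kcal/mol on a logistic water-to-oil ramp of
318 kcal/mol (scale 3 Å, zero-referenced at x = -30 Å).  Two details
make this a usable oracle:

* **Exact depth calibration.**  Well amplitudes come from a small
  linear solve so the surface *value* at each planted node equals the
  requested depth exactly, despite ramp tails and well overlap.
* **Band-limited theta profiles.**  The theta factor of each well is a
  wrapped Gaussian (width 10°) truncated to its first 5 Fourier
  harmonics — below the Nyquist mode of the 12-node coarse ring.
  Consequently torque sums around any coarse ring close exactly, and
  the planted field can be made exactly curl-free on the grid.
* **Grid-consistent sampling.**  The physical mean force is the
  pointwise derivative, but a trapezoid quadrature of a pointwise
  gradient carries O(dx²) bias that is *large* for wells narrower than
  the coarse spacing — it would swamp the statistical effects the
  recovery tests are about.  `sample_gradient_field()` therefore (by
  default) emits *effective* node gradients, minimally adjusted from
  the analytic ones (the adjustment lives in the alternating vector
  that every trapezoid pair-mean annihilates) so that each edge work
  equals the planted free-energy difference exactly.  Noise of standard
  error `sigma/sqrt(n)` is then added on top.  With `consistency =
  "analytic"` the pointwise derivatives are used instead, and the
  reconstruction shows the ordinary quadrature bias — which real data
  would also carry for sub-grid features; passing the recovery tests
  therefore demonstrates statistical correctness of the estimator, not
  that a 5 Å grid can resolve 1 Å features.
* The well widths (1.1 Å, 10°) were chosen once so that the planted
  surface restricted to the fine grid has exactly three strict minima
  at the planted nodes; the barrier heights between the planted wells
  are emergent properties of this construction, not calibrated values.

**Force/torque series.**  The time-series mode writes stationary AR(1)
series (marginal sd `sigma`, autocorrelation time `ac_time`) whose
sample means become the field's node means, exercising the block
averaging on correlated data.

**Gap water** (`cnc_gap_spec()`): oxygens take anisotropic Brownian
steps (variance `2 D_a dt` per axis) between reflective walls 5 Å
apart in x — emulating the 3–6 Å water layer between the crystal
surface and the oil — and wrap periodically in y, z.  Planted
coefficients are (0.02, 0.17, 0.12) Å²/ps with 101 molecules for the
hydrophilic-face layer and (0.005, 0.078, 0.085) with 148 molecules
for the oleophilic-face layer, 0.5 ns at 1 ps frames.  Hydrogens sit at
rigid three-site geometry (O–H 0.9572 Å, H–O–H 104.52°) with dipole
orientations drawn from `exp(kappa_s sin(theta) - kappa_c cos(theta))`
(defaults 4 and 0.2: a lying-down preference with a slight tilt of the
dipole toward the crystal, i.e. a corrected-P(theta) peak just above
90°) and the H–H axis concentrated around the interface plane
(`phi_kappa = 40`, a ±9° spread, so the planted phi = 0 alignment is
unambiguous in a binned peak test).  Leaver molecules can be planted
with a single-frame excursion outside the slab to exercise the strict
residency rule.

What the generator does *not* emulate: hydrogen bonding, molecular
shape beyond rigid water, coupling between orientation and position,
groove-trapped sub-populations, or any force field.  Tests passing on
these fixtures validate the estimators (integration, relaxation,
residency filtering, MSD averaging, Jacobian correction), not the
molecular physics.

## Orientation and diffusion estimators

`water_vectors()` builds the dipole direction geometrically (unit
bisector through the H,H midpoint — identical to the charge dipole for
rigid 3-site water, and free of any force-field definition) with
minimum-image intramolecular vectors, so molecules split across the
periodic boundary are safe.  `orientation_angles()` defines `theta`
against the interface normal (+x, water → oil) and `phi` as the angle
between the H–H vector and `d × n`, folded to [0°, 90°] because
hydrogen labels are arbitrary; at the poles (`theta` = 0° or 180°)
`phi` is undefined and excluded from histograms.
`jacobian_corrected_hist()` divides bin counts by the *exact* integral
of sin(theta) over each bin — the centre-value approximation would be
singular in the pole bins — and normalises to unit integral, so
isotropic orientations give a flat density.  `phi` histograms get no
Jacobian: a rotation about the dipole has uniform measure.

`gap_residents()` keeps molecules inside the slab at *every* frame of
the window (an `allow_excursions` tolerance exists but defaults off).
`msd_curve()` unwraps coordinates defensively, uses oxygen positions
for the molecule, and averages squared displacements over all time
origins; `max_lag` defaults to half the window so every lag retains
meaningful pair counts.  `fit_diffusion()` takes the ordinary
least-squares slope inside a fit window — default the 25–50% span of
the computed lags, a plain reading of "sufficiently large t" —
and reports `D = slope/2` per axis in 1e-8 m²/s (numerically equal to
Å²/ps).  Negative fitted slopes are clamped to zero with a warning.
For a reflective slab of width `L` the x-displacement variance
saturates at `L²/6`, so the apparent `D_x` from a finite window is
wall-limited rather than a material property; the tests assert exactly
that behaviour.

## Problem sizes and statistical tolerances in the test suite

The suite validates at deliberately modest sizes: coarse 13 × 12 and
fine 16 × 16 reconstructions (noise sem 0.01 from sigma = 1,
n = 1e4), orientation statistics on ~1e5 samples, diffusion on
101–148 molecules × 0.5 ns, and brute-force oracles (path enumeration,
double-loop MSD) on 4 × 4 grids and ~10-frame fixtures.  Exact claims
(node counts, atom counts, unit conversions, curl-free recovery) are
tested at 1e-8 or tighter; statistical claims carry tolerances derived
from their sampling spread — e.g. per-axis diffusion at these counts
has a ~5% standard error, so single-seed checks use 15% per axis and
10% on the isotropic mean.

## Known limitations

* The reconstruction assumes the restrained coordinates capture all
  slow degrees of freedom; hysteresis or hidden barriers in real
  sampling appear only as enlarged residuals.
* Quadrature bias for features below the grid spacing is inherent to
  trapezoidal mean-force integration; the grid-consistent generator
  isolates it from the statistical tests but real data keep it.
* Saddle points are grid-resolved only; there is no sub-grid (e.g.
  spline or string-method) refinement of barrier locations.
* The residency rule makes the diffusing population survivorship
  biased at long lags, as in the original procedure; fit windows should
  stay well inside the sampling window.
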