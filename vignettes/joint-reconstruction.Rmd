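---
title: "Methods: joint initial-pressure and sound-speed reconstruction in 2D PAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint initial-pressure and sound-speed reconstruction in 2D PAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, its numerical choices,
and what its synthetic studies do and do not demonstrate.

## The forward model and its discretisation

Acoustic propagation from an initial pressure `p0` in a heterogeneous,
non-absorbing, constant-density 2D medium follows the initial value problem

$$\frac{1}{c^2(r)}\,\partial_t^2 p - \nabla^2 p = 0,\qquad
p(\cdot,0)=p_0,\quad \partial_t p(\cdot,0)=0 .$$

`simulate_forward()` integrates the equivalent first-order system (particle
velocity, split acoustic density, pressure $p = c^2(\rho_x+\rho_y)$) with

* **spectral spatial derivatives** carrying the k-space correction factor
  $\operatorname{sinc}(c_{\mathrm{ref}} k \Delta t/2)$. With this factor in
  the derivative multipliers, the staggered leapfrog update — including the
  rest-start half-step $u_{1/2} = -(\Delta t/2) \nabla p_0$ evaluated with
  the corrected operator — reproduces the exact propagator for a homogeneous
  medium at any stable $\Delta t$. The test suite checks the scheme against
  the analytic free-space solution of a Gaussian source (radial
  Fourier–Bessel quadrature) at sub-percent level and verifies the error at
  least halves under grid refinement.
* **a split-field PML**: polynomial absorption ramps (order 4, peak
  coefficient 2, scaled by $c_{\mathrm{ref}}/\Delta x$) applied as
  $e^{-\alpha\Delta t/2}$ factors on both sides of each update. The PML is
  20 pixels in the full-scale grids; the tests bound re-entrant reflections
  at below 1% of the source peak.
* **stability guard**: the solver refuses `c_max * dt / dx > 1` and names
  the offending value; `c_ref` defaults to `max(c)` and is held fixed over
  an optimisation so that all iterates share one discrete forward map.

Sensors are ideal point detectors snapped to grid nodes on a square contour
just outside the target domain (nearest-node sampling, no interpolation),
mirroring a planar detection geometry with sensors on all four sides.

## Objective, priors, noise

The unknown vector stacks `I` initial pressures and the shared sound speed
over the target-domain pixels; sensor-band and PML pixels keep `p0 = 0` and
`c` fixed at the prior mean. The objective combines per-dataset data
misfits weighted by the scalar noise precision with Ornstein–Uhlenbeck (OU)
Gaussian priors for every field:
$\Gamma_z = \sigma_z^2\,\Xi$, $\Xi_{ij}=e^{-\|r_i-r_j\|/\tau}$.
The OU prior favours locally correlated fields while tolerating sharp
jumps, which suits piecewise-smooth tissue maps. One Cholesky factor of
$\Xi$ per grid level serves both the `p0` and `c` priors (they share the
pixel set and `tau`); whitening uses triangular solves, never an explicit
inverse.

Parameter conventions (all configurable):

| parameter | default | meaning |
|---|---|---|
| `sigma_z` | (range of true values)/4 | ~95% of prior mass inside the true range |
| `eta_z` | median of the true range | prior mean; also the `c` initial guess |
| `tau` | 1.5 mm (simple targets), 1 mm (tissue) | OU correlation length |
| noise | 1% of peak-to-peak, per dataset | `sigma_e` re-estimated from the *noisy* traces |
| bounds | `p0 >= 0`; `c` in [1300, 1800] m/s | upper `c` bound 3000 m/s for bone-like targets |

## Gradients: exact discrete adjoint

Gradients are computed with the adjoint-state method: the weighted residual
$L_e'L_e(y - f)$ drives one adjoint wave problem per dataset, whose terminal
field is the data-misfit gradient with respect to `p0`, and whose pairing
with the stored forward history yields the `c` gradient (the continuous
form is $\sum_i \int_0^T (-2/c^3)\,\partial_t^2 p^i\; q^i(T-t)\,dt$ plus the
prior term).

A design choice worth stating plainly: instead of discretising the
continuous adjoint PDE and choosing a source-injection scaling, the package
implements the **exact transpose of its own forward recursion**. The
spectral derivative is a real skew-symmetric operator (Nyquist components
zeroed on even grids), PML and material factors are diagonal, so the
transposed time loop uses the same primitives in reverse order; the same
sweep accumulates the exact reverse-mode sensitivity with respect to `c`
against the recorded forward density history. Consequences:

* the forward/adjoint dot-product identity holds to near machine precision
  (the suite demands 1e-3; the implementation delivers ~1e-10), and
* stacked analytic gradients match central finite differences of the full
  objective at ~1e-5 (p0 blocks) and ~1e-4 (c block) on the verification
  problems, comfortably inside the 1e-3/1e-2 acceptance tolerances.

The sign convention follows the descent direction of the misfit: the
adjoint sweep returns the sensitivity of $\langle v, f\rangle$ and
`gradient_p0()` / `gradient_c()` negate it before adding prior gradients.
`second_time_derivative()` (centred interior stencils, one-sided
second-order ends) is provided for users who want the continuous-form
integrand as a diagnostic.

## Optimisation and multigrid continuation

`minimize()` is a projected L-BFGS: two-loop recursion with the scaled
identity seed $H_k^0 = (\kappa'\varphi)/(\varphi'\varphi) I$, memory 20,
curvature-guarded pair updates (pairs with
$\varphi'\kappa \le 10^{-10}\|\varphi\|\|\kappa\|$ are skipped), projected
Armijo backtracking ($c_1 = 10^{-4}$, halving, first step scaled by
$1/\|g\|_\infty$), and a stopping rule of relative objective decrease below
1e-4 on five consecutive iterations or an iteration cap. On a line-search
failure the history is cleared and one steepest-descent restart attempted.
Iterates satisfy the bounds exactly by construction.

The joint problem is non-convex; coarse grids support only low frequencies,
which smooths the objective and avoids locking onto the wrong oscillation
cycle of the data. `run_multigrid()` therefore optimises level by level
(strictly decreasing `dx`), rebuilding priors from each level's physical
pixel coordinates, resampling the data onto the level's time axis
(forward–backward Butterworth low-pass at the level's supported band
`c_min/(2 dx)` by default, then linear interpolation), and bilinearly
prolonging the estimates as the next level's start. The L-BFGS history is
grid-specific and resets across levels. Bound-feasibility survives
prolongation because bilinear interpolation is a convex combination.
Schedules that share a level `dx` with the data-simulation grid are refused
unless explicitly overridden.

## Synthetic data generators

* **Circular-inclusion targets** (`simple_phantom_spec()`): nine (or three,
  for reduced-scale studies) sound-speed disks at 1580 m/s in a 1430 m/s
  background, optional 1482 m/s water-bath frame, optional 2500 m/s
  bone-like rectangle; per-dataset `p0` disk sets at 10 Pa. The inclusion
  layout is stored in domain fractions and is an approximation — the
  reference layouts exist only as figures — so error metrics tied to the
  geometry are approximate by construction.
* **Tissue-mimicking targets** (`make_tissue_phantom()`,
  `tissue_p0_sets()`): a procedural 2D stand-in with vessel-like curvilinear
  absorbers (blood-dominated), smooth water/fat background variation, two
  sound-speed lobes and faster vessels. Initial pressures come from a
  continuous-wave diffusion-approximation light model
  ($-\nabla\cdot(\kappa\nabla\Phi) + \mu_a\Phi = 0$,
  $\kappa = 1/(2(\mu_a+\mu_s'))$, Robin boundaries
  $\Phi/2 + \kappa\,\partial_n\Phi = q_{in}$, unit inward flux on
  illuminated sides; cell-centred finite volumes with harmonic-mean face
  diffusivities, solved sparsely) via $p_0 \propto \mu_a \Phi$. Three
  dataset designs are built in: illumination from each side in turn;
  four wavelengths (650/750/850/950 nm) through a small bundled — and
  explicitly synthetic — chromophore table; and exogenous boundary
  absorbers ($\mu_a = 0.3\,\mathrm{mm}^{-1}$ disks). By design the
  multi-illumination sets are strongly distinct while the multi-wavelength
  sets are near-collinear in shape (normalised cross-correlation > 0.9):
  that collinearity is the known reason wavelength diversity alone helps
  little.
* **Noise**: additive zero-mean Gaussian at 1% of each clean dataset's
  peak-to-peak amplitude, seeded reproducibly; the reconstruction re-
  estimates `sigma_e` from the noisy data.

What the generators do *not* emulate: real detector bandwidth and
directivity, acoustic absorption/dispersion, 3D propagation, speckle-like
heterogeneity, or radiative-transport corrections to the diffusion model.
Passing the twin study shows the estimator behaves as designed under its
own modelling assumptions — not that those assumptions hold for any
particular scanner.

## Study problem sizes

The package's standard verification battery uses: a 32-pixel interior grid
with 64 time samples for the adjoint identity (five random heterogeneous
media); a 24-pixel, two-dataset problem for the 20-direction
finite-difference gradient check; 64- and 128-pixel homogeneous grids for
forward fidelity and refinement. The reduced-scale twin study — the
package's core scientific check — uses a 20 mm domain simulated at 64
pixels (312.5 µm, 250 × 80 ns samples), reconstructed through a 32-pixel
(625 µm) and a 48-pixel (416.7 µm) level with 30/25 iteration caps, 100
boundary sensors 0.2 mm outside the target (25 per side keeps snapped nodes
distinct on the coarsest level), four datasets versus one, 1% noise, ten
noise seeds. These sizes were chosen as the smallest configuration that
still exhibits the full mechanism (distinct simulation/reconstruction
grids, multigrid continuation, active bounds); the full-scale printed
schedule is available through `study_grids()` and
`scripts/reproduce_full_table.R`.

## Numerical details and degenerate inputs

* `chol(Xi)` can be sensitive for very small `tau/dx`; failures surface
  with a conditioning message rather than silently regularising.
* `estimate_noise_std()` rejects constant data; `relative_error()` rejects
  a zero-norm truth; `resample_data_time()` refuses to extrapolate beyond
  the recorded horizon.
* Bilinear prolongation clamps beyond the outermost coarse pixel centres
  (constant extrapolation) and tolerates up to 5% physical-extent mismatch
  between levels, since the printed discretisations cannot all hit the
  nominal domain size exactly.
* Rasterisation uses the pixel-centre-inside-shape rule; inclusion areas
  converge to $\pi r^2$ as `dx -> 0` (tested).
* The twin study's c error is dominated by the background norm: even the
  prior-mean start sits at ~5%, so sub-6% final errors reflect genuine
  inclusion recovery, which is why the acceptance check also demands the
  proposed-vs-reference ordering across seeds.

## Known limitations

2D only; non-absorbing media; shared sensor geometry across datasets; dense
OU factors limit levels to ~10^4 target pixels (ample for the shipped
schedules: the finest printed level is 199² ≈ 4·10^4 pixels, where the
dense factor (~12 GB) would not fit comfortably — at that scale a truncated
sparse approximation or a smaller `tau` would be required, and the
full-scale script should be regarded as compute-bound in both time and
memory at level 5); no checkpointing of forward fields (memory scales with
`nt`); no slowness reparameterisation; no Hessian information beyond
L-BFGS.
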