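---
title: "Active-gel mechanics of monolayer fluidization: model, measurement and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-gel mechanics of monolayer fluidization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(activegel)
```

## The model

A confluent epithelial monolayer confined to a circular well is treated
as a thin, linearly elastic active gel on a frictional substrate. Two
fields live on the unit disc: the in-plane displacement $u(x,t)$ and the
actinomyosin concentration $c(x,t)$. The force balance reads

$$\Gamma\,\partial_t u \;=\; h_{eq} E\, \nabla\cdot\varepsilon
  \;+\; h_{eq}\eta\, \partial_t \nabla\cdot\varepsilon
  \;+\; h_{eq}\alpha\, \nabla c,$$

with $\varepsilon = \tfrac12(\nabla u + \nabla u^T)$, and the
concentration obeys a convection–diffusion–reaction equation

$$\partial_t c + \partial_t u \cdot \nabla c \;=\;
  -\frac{c - c_{eq}}{\tau_c} \;\pm\; \beta\, \nabla\cdot u
  \;+\; D\,\nabla^2 c.$$

The traction transmitted to the substrate is the friction law
$T = \Gamma\,\partial_t u$ — traction is proportional to local sheet
velocity, which is why a burst of contraction is visible as a burst of
traction.

Parameters (defaults of `model_params()`): $E = 4000$ Pa,
$h_{eq} = 8\,\mu m$, $\Gamma = 2.5\cdot10^8\,\mathrm{N\,s\,m^{-3}}$,
$D = 10^{-9}\,\mathrm{m^2 s^{-1}}$,
$\beta/c_{eq} = 8\cdot10^{-5}\,\mathrm{s^{-1}}$, $\tau_c = 13{,}000$ s,
$\eta = 0$, well radius $R = 3.5$ mm. Nondimensionalization: lengths by
$R$, time by $\tau_L = \Gamma R^2 / (h_{eq} E) \approx 9.6\cdot10^4$ s
($\approx 26.6$ h), concentration by $c_{eq}$. One nondimensional
velocity unit is $\approx 132\,\mu m/h$. The contractility enters only
as $\hat\alpha = \alpha c_{eq}/E$.

## The sign of the strain coupling

The printed form of the strain-activation term, $\beta\nabla\cdot
\bar{\bar\varepsilon}$, is a vector in a scalar equation; we read it as
$\beta\,\mathrm{tr}\,\varepsilon = \beta\,\nabla\cdot u$. Its sign is a
genuine modelling choice, and the two choices behave qualitatively
differently:

* **stretching raises $c$** (`strain_activation = "stretching"`). The
  coupling is purely stabilising: eliminating $c$ adiabatically gives an
  effective bulk stiffening $\propto \hat\alpha\beta\tau_c$, transients
  decay, and no amplification of contractile centres is possible at any
  contractility.
* **compression raises $c$** (`strain_activation = "compression"`,
  the default). This is the mass-conservation-consistent convention —
  actinomyosin rides with the tissue, so compression concentrates it.
  Notably $(\beta/c_{eq})\,\tau_c \simeq 1.04$: the concentration
  relaxes toward the density-tracking value $c_{eq}(1 - \nabla\cdot u)$,
  which is exactly the linearised conservation law. With this
  convention the uniform state supports amplification of contraction
  centres: beyond an onset contractility the centred collapse mode of
  the disc grows, which is the mechanism behind the global inward
  migration the package's sweeps quantify.

We therefore default to the compression convention and expose the
printed alternative as an option.

## Boundary conditions

Displacement is clamped on the rim, $u(|x| = 1) = 0$. For the
concentration the package defaults to an *anchored* rim,
$c(|x|=1) = c_{eq}$: the actinomyosin pool at the confinement edge stays
at its equilibrium level. With the natural no-flux condition instead,
the leading unstable mode of the coupled operator is dipolar — the
collapse picks a side — whereas the anchored rim re-orders the spectrum
so that the axisymmetric (centred) collapse leads, which is the
phenotype seen in serum-activated discs: nearly the whole sheet moving
toward the centre. `simulate_monolayer(..., c_boundary = "noflux")`
restores the natural condition.

## Contractility calibration

The default $\hat\alpha$ is tied to the onset of the centred-collapse
instability. On the reference meshes the onset sits near
$\hat\alpha^* \approx 18$–$20$ (located by stepwise bisection on
prefactor-1.0 runs, `analysis/02_calibrate_alpha.R`; the exact value
shifts slightly with mesh and seeding detail). Past the onset
the growth is not saturated by any term of the model — the fields are
linear in $c$ and $u$ apart from the advective term — so the collapse
accelerates beyond what the fixed-cap time stepper resolves and the
displacement leaves the geometrically linear regime. The default is
therefore set ~25% below onset, `default_alpha_hat() = 14`: the
strongest contraction whose transient amplification the standard
stepper integrates robustly. This is a deliberate deviation from a
strict "smallest value that migrates" rule, which in this model selects
the runaway regime itself.

## The quiescence-exit protocol

`quiescence_run()` performs one in-silico serum-activation experiment:

1. `seed_concentration()` — each node has a 60% chance of carrying a
   random excess drawn from a Gaussian truncated to $[0,1]$ (location
   1/3, scale 1/6), scaled by the *prefactor* and added to $c_{eq}$.
   The truncation parameters calibrate the realized prestress
   $c_0 = \int c\,dA / (c_{eq} A)$ to $1 + 0.206\times$ prefactor, so
   prefactor 0.01 gives $c_0 \approx 1.002$ and prefactor 1.0 gives
   $c_0 \approx 1.2$.
2. `dormant_concentration()` — the boundary ring is held at $c_{eq}$
   (rim compatibility). Optionally the excess can be modulated by the
   diffusion–relaxation envelope `rim_envelope()`, the stationary
   profile $1 - I_0(\kappa r)/I_0(\kappa)$,
   $\kappa = 1/\sqrt{\hat D \hat\tau_c}$, of a species produced
   uniformly during dormancy; the envelope is normalised to unit mean
   so $c_0$ is unchanged.
3. The model is integrated from $u = 0$: switching contractility on
   against the stored prestress produces the traction burst, after
   which the amplified inward response develops and eventually drains.

```{r}
mesh <- disc_mesh(0.05)
traj <- quiescence_run(mesh, model_params(),
                       seeding_spec(prefactor = 1, rng_seed = 1))
rvs <- radial_velocity_series(traj)
averaged_radial_velocity(rvs)
```

## Numerics

P1 (piecewise-linear) finite elements on a concentric-ring
triangulation of the unit disc (`disc_mesh()`; ring $k$ carries $6k$
nodes, so radial and azimuthal spacing match the target and the area
converges to $\pi$ quadratically). Time stepping is backward Euler for
both fields on the published schedule: initial step $5\cdot10^{-5}$,
grown by 5% per step to a cap of $10^{-3}$, run to nondimensional time
3. Each step solves the coupled nonlinear residual by Newton iteration
to a relative tolerance of $10^{-8}$ (cap 25 iterations). The Jacobian
— constant elastic/reaction blocks plus convection blocks linearised at
a reference state — is LU-factorised once and reused across steps and
iterations; it is refreshed at the current state when the iteration
needs more than a handful of iterations to contract, and the step fails loudly if
the refreshed iteration still stalls. Convection uses the discrete
step velocity $(u^{n+1}-u^n)/\Delta t$ with no upwinding (the cell
Péclet number stays modest at the stated diffusivity). The uniform
state $c \equiv c_{eq}$ is preserved to machine precision because the
discrete concentration-to-force map annihilates constants exactly.

Snapshots are linear interpolations between accepted steps at the
requested output times (default spacing 0.02). The solver was verified
against an independent 1D radial finite-difference discretisation of
the same equations (axisymmetric oracle, matched time grid, <2%
relative $L^2$ on the displacement profile) and by mesh-refinement
convergence in the smooth subcritical regime.

## Simulation observables

`radial_velocity_series()` reports, per snapshot pair, the
area-weighted mean inward radial velocity ($\mu m/h$) and the
outward-moving area fraction. `averaged_radial_velocity()` applies the
coordinated-migration window: it opens at the first frame with less
than 1% of the area moving outward and closes when the velocity falls
below 20% of its value at opening (or at the end of the series). Runs
whose window never opens are immobile (velocity 0 in ensembles). Since
the continuum model has no cells, "cells moving away from the centre"
is interpreted per mesh node, area-weighted.

`prestress_sweep()` runs the protocol over prefactors
$\{0.01, 0.1, 0.5, 1, 2, 3\}$ with an ensemble of seeds and summarises
each prefactor by the ensemble mean and the min/max envelope (the
published ensemble "SD" convention) plus a conventional SD.
`fit_sigmoid()` fits $v = a_0/(1+e^{-a_1(x-a_2)})$ by
Levenberg–Marquardt from a deterministic multi-start grid. Fits are
performed against *excess prestress* $c_0 - 1$: realized $c_0$ values
are $\ge 1$ by construction while the reference midpoint $a_2 = 0.19$
lies below 1, which is only consistent with the excess scale
($0.002 \ldots 0.62$ at the standard prefactors).

## Measurement pipeline

* `bead_displacement()` / `piv_velocity()`: windowed cross-correlation
  with zero-padded (linear) correlation, overlap-normalised lags and
  3-point Gaussian subpixel interpolation. Defaults 48 px windows at
  50% overlap for PIV; featureless windows are masked, never zeroed.
* `fttc_traction()`: unconstrained Fourier-transform traction
  cytometry. The Boussinesq half-space surface Green tensor in Fourier
  space, $G(k) = \frac{2(1+\nu)}{E k^3}(k^2 I - \nu\, k k^T)$, is
  inverted per wavevector after zero-padding the displacement grid to
  twice its size; the $k = 0$ mode carries no traction information and
  is set to zero; no regularisation by default (a Tikhonov knob
  exists). Padding artefacts concentrate in a ~2-cell border, so
  validation is reported on the interior.
* `recover_stress()`: monolayer stress microscopy. The 2D force
  balance $\nabla\cdot\sigma = -T$ is closed as a plane-stress elastic
  problem (P1 elements on the traction grid, clamped border, Poisson
  ratio 0.5) and reported on a 10% interior crop;
  $|\sigma| = |(\sigma_{xx}+\sigma_{yy})/2|$ in mN/m. The recovered
  stress is exactly independent of the auxiliary modulus (it only
  rescales the auxiliary displacement) — the property the method relies
  on — and the manufactured-solution oracle
  (`manufactured_stress_case()`, an elastically *compatible* stress
  built from a quartic-bump displacement potential) is recovered to
  well under 3% interior error. A uniform border-balanced tension state
  is invisible to traction-based recovery (it is the homogeneous mode
  absorbed by the clamped border), which is why the oracle uses
  border-vanishing fields.
* Substrate Poisson ratio defaults to 0.49 (near-incompressible
  polyacrylamide); it is not separately reported in the reference
  materials.
* Image convention: x right, y up, origin lower-left; TIFF row 1 is the
  top row and is flipped on load by `read_image_stack()`.

## Synthetic data

Every generator is deterministic under its seed. Bead images use 2D
Gaussian spots (σ 1.5–2 px) rather than a full PSF model — sufficient
for cross-correlation testing. `boussinesq_forward()` provides the
forward displacement operator: direct real-space quadrature (with
sub-cell near-field quadrature and an analytic equal-area-disc self
term) for grids up to ~40², Fourier multiplication with 4× padding
above; the two routes agree to <1% on zero-net-force fields and serve
as each other's oracle. Nuclei movies advect Gaussian nuclei with a
parametric flow (uniform / radial / rigid), respawning out-of-frame
nuclei uniformly to keep density stationary; the ground-truth velocity
field is returned alongside. What the generators do *not* emulate —
imaging aberrations, bead detachment, cell division, heterogeneous
friction — bounds what green tests imply about real microscope data:
they validate the algorithmic chain, not its robustness to every
experimental nuisance.

## Known limitations

* Beyond the collapse onset nothing saturates the amplification: the
  model is linear in its fields apart from advection, so the
  supercritical collapse grows until the geometric linearity and the
  fixed-cap stepper both fail. The bounded default (~25% below onset)
  yields windowed velocities whose dependence on prestress is close to
  proportional; the sharp threshold-and-saturation shape of the
  reference response (saturation speed 28 μm/h, steepness 17.1,
  midpoint 0.19) lives in the runaway regime this implementation cannot
  integrate faithfully, and the acceptance report documents the
  discrepancy rather than masking it.
* The windowed velocity latches onto the serum-exposure burst when the
  initial random phase is shorter than an output frame; at the stated
  diffusivity the node-scale noise smooths within a frame, so the
  window opens at the first frame.
* No finite-substrate-thickness Green functions; no 3D mechanics; no
  cell-based resolution of neighbour exchange; plane-stress recovery
  assumes the monolayer transmits stress as a compatible elastic sheet.
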