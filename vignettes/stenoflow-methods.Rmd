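---
title: "stenoflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stenoflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stenoflow` simulates pulsatile, shear-thinning blood flow with heat
transfer through an axisymmetric stenosed artery under a transverse
magnetic field.  This vignette records the governing model, every tunable
that matters, the numerical choices, and the reasoning behind the design
decisions that were genuinely open.

## Governing model and assumptions

The flow is incompressible, laminar, axisymmetric and swirl-free
(`u_theta = 0`), in a rigid vessel.  Momentum carries four force
contributions beyond pressure: the divergence of the full
variable-viscosity stress `div(mu (grad V + grad V^T))`, the
magnetohydrodynamic damping force, the ferrohydrodynamic (Kelvin)
magnetization force, and gravity is neglected (horizontal vessel, small
density variations).  Energy transports heat by convection and
conduction with two volumetric sources: Joule heating of the induced
currents and viscous dissipation `mu * Phi` with the axisymmetric
dissipation function

    Phi = 2[(du_r/dr)^2 + (u_r/r)^2 + (du_z/dz)^2]
          + (du_r/dz + du_z/dr)^2 - (2/3)(div V)^2.

**Rheology.**  The Carreau law interpolates between the zero-shear
plateau `mu1 = 0.056 Pa s` and the infinite-shear plateau
`mu_inf = 0.036 Pa s` with relaxation time `lambda = 3.313 s` and power
index `n = 0.3568`, the standard whole-blood fit.  The shear rate is the
invariant `sqrt(2 D:D)` of the rate-of-strain tensor including the hoop
term `u_r/r`; the literature often leaves this choice implicit, and the
invariant form is the generalized-Newtonian convention.  Setting
`mu1 = mu_inf` recovers a Newtonian fluid.  The momentum equation solves
the full variable-viscosity stress by default; a `viscous_form =
"laplacian"` switch restores the constant-viscosity `mu lap(V)` form for
comparison, since that form is the special case printed in most
derivations.

**Electromagnetics.**  The low-magnetic-Reynolds approximation applies:
induced fields are neglected and the current is `J = sigma (V x B)` with
blood conductivity `sigma = 0.8 S/m`.  A uniform transverse induction is
incompatible with exact axisymmetry, so the solver uses the standard
biomagnetic-fluid-dynamics reduction: the azimuthally averaged damping
force `-sigma B(z)^2 u_z` and Joule source `sigma B(z)^2 u_z^2`.  This
reduction has the exact Bessel-form Hartmann pipe solution as its
steady straight-tube limit, which is what the validation oracle uses.
The field envelope `B(z)` is a plateau over `[z_on, z_off]` (default: the
distal section, from the stenosis throat to the outlet) with C1 cosine
ramps of length `0.1 L0`.  The Hartmann number is `Ha = B0 R0
sqrt(sigma/mu_ref)` referenced to `mu_ref = mu_inf`, the plateau that
governs the high-shear near-wall layers; no other reference viscosity is
canonical for a shear-thinning fluid, and `mu_inf` makes `Ha` a
conservative (largest) estimate of the electromagnetic-to-viscous force
ratio.

**Magnetization force.**  The Kelvin force `mu0 M grad H` is implemented
with the linear, temperature-independent law `M = chi H`, which also
makes the magnetocaloric energy term `mu0 T (dM/dT) DH/Dt` identically
zero (it remains in the code as a pluggable hook).  The default
susceptibility is `chi = 0`: blood conductivity is so low that Hartmann
numbers of order one already imply inductions of tens of tesla, where
even a weak-paramagnetic `chi ~ 3.5e-6` would put hundreds of pascals of
Kelvin force on the field-entry ramp — an order of magnitude above the
physiological driving pressure, swamping the damping physics the model
targets.  Users studying ferrofluid-doped blood can set `chi` in the
magnetics block.

**Boundary conditions.**  No-slip on the stenosed wall (applied on the
actual wall `r = R(z)`, not the unobstructed radius — no-slip on the real
wall is physically required); symmetry on the axis; pressure boundaries
at both ends, with the pulsatile gauge `P(t) = Pm (1 + eps sin(omega0
t))` at the inlet and 0 at the outlet; fully developed outflow
(`du_z/dz = 0`).  Thermally: Dirichlet inlet temperature, adiabatic
walls except an optional cooled Dirichlet patch on the distal stenosis
half, zero-gradient outlet.  The inlet temperature defaults to the
physiological 310 K; the literal 300 K variant that appears in some
formulations is available via `T_inlet`, since 300 K blood entering a
living vessel is not physically meaningful and conflicts with the
"keep blood under 40 °C" framing the thermal scenario exists for.

## Geometry

The lumen radius follows the piecewise profile with a straight
converging ramp on the proximal stenosis half and a cosine recovery on
the distal half, throat at `z = d + L0/2`:

    r(z)/R0 = 1 - (2 delta / (R0 L0)) (z - d)                 (ramp)
    r(z)/R0 = 1 - (delta/2R0)(1 + cos(2 pi (z-d-L0/2)/L0))    (recovery)

This asymmetric form is implemented exactly as printed in the source
formulation even though prose descriptions of such geometries usually say
"cosine"; a symmetric double-cosine variant (`profile = "cosine"`) is
provided but not default — fidelity first, flexibility second.  The
base case uses `R0 = 1 cm`, length 7 cm, stenosis length 2.824 cm
(treated as an input constant), blockage 50%, throat at `z = 2 cm`.
Note the ramp/cosine junction leaves a slope discontinuity at the
throat; see the convergence discussion below.

## Mesh

A structured, body-fitted quadrilateral grid in the mapped coordinates
`(z, eta = r/R(z))`, uniform in both directions, replaces the
unstructured triangulations sometimes used for such domains: it is
deterministic, exactly nestable under refinement (every parent cell is
the union of `factor^2` children), and the physics does not depend on
mesh family.  All areas and volumes are per unit radian; the `2 pi`
factor cancels in every balance.  Cell volumes integrate `R(z)^2`
exactly over each column (Gauss panels split at the profile
breakpoints), so refinement conserves volume to round-off.  For a
1-radian wedge the closed-surface identity reads: axial face-area
components sum to zero exactly, and radial components sum to the cell's
cross-sectional area (the projection of the two azimuthal faces) — both
are asserted in tests at 1e-12.

## Discretization and solver

Finite volumes with collocated variables.  Convection is first-order
upwind through stored face mass fluxes; diffusion is central with the
over-relaxed non-orthogonal decomposition, the deferred part evaluated
from cell gradients.  Gradients use central differences in the mapped
coordinates plus the chain rule for `r = eta R(z)` (mirror symmetry
across the axis, with odd parity for `u_r`; face values close Dirichlet
boundaries, one-sided differences close Neumann ones).

Pressure-velocity coupling is SIMPLE with Rhie-Chow momentum
interpolation for the face fluxes, plus two consistency corrections that
proved necessary rather than optional:

* **Majumdar correction** (carrying the previous outer iteration's
  face-minus-interpolated flux difference scaled by `1 - relax_u`):
  without it the converged fluxes depend on the under-relaxation factor.
* **Choi transient correction** (carrying the previous time level's
  difference scaled by the transient fraction of the momentum diagonal):
  without it the converged step — and even the large-time steady limit —
  depends on `dt`, and the observed temporal order degrades to about
  `dt^0.5`.  With both corrections the steady limit is independent of
  `dt` and relaxation to solver tolerance, and halving `dt` halves the
  time-stepping error (first-order backward Euler), as the Richardson
  test asserts.

Momentum equations use implicit (Patankar) under-relaxation with the
classical stable pairing `relax_u = 0.7`, `relax_p = 0.3`; the explicit
alternative destabilizes the pressure feedback loop on these meshes.
The known cost of the implicit form — geometric stalling of one smooth
global flow mode, which is slow precisely on high-aspect cells — is
addressed twice: the initial state is a lubrication-theory warm start
(quasi-Poiseuille profile whose flow rate balances the driving pressure
against the series resistance `(8 mu / pi) int dz/R^4`, with the Carreau
viscosity at the wall-shear estimate and the corresponding nonlinear
pressure distribution), and a safeguarded Aitken extrapolation fires
every fifth outer iteration, boosting along the last increment by
`rho/(1-rho)` only when the increment direction is stable
(cosine-similarity above 0.95, estimated ratio in (0.5, 0.995), boost
capped at 100).  Convergence requires both the normalized mass residual
(`outer_tol = 1e-6`, normalized by a Poiseuille-scale reference flux)
and the relative velocity change per iteration (`du_tol = 1e-6`) — the
mass residual alone cannot see the stalled mode, because a radially
smooth, axially uniform velocity error is divergence-free.

Severely constricted cases (blockage around 80% and above) destabilize
the deferred non-orthogonal corrections at the default relaxation;
`solve_steady()` restarts automatically with factors scaled by 0.6 (up
to three times) and a proportionally larger iteration budget, which
converges all blockages in the 20-85% study range.

The r-momentum hoop stress `tau_theta/r` is implicit on the diagonal
(coefficient `2 mu V / r_hoop^2` in full-stress form), which regularizes
the axis region.  Time integration is backward Euler, first order, with
the SIMPLE loop iterated to tolerance inside each step; the energy
equation is advanced after the velocity solve (one-way coupling within a
step, since viscosity is temperature-independent).  Divergence is
detected by residual growth beyond 1e4 times the best residual over a
20-iteration patience window and reported with diagnostics rather than
producing NaNs.

**Degenerate inputs.**  `delta = 0` is a straight tube; `Pm = 0` yields
the exact quiescent state (the residual normalization guards against
0/0); `delta >= R0` and meshes under 4x4 cells are rejected; negative
diffusivities and shear rates are errors; flow resistance is flagged
undefined below a flow-rate threshold instead of returning infinities.

## Scenario presets: what they emulate and what they do not

The presets define the study conditions: a base 50% case (7 cm vessel),
a Hartmann sweep `Ha in {0, 0.1, 1}`, a blockage sweep
`{20, 40, 50, 60, 70, 80, 85}%` (6 cm vessel, matching the sweep-case
descriptions), and a low-pressure 60% case with Joule heating and a
cooled distal wall.  Values never printed in the source formulation were
fixed once, as follows, and are all config-exposed:

* **Mean driving pressure**: `Pm` is calibrated so the unobstructed
  Newtonian tube runs at Re = 100 (`Pm ~ 34.6 Pa`), a representative
  small-artery regime; `eps = 0.2`, `omega0 = 2 pi` (a 1 Hz beat, so the
  five standard snapshot instants are the quarter-periods of one cycle).
* **Low-pressure preset**: `0.75 Pm`.  Mapping the 60%-blockage, Ha = 1
  family at 64x24 places the separation onset between `0.5 Pm` and
  `0.75 Pm`; `0.75 Pm` is therefore the lowest driving level of the
  family that exhibits the post-throat recirculation the scenario is
  about, while staying below the base-case driving.  Within this regime
  the recirculation extent grows monotonically with the driving
  pressure, which the acceptance suite asserts.
* **Thermal conductivity** `k = 0.5 W/(m K)`: standard blood value.
* **Cooled patch**: Dirichlet at the inlet temperature on the distal
  stenosis half, the place heat is described as being removed from;
  no removal rate being given, pinning the wall to the physiological
  inlet temperature is the simplest "perfectly cooled" idealization.

The synthetic fixtures (`make_fixture`) provide a straight tube, a tiny
stenosed mesh, and manufactured smooth fields with exact derivatives for
operator tests; they are seed-deterministic.  What none of this
emulates: real arterial geometry (tapering, curvature, eccentric
plaque), wall compliance, non-periodic physiological waveforms,
temperature-dependent properties, or 3D secondary flows.  Passing tests
therefore demonstrate correctness of the stated axisymmetric model, not
clinical fidelity.

## Validation and known limitations

* The straight-tube solver matches Poiseuille within 1% and the
  Bessel-form Hartmann profiles within 2% at `nr = 32` (acceptance
  suite); the steady centerline velocity is non-increasing in `Ha`, and
  resistance escalates with blockage (more than doubling from 60% to
  80%).
* Discrete continuity closes to `1e-6` of the inlet flux per cell after
  convergence by construction of the pressure correction; the thermal
  balance (enthalpy rise vs. Joule + viscous sources, plus wall cooling)
  closes to well under 1% because both sides discretize consistently.
* The **mechanical** audit `dP*Q = int(mu Phi) + Joule + dKE` closes
  within 2% on resolved straight-tube flows, but on strongly constricted
  geometries the gap measures the first-order upwind scheme's artificial
  dissipation in the throat jet — several percent at study resolutions,
  decreasing under refinement (a dedicated test asserts the decrease).
  This is the main accuracy cost of the robust convection scheme.
* The peak wall shear stress converges monotonically under nested
  refinement, but at a reduced rate on the as-printed geometry: the
  ramp/cosine slope break at the throat is a corner that limits the
  observed order of the peak to about one half.  On the smooth
  double-cosine variant the same protocol shows an observed order above
  one (asserted in tests), isolating the geometry, not the scheme, as
  the cause.
* Wall shear stress uses a two-point one-sided (quadratic) wall-normal
  gradient with the Carreau viscosity at the wall shear rate.
* Problem sizes in the tests (typically 16x32 for oracle checks, 64x24
  for the sweeps, 24x8 to 96x32 for the convergence ladder, 40 steps of
  `dt = 12.5 ms` for the thermal-safety run) were chosen as the coarsest
  resolutions at which each behavior is cleanly resolved.

## Reported-behavior caveats

Published discussions of this configuration contain an internal tension:
velocity is described both as dropping and as increasing with the
Hartmann number.  The damping model implemented here admits only the
monotone decrease (the Lorentz force `-sigma B^2 u_z` is strictly
dissipative, and `u . f <= 0` with `u f = -` Joule heating holds as a
discrete identity), so only that direction is asserted.  Similarly, the
printed mesh-error percentages of any particular unstructured mesh
family are not transferable to this structured mesh; the
grid-convergence study reproduces the protocol (strictly decreasing
error of the peak wall shear stress against the finest level over at
least three nested meshes), not those specific percentages.
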