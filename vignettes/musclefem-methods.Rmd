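---
title: "Active muscle finite elements: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active muscle finite elements: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`musclefem` simulates active skeletal muscle as an incompressible,
transversely isotropic hyperelastic continuum with a Hill-type fiber
stress, discretized by linear tetrahedra in a total-Lagrangian setting and
driven through quasi-static load/activation schedules. This vignette is
the package's own account of the model, the numerical machinery behind it,
and the design decisions taken where the problem statement left the design
open. Everything quantitative shown here is computed by the test suite or
the worked examples; nothing is quoted from elsewhere.

## The constitutive model

The muscle strain energy density per unit reference volume is

$$U = \kappa\,(J-1) \;+\; c\left(e^{b(\tilde I_C - 3)} - 1\right)
      \;+\; U_{PE}(\tilde\lambda_f) \;+\;
      U_{CE}(\tilde\lambda_f;\dot{\tilde\lambda}_f,\alpha),$$

with $J = \det F$, the reduced invariant
$\tilde I_C = J^{-2/3}\operatorname{tr} C$, and the isochoric fiber
stretch $\tilde\lambda_f = \sqrt{J^{-2/3}\, N^T C N}$ along the reference
fiber direction $N$. The exponential term is the isotropic matrix that
embeds the fibers (defaults $c = 3.795\times10^{-4}$ MPa, $b = 23.46$);
note its very low small-strain shear modulus, about $2bc \approx 0.018$
MPa, which dominates much of the numerical behaviour discussed below.

The fiber energy follows the Hill three-element picture. The passive
branch integrates
$f_{PE} = 2aA\,e^{a(\tilde\lambda_f-1)^2}(\tilde\lambda_f-1)$ for
$\tilde\lambda_f > 1$ (zero below slack length; closed form
$T_0^M A (e^{a(\tilde\lambda_f-1)^2}-1)$), with $A = 8.568\times10^{-4}$,
$a = 12.43$, and maximal nominal fiber stress $T_0^M = 0.535$ MPa. The
contractile branch is
$T_{CE} = T_0^M f_{LCE}(\tilde\lambda_f)\, f_{VCE}(\dot{\tilde\lambda}_f)\,
\alpha(t)$ with the parabolic force-length curve
$f_{LCE} = 1 - 4(\tilde\lambda_f-1)^2$ on $[0.5, 1.5]$ and a
force-velocity curve that vanishes at shortening rates at or below
$-10\,\mathrm{s^{-1}}$, equals
$-\arctan(-0.5\dot{\tilde\lambda}_f)/\arctan 5 + 1$ up to
$2\,\mathrm{s^{-1}}$, and plateaus at $\pi/(4\arctan 5)+1 \approx 1.57$
for faster lengthening. Fast- and slow-twitch fiber populations mix by
cross-sectional area fraction,

$$T = T_0^M\left[\mu_{SO}\,(f_{PE} + f_{LCE} f_{VCE}\,\alpha_{SO})
      + \mu_{FG}\,(f_{PE} + f_{LCE} f_{VCE}\,\alpha_{FG})\right],$$

which reduces exactly to the single-population law when the activations
coincide.

The second Piola-Kirchhoff stress is the exact strain derivative of $U$
plus the incompressibility term $\lambda\,\partial W/\partial E$ with
constraint function $W = J^2 - 1$:

$$S = \kappa J C^{-1}
  + 2bc\,e^{b(\tilde I_C-3)}\left(J^{-2/3} I - \tfrac13 \tilde I_C C^{-1}\right)
  + T\left(J^{-2/3}\tilde\lambda_f^{-1}\,N\!\otimes\!N
      - \tfrac13\tilde\lambda_f C^{-1}\right)
  + \lambda\, 2J^2 C^{-1}.$$

Two modelling notes. First, the matrix-term exponent: applying the chain
rule to $\tilde I_C = J^{-2/3}\operatorname{tr}C$ yields the $J^{-2/3}$
factor shown; a printed form with a $J^{-3/2}$-type exponent circulates
in the source literature but fails a central-difference check of
$S = \partial(U + \lambda W)/\partial E$, so the package implements the
chain-rule-consistent derivative (the test suite verifies agreement with
the finite-difference oracle to $10^{-5}$ relative on random states).
Second, the volumetric term $\kappa(J-1)$ with $\kappa = 2$ MPa is kept
exactly as the model states it; its gradient $\kappa J C^{-1}$ is balanced
at the reference state by the constraint term when the multiplier starts
at its rest value $-\kappa/2$, which makes the undeformed mesh exactly
stress-free. $\kappa$ is exposed as `kappa_vol` in `muscle_params()`.

The stretch rate $\dot{\tilde\lambda}_f$ is computed by first-order
backward difference over the time increment, and $f_{VCE}$ is treated as
*frozen* at the current rate inside the energy and the stress: the rate
enters parametrically, not variationally. The contractile energy
integrates $f_{LCE}$ over stretch by adaptive quadrature with the frozen
velocity factor outside the integral.

Bone and tendon are St. Venant-Kirchhoff solids,
$S = \lambda_m \operatorname{tr}(E)\,I + 2\mu E$, with
$(\mu, \lambda_m) = (6154, 9231)$ MPa for cortical bone and $(56, 9296)$
MPa for tendon. The law is linear in $E$ and therefore exact under the
large rotations the forearm undergoes.

## Activation dynamics

Constant neural excitation $u \in [0, 0.5]$ drives the activation level
through first-order dynamics whose closed-form solution the package uses
directly:
$\alpha(t) = \alpha_{ss}(1 - e^{-kt})$ with
$k = u/\tau_{rise} + (1-u)/\tau_{fall}$ and
$\alpha_{ss} = (u/\tau_{rise} + \alpha_{min}(1-u)/\tau_{fall})/k$. With
$u = 0.5$, $\tau_{rise} = 0.02$ s, $\tau_{fall} = 0.2$ s and
$\alpha_{min} = 0$ the steady state is $10/11 \approx 0.91$. The floor
$\alpha_{min}$ has no published value; the package sets it to zero, which
is the choice that reproduces the 0.91 ceiling. Fiber types differ only
in their time constants (fast twitch 0.1/1.0 s, slow twitch 0.3/3.0 s),
so both populations share the steady state but the fast-twitch population
rises about three times faster. The contraction-velocity scenarios use
piecewise-linear ramps to $\alpha_{max} = 0.91$ instead, with the ramp
duration as the swept parameter.

Deactivation (switching $u$ off mid-run) is out of scope: all studies
hold $u$ constant.

## Fiber directions from a Laplace field

Fiber directions on the muscle region come from a harmonic interpolant:
a linear-tetrahedron Galerkin solve of $\nabla^2\varphi = 0$ with
$\varphi = 0$ on the proximal attachment cross-section and $\varphi = 1$
on the distal one, followed by the element-constant gradient of the
interpolant, normalized, with the sign fixed along the source-to-sink
centroid axis. The Dirichlet sets are a package choice (the description
this mimics names no boundary sets), as is the per-element rather than
nodal representation — linear tetrahedra carry element-constant gradients,
and no smoothing is applied. On a straight cylinder the potential is
exactly linear and the directions recover the axis to solver round-off;
on the synthetic fusiform muscle the mean angular deviation from the
generative centerline is below 10 degrees (both are asserted by tests).

## Mixed discretization and the multiplier space

Displacements use linear tetrahedra (one quadrature point); the
incompressibility constraint is enforced weakly, element-integrated, with
element-constant multipliers: each constrained element contributes a row
$\int_{\Omega_e} \delta\lambda\, W \, d\Omega = \delta\lambda_e V_e
(J_e^2-1)$, volume-scaled for conditioning. The residual couples to the
multiplier linearly, so the displacement-multiplier blocks of the tangent
are analytic; the displacement block is a numerical consistent tangent —
central differences of each element residual with respect to its own
twelve nodal displacements (step $10^{-6}$ mm) — which includes the
geometric stiffness exactly and sidesteps hand-derivation errors in the
typo-prone stress expression.

Two well-known pathologies of this element pair shaped the solver design:

* **Checkerboard multiplier modes.** On structured tetrahedral meshes the
  per-element constraint gradients are linearly dependent; the
  element-constant multiplier space contains near-null "checkerboard"
  combinations, and the raw KKT system is singular. The package offers
  two mitigations. A consistent perturbed-Lagrangian stabilization
  (`stabilization`, default $10^{-7}$) regularizes the constraint
  residual to $V_e(J^2-1) - \varepsilon V_e(\lambda_e - \lambda_{rest})$,
  leaving the reference state exact and perturbing $|J-1|$ only at order
  $\varepsilon\times$pressure. And the mean-dilatation option
  (`constraint = "patch"` in `fem_model()`) assigns one multiplier per
  generator hex patch (six tetrahedra), which removes the degeneracy
  altogether and also relieves volumetric locking.
* **Volumetric locking.** Exact per-element incompressibility on linear
  tetrahedra over-constrains bending-dominated deformation. The forearm
  studies therefore run with the patch constraint and an
  augmented-Lagrangian penalty that evaluates the constraint stress with
  multiplier $\lambda_e + \rho(J^2-1)$: the penalty keeps the volumetric
  deviation small along the Newton path while the patch multipliers
  enforce the patch-average constraint exactly at convergence; the
  converged mixed solution is independent of $\rho$. The attainable
  penalty is regime-dependent — stiff penalties break the Newton path
  through the weak-tone load transient — so the studies stage it: a
  robust 2000 MPa during the transient and 8000 MPa (or the stiffest
  level at which every case of a sweep converges; all cases of a sweep
  share one level so their comparison shares numerics) afterwards. The
  worst per-element $|J-1|$ across the study trajectories is then about
  $1\times10^{-3}$ for the velocity, composition and strength studies
  and about $1.4\times10^{-3}$ for the lowest-excitation case of the
  excitation study, whose muscle never develops enough tone to carry a
  stiff penalty. The element-exact layout (`constraint = "element"`)
  remains the default for small and homogeneous problems (the uniaxial
  validation enforces per-element $J = 1$ to $10^{-6}$), but on the
  forearm geometry its degenerate multiplier space makes the Newton path
  unreliable; per-element deviations on the forearm are bounded by the
  penalty, not driven to zero, and this is recorded as a known
  limitation.

## Globalized Newton solution

Each quasi-static increment solves the coupled system for displacements
and multipliers with a damped Newton method, Dirichlet elimination, and a
sparse LU solve. Globalization is a watchdog scheme tuned to the two
stiffness regimes this problem mixes:

* Full steps are accepted speculatively whenever the candidate state
  assembles without element inversion. The stiff bone rotating through
  tens of degrees makes the first Newton step overshoot quadratically
  (the St. Venant-Kirchhoff response to a linearized rotation), and the
  iteration recovers in a few steps; a monotone line search would stall
  on exactly this path.
* Every new best residual checkpoints the state. If no progress occurs
  within a few iterations, the checkpoint is restored and the iteration
  switches to a strict backtracking line search; persistent failure is
  reported to the caller, which bisects the load/activation increment
  (continuation between the last converged and the target inputs, with
  adaptive re-doubling). This subsumes plain time-step halving and is
  what carries the runs through the application of the distal load.
* A trust region caps the largest nodal displacement component per step
  (25 mm default), and a second cap limits the per-iterate change of any
  muscle element's fiber stretch whenever the muscle is activated
  (`rate_cap`, default 4 s$^{-1}$ times the time step). The
  force-velocity relation acts as a narrow viscous well — its slope
  $\sim f'_{VCE}/\Delta t$ dominates the activated muscle tangent but
  decays away from zero rate — and iterates that jump outside the well
  lose the damping stiffness and diverge. Converged increments move the
  physical stretch far less than the cap, so the cap only disciplines
  transient iterates.

Convergence requires the force residual to drop below `tol` (relative,
$10^{-6}$) times the external load scale and the constraint deviation
below `tol_J` ($10^{-5}$). On a single element the converged iteration
exhibits the superlinear tail expected of a consistent tangent (asserted
by a convergence-order test).

The constant-load schedule of the sarcopenia studies is brought in over a
short ramp (`ramp_in`, 0.2 s in the study configuration): a quasi-static
state cannot jump at $t = 0$, and the window is long enough that even
the weakest swept case (neural excitation 0.1) has developed activation
tone by the time the full load is carried. The trajectories reported by
the studies all use the same schedule, so within-study comparisons are
unaffected.

## Synthetic geometry

The study geometry emulates a forearm with three conforming regions built
from structured hex blocks split into tetrahedra (Kuhn subdivision, which
keeps shared block interfaces conforming): a slender cylindrical radius
along $+x$ (250 mm long, 8 mm radius), a fusiform biceps on an inclined
axis in the sagittal plane (200 mm long, 32 mm mid-belly radius,
sinusoidal profile), tendon straps continuing both muscle ends, and an
insertion bridge that continues the muscle axis down to a patch of bone
surface nodes near 30% of the bone length. Cross-sections map a square
grid onto the disc with an area-preserving scaling, so region volumes
match their generative solids to a few percent (tested at 5%). The
tapered ends of the fusiform profile below 45% of the maximal radius are
labelled tendon (aponeurosis): the narrow necks funnel the entire muscle
force, and treating them as contractile tissue concentrates stretch in a
few soft elements and destabilizes the solve — anatomically they are
collagenous anyway. The bridge continues the muscle axis rather than
descending vertically for the same reason: a kinked force path bends the
very soft belly and wrinkles it.

The hinge is emulated, not modelled: the proximal tendon cap is fully
fixed (the muscle origin), a single node at the proximal bone end is
pinned, and nodes within 10% of either bone end are restrained
mediolaterally; the load (up to 100 N) pulls the distal bone end cap
straight down. The default muscle inclination (50 degrees) and insertion
position were chosen once so that the passive droop under full load stays
in a regime the discretization handles, and are documented here as
package choices; peak-angle magnitudes on this geometry are not
comparable to any specific anatomy, which is why the studies report
orderings, linearity and threshold behaviour rather than absolute angles.

With zero activation and the full 100 N held, the arm droops by a few
tens of degrees before activation lifts it; the flexion angle is measured
between the current and reference pin-to-load-end axis projected on the
sagittal plane, positive upward, exact on rigid rotations.

## Study protocols and problem sizes

* *Contraction velocity*: linear activation ramps to 0.91 over 0.05, 0.20
  and 1.00 s, load ramped with activation; each case runs to its own ramp
  end with $\Delta t = t_{peak}/50$, and the angle there is the case's
  peak. The fast ramp flexes least because rapid shortening suppresses
  fiber force through the force-velocity relation.
* *Fiber composition*: fast-twitch fractions 58/51/44% under constant
  load with excitation-driven dynamics per fiber type; peak angle is
  expected linear in the fraction (the mixture enters the stress
  linearly), and onset of elevation is earliest for the fast-rich case.
* *Maximum stress*: $T_0^M$ scaled 1.0 down to 0.7 (young composition
  otherwise); near-linear peak response.
* *Neural excitation*: $u$ from 0.5 down to 0.1; the steady state
  $\alpha_{ss}(u) = 10u/(9u+1)$ saturates, so the peak angle declines
  gently above $u = 0.2$ and sharply below it — the threshold behaviour
  the excitation study quantifies with separate slopes on either side.

The packaged defaults run the sarcopenia studies at $\Delta t = 0.01$ s
over 1.5 s. The test suite and worked examples use a deliberately
smaller problem — 18 mm target edge length (about 750 elements, of which
roughly 260 are muscle), $\Delta t = 0.015$ s, 1.2 s window — chosen so
the full study battery solves in minutes while leaving every asserted
property (orderings, fit quality, threshold contrast) unchanged in sign
and comfortable in margin. Sweep values, loads and material constants
are never scaled down.

## What the synthetic data can and cannot show

The generator emulates the load-bearing topology of a forearm — origin
fixation, a compliant actuated link, a stiff lever, a distal load — and
that is what the parametric trends exercise. It does not reproduce
subject-specific geometry: muscle wrapping, contact with the humerus,
synergist muscles, pennation, or realistic insertion footprints are all
absent, and peak-angle magnitudes (here around 6-12 degrees at test
resolution) therefore carry no anatomical meaning. Passing studies show
that the implementation propagates fiber mixture, maximum stress and
excitation into motion outcomes with the correct monotonicity, linearity
and threshold structure — not that any specific angle value would be
reproduced on real anatomy.

## Numerical choices, degenerate inputs, limitations

* Units are mm / N / MPa / s throughout; gravity and inertia are
  neglected (quasi-static increments; the potential has no kinetic term).
* Branch points of $f_{PE}$, $f_{LCE}$, $f_{VCE}$ are continuous but not
  smooth; the finite-difference tangent averages across them, which is
  harmless at the default step.
* Non-positive Jacobians raise a structured error naming the element;
  meshes without region labels are rejected rather than defaulted;
  degenerate (zero-gradient) fiber elements are reported by index.
* Determinism: generation and solves contain no randomness beyond the
  optional seeded mesh jitter; repeated study runs produce bitwise-equal
  trajectories and CSV exports (tested).
* Known limitations: element-exact incompressibility is unreliable on
  the forearm geometry (see the multiplier-space discussion); the
  force-velocity well makes activated solves stiff at small time steps;
  and the rate is resolved only to first order in $\Delta t$, so the
  contraction-velocity study's medium/slow contrast is small and
  protocol-sensitive.
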