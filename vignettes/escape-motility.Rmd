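---
title: "Modelling escape motility of multicellular magnetotactic prokaryotes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling escape motility of multicellular magnetotactic prokaryotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mmpsim simulates the magneto-aerotactic behaviour of multicellular
magnetotactic prokaryotes (MMPs) near an oxygenated interface, at two
levels of description — non-interacting point particles and finite-size
squirmers with near-field hydrodynamics — together with the statistics
used to compare either level with cell-tracking data. This vignette is the
package's account of the model, its parameters, the numerical choices, and
what the implementation does and does not capture.

## The stochastic point model

A colony is an overdamped self-propelled point. Its orientation relaxes
toward the magnetic field direction `phi_B` at the alignment rate `k`
(`dphi/dt = k sin(phi_B - phi)` plus rotational noise), and it translates
along its orientation at a signed speed: `+v_jump` in jump mode (parallel)
or `-v_return` in return mode (antiparallel). Oxygen enters the fluid
(`x >= 0`) from the interface at `x = 0` and follows the 1-D diffusion
solution `C(x,t) = C0 erfc(x / 2 sqrt(D_C t))`. Each colony updates a
reversal rate every timestep from two bits of information: the local
concentration relative to the threshold `c* = 2.5` uM, and whether it is
currently swimming along (`d = +1`) or against (`d = -1`) the field. The
rate is the increased `lambda_plus` when the two disagree with the
favourable configuration — high oxygen while swimming against the field,
or low oxygen while swimming along it — and the basal `lambda_minus`
otherwise. Reversals flip only the sign of the propulsion; the orientation
vector continues to evolve by the alignment equation alone.

Two consequences of these equations are worth stating explicitly, because
they fix the phenomenology the tests assert:

* a colony pressed against the interface in jump mode (facing the field,
  high oxygen, `d = +1`) waits an `Exp(lambda_minus)` time before it
  reverses — this is what makes the never-departed fraction at a finite
  observation time an estimator of `lambda_minus`;
* the outbound leg of an excursion runs in return mode at `v_return` with
  reversal rate `lambda_plus` (mean duration `1/lambda_plus ~ 2.4` s, so a
  typical excursion reaches ~18 um), and the colony races back at
  `v_jump`. The long-run fraction of interface-facing ("left") swimmers is
  `lambda_plus / (lambda_plus + lambda_minus) ~ 0.91`, approached at the
  relaxation rate `lambda_plus + lambda_minus`.

The decision logic therefore produces *fast inbound, slow outbound*
shuttling. Tracking-based phase nomenclature often labels the outbound leg
the "jump"; in this model the jump *mode* is the interface-facing one, and
the phase segmentation in `segment_phases()` deliberately labels phases by
direction of motion (J = away from the interface, R = toward it,
T = slower than `speed_lo`), not by which mode speed they match, so it
applies unchanged to experimental tables. A fixed three-band speed rule
keyed to `v_jump` would leave the model's outbound legs unlabelled.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `phi_B_rad` | 2.7 | rad | field direction (fitted escape-jump direction); points toward the interface |
| `k_per_s` | 10 (point), 50 (lattice protocol) | 1/s | alignment rate `1/tau_B`; convert physical magnetics with `alignment_rate()` |
| `v_jump_um_s`, `v_return_um_s` | 26.6, 7.6 | um/s | fitted mode speeds |
| `lambda_minus_per_s`, `lambda_plus_per_s` | 0.0413, 0.4186 | 1/s | fitted reversal rates |
| `C0_uM`, `D_C_um2_s` | 250, 2000 | uM, um^2/s | air-saturated boundary concentration and oxygen diffusivity in water — conventional values; the erfc profile itself is the modelled quantity |
| `c_star_uM` | 2.5 | uM | sensing threshold |
| `D_um2_s`, `D_r_rad2_s` | 0.05, 0.002 | um^2/s, rad^2/s | Stokes–Einstein diffusivities for a 4.3 um sphere in water at 298 K |
| `a_um` | 4.3 | um | mean colony radius |

The standard protocol (the `default_config("point")`) releases 150
colonies at the interface, oriented along the field toward it, in jump
mode with the basal rate, and records 17 s. Initial positions carry a
`U(0, a)` jitter in `x` (toggleable via `init$jitter_um`) so that
finite-size placements do not start degenerate.

### Numerical choices

* Euler–Maruyama with `dt = 1e-3` s for the point engine; all right-hand
  sides are evaluated at the old state, three independent Wiener
  increments per colony per step. Convergence of the deterministic
  alignment error is first order in `dt` and checked by halving in the
  tests against the closed form
  `tan((phi_B - phi)/2) = tan((phi_B - phi0)/2) exp(-k t)`.
* The reversal process is a per-step Bernoulli hazard
  `1 - exp(-lambda dt)`, exact for a rate held constant over a step; the
  memoryless waiting-time description and the hazard implementation
  coincide for the piecewise-constant `lambda(t)` the decision function
  produces. A hard error at `lambda dt > 1` and a warning above 0.1 guard
  the discretisation; a stability guard requires `k dt < 0.5`.
* The interface is a clamped reflecting boundary (`x >= 0`): colonies
  oriented into it stay pressed at `x = 0` while continuing to rotate and
  sense. The boundary rule is a modelling choice; nothing in the
  continuum equations prescribes it.
* Angles are wrapped to `(-pi, pi]` every step; the direction-indicator
  tie (`v p . B = 0`) goes to `+1`, matching the printed inequality.
* With oxygen sensing disabled (the oil-interface control,
  `oxygen$enabled = FALSE`) concentration queries return 0 **and the
  reversal process is silent** (rate 0). Feeding `c = 0` through the
  decision function instead would put interface-facing colonies in the
  *high*-rate branch and disperse the population — the opposite of the
  observed control, in which removing the oxygen source removes the
  escape response altogether. The same flag implements "aerotaxis off" in
  the squirmer protocols.

## The squirmer model

Finite colony size matters in the packed accumulation region, so the
second engine represents each colony as a 2-D spherical squirmer of
radius `a` near a rigid no-slip wall (the rigid-wall approximation of the
air–water interface), with tangential surface slip
`u_s = B1 sin(theta)(1 + beta cos(theta))`, `B1 = 3/2` times the signed
swim speed, puller `beta = 1` by default (configurable). The magnetic
dipole is along the swimming axis; its torque is parameterised through
`k` so that an isolated body obeys the same alignment equation as the
point model — the two engines coincide exactly in the isolated,
noise-free limit, and the tests assert it.

### Interaction closure

Near-field interactions use leading-order lubrication resistances
evaluated on the *relative surface velocity* at the closest points of a
pair (or body and wall):

* normal squeeze resistance `C_n ~ pi eta a^2 / gap` (sphere–wall
  coefficient 6, reduced-radius pair coefficient 3/2), resisting
  approach and diverging as the gap closes;
* tangential resistance `C_t ~ (pi/2) eta a log(gap_cut/gap)`, coupling
  sliding, rotation and the ciliary slip — because the slip enters the
  relative surface velocity, tightly packed squirmers drive forces and
  torques on each other even when their centres are at rest. This is the
  term that destabilises a wall-facing colony (a head-on orientation is an
  unstable equilibrium) and scrambles the lattice when the magnetic
  torque is weak;
* the steric repulsion `rep_strength * exp(-gap/rep_range) /
  (1 - exp(-gap/rep_range))` along the line of centres.

Both resistances are tapered to zero at the neighbour cutoff (3 colony
radii centre-to-centre) so forces vanish continuously; gaps are clamped at
`contact_eps * a = 1e-3 a` inside the force laws. The order-one
lubrication coefficients are classical sphere–sphere/sphere–wall values
and are exposed as config multipliers (`lub_normal`, `lub_tangential`);
the contract they implement — divergent normal resistance, logarithmic
tangential coupling, no overlap — is the modelled physics, not any
particular tabulated kernel, and statistics derived from this engine
should be read as approximate.

Every step assembles the 3N-dimensional overdamped force/torque balance
`(R_iso + R_lub) V = F_thrust + F_steric + T_magnetic + slip drive` and
solves it directly (dense LU), which treats each body's mobility as the
isolated-sphere mobility corrected by all pairwise resistances within the
cutoff and makes the stiff lubrication terms implicit in the velocities.
Far-field flow beyond the cutoff is neglected (disturbances decay at
least as `1/r^2`). The domain is periodic in `y` with width defaulting to
the lattice width; the wall occupies `x = 0`.

### Numerical choices

* `dt = 5e-4` s by default. With the velocity solve implicit in the
  resistances and gaps clamped, this step is stable for the protocols
  shipped (including `k = 50`, where `k dt = 0.025`) and halving it does
  not change the reported statistics beyond their Monte-Carlo spread. The
  integrator halves the step automatically (up to six times) if the
  linear solve fails.
* After each position update a few Gauss–Seidel projection sweeps remove
  any residual overlap by separating offending pairs symmetrically along
  the line of centres and re-clamping at the wall. Clamped finite
  resistances otherwise let pressed configurations creep a few percent of
  a radius into each other over thousands of steps; the projection keeps
  every gap non-negative to within ~0.5% of a radius, which the tests
  assert on crowded runs.
* The reversal process is identical to the point engine, evaluated at
  each colony's own position.

### Standard protocols

`protocol_k_sweep()` runs the dispersal–condensation experiment: 100
colonies (10 x 10 hexagonal lattice, spacing 2.2 radii) uniformly aligned
with the field into the wall (`Phi(0) = 1`), aerotaxis off, 60 s per run,
with the time-averaged order parameter and its standard deviation taken
over the trailing 50 s. Per-run seeds derive deterministically from the
master seed with a fixed stride, so extending a sweep never perturbs
completed runs. For these wall-normal protocols the configs set
`phi_B = pi`; the fitted 2.7 rad belongs to the tilted escape geometry of
the point protocol. At full scale the fluctuation maximum sits at a small
non-zero `k` between the dispersed (`<Phi> < 0`) and condensed
(`<Phi> ~ 1`) regimes; at the reduced lattice sizes the test suite uses
(3 x 10, 30 s), the same non-monotonicity appears with the peak shifted
to slightly smaller `k` (~1 s^-1) because fewer neighbours disturb each
body. The acceptance script reports the full-scale `k = 0` dispersal
time — the first time the running `Phi` falls below zero.

`protocol_lattice_escape()` measures escape through the lattice: a strong
field (`k = 50`) holds an `n x 10` lattice at the wall with aerotaxis on,
and each reversal into the outbound mode initiated in the wall-adjacent
region (`x <= 2.5 a`, i.e. the first layer) is an *attempt*, successful
if the colony passes the success threshold before reversing back.
Restricting attempts to the wall layer is deliberate: under this model's
short outbound excursions, attempts launched from the outer layers of a
deep lattice start closer to any fixed threshold and would mask the
blocking effect the statistic is meant to isolate. The default threshold
is 16 colony radii (roughly the outer edge of an eight-layer packed
structure); the reduced-scale tests use 6 radii, commensurate with the
model's outbound excursion scale `v_return / lambda_plus ~ 18` um ~ 4
radii, so that depth ordering is statistically resolvable with feasible
run lengths.

## Estimation

`fit_switching_rates()` packages the two estimators: `lambda_minus` from
the never-departed fraction (`-log(n_stayed/n_total)/t_final`; the
engines' reversal event log dates departures by the initiating reversal,
so the estimate is free of the travel-time censoring a pure position
threshold induces — for external tables without an event log the
threshold fallback is used) and `lambda_plus` as the converged left:right
count ratio times `lambda_minus`, pooled over the trailing 5 s window
(exposed; the relaxation rate `lambda_plus + lambda_minus ~ 0.46` s^-1
makes 12 s ample burn-in for a 17 s record). Colony-level bootstrap
percentile intervals quantify the sampling noise; the acceptance tests
verify recovery of both generating rates across 100 replicate runs of the
standard protocol.

## What the generator emulates, and limits

The synthetic runs emulate the study conditions: 150 colonies / 17 s for
the point protocol, `n x 10` lattices, 100 colonies / 60 s for the
squirmer sweeps, fitted speeds and rates, oxygen entering at `t = 0`.
They do not emulate sensory noise in the concentration measurement
(deliberately omitted), oxygen consumption or advection, 3-D motion or
helical swimming with body rotation, stress-free (free-surface)
hydrodynamics at the interface, field-strength-dependent switching rates,
or colony-to-colony variability in speeds and radii. Passing tests
therefore show that the implementation realises *this* model faithfully —
not that the model captures every feature of real tracking data; in the
experiments the apparent overlap of cells is a 2-D projection artefact,
and multilayer sliding in 3-D can relieve blocking that is absolute in a
2-D lattice. The escape-success statistics inherit the interaction
closure's approximations and should be compared across conditions
(ordering, trends) rather than as absolute fractions.
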