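# mmpsim

Agent-based simulation and analysis of the magneto-aerotactic **escape
motility** of multicellular magnetotactic prokaryotes (MMPs).

MMPs are spherical colonies of 4–16+ flagellated bacteria that swim as a
single unit and carry a net magnetic dipole. Near an oxygenated air–water
interface, with a strong magnetic field normal to the interface, they pack
into a dense lattice against the interface and shuttle back and forth along
the field lines — abrupt, coordinated reversals of the whole colony's
ciliary beating ("escape" or "ping-pong" motility). This package is for
biophysicists and quantitative microbiologists who want to simulate that
behaviour, fit its switching rates from tracking data, and study how
near-field hydrodynamics shape the collective dynamics at the interface.

## The model

**Point engine.** Each colony is an overdamped self-propelled point with
position $(x, y)$ and orientation $\phi$:

$$
\dot\phi = k\,\sin(\phi_B - \phi) + \sqrt{2D_r}\,\xi_\phi,\qquad
\dot x = \tilde v\cos\phi + \sqrt{2D}\,\xi_x,\qquad
\dot y = \tilde v\sin\phi + \sqrt{2D}\,\xi_y,
$$

where $k = 1/\tau_B = \|m\|\|B\|/(8\pi\eta a^3)$ is the magnetic alignment
rate toward the field direction $\phi_B$, and the signed speed is
$\tilde v = +v_\mathrm{jump}$ (parallel to the orientation) or
$-v_\mathrm{return}$ (antiparallel). Oxygen diffuses in from the interface
at $x = 0$ as $C(x,t) = C_0\,\mathrm{erfc}\!\big(x / 2\sqrt{D_C t}\big)$.
Each colony carries a reversal rate $\lambda(t) \in
\{\lambda_-, \lambda_+\}$ set every instant by a decision function: the
increased rate $\lambda_+$ when it senses high oxygen
($c \ge c^\* = 2.5\,\mu M$) while swimming against the field, or low oxygen
while swimming along it; the basal rate $\lambda_-$ otherwise. Reversals
flip the sign of $\tilde v$.

**Two-state chain.** Once the oxygen front has passed the population, the
left/right swimming state reduces to a continuous-time Markov chain with
generator rows $(-\lambda_-, \lambda_-)$ and $(\lambda_+, -\lambda_+)$,
stationary law $\pi = (\lambda_+, \lambda_-)/(\lambda_+ + \lambda_-)$ and
relaxation rate $\lambda_+ + \lambda_-$. This yields the two estimators
implemented in `fit_switching_rates()`:
$\hat\lambda_- = -\log \Pr(T \ge t_\mathrm{final})/t_\mathrm{final}$ from
the fraction of colonies that never depart the interface, and
$\widehat{\lambda_+/\lambda_-}$ from the converged left:right count ratio.
Fitted defaults throughout: $\phi_B = 2.7$ rad, $v_\mathrm{jump} = 26.6$
and $v_\mathrm{return} = 7.6\,\mu m\,s^{-1}$, $\hat\lambda_- = 0.0413$ and
$\hat\lambda_+ = 0.4186\,s^{-1}$, colony radius $a = 4.3\,\mu m$.

**Squirmer engine.** For the dense lattice at the interface, colonies are
finite-size spherical squirmers (puller, $\beta = 1$) near a rigid wall.
Near-field interactions use leading-order lubrication resistances (normal
$\sim 1/\mathrm{gap}$, tangential $\sim \log 1/\mathrm{gap}$) acting on the
relative *surface* velocity — which includes the ciliary slip, so closely
packed squirmers exert forces and torques on each other even at rest —
plus an exponential steric repulsion and the magnetic torque
$\tau = m \times B$. Every step solves the overdamped force/torque balance
for all bodies simultaneously (zero net force and torque on each). The
engine reproduces lattice formation under strong fields, blocked escape
jumps, and the dispersal–condensation transition measured by the order
parameter $\Phi(t) = \tfrac1N\sum_i \cos(\phi_i - \phi_B)$.

## Worked example

Simulate the standard escape protocol (150 colonies released at the
interface, fitted parameters, 17 s) and re-estimate the switching rates
from the synthetic record:

```r
library(mmpsim)
cfg <- default_config("point")   # 150 colonies, 17 s, fitted parameters
ts  <- run_point_simulation(cfg)
ts
#> <trajectory_set: point engine, 150 colonies, 516 frames, t = 0..16.995 s>
#>   seed 1, config hash 675aff08, 175 reversal events
summary(fit_switching_rates(ts))
#> Two-state switching-rate fit
#>   lambda_minus = 0.0416 s^-1  (from 74/150 never-departed over 16.995 s)
#>   lambda_plus  = 0.4122 s^-1  (left:right = 9.914 over trailing 5 s)
#>   bootstrap percentile intervals:
#>               2.5 %  97.5 %
#> lambda_minus 0.0341  0.0510
#> lambda_plus  0.2886  0.6453
#> ratio        7.0389 16.1322
#>   implied stationary law: pi_left = 0.9084, pi_right = 0.0916
#>   implied relaxation rate: 0.4538 s^-1
```

The fit recovers the generating rates (0.0413, 0.4186): about half the
colonies never depart in 17 s — that fraction is what pins
$\hat\lambda_-$ — and roughly ten colonies swim toward the interface for
every one swimming away, the stationary ratio $\lambda_+/\lambda_-$.
`excursion_stats(ts)` adds the per-colony excursion statistics (mean
outbound distance ~21 µm here), `plot(ts)` the shuttling trajectories.

Squirmer runs are configured the same way:

```r
cfg <- default_config("squirmer")
cfg$environment$magnetic$k_per_s <- 50   # strong field: rigid lattice
ts  <- run_squirmer_simulation(cfg)
escape_success_rate(ts, success_threshold_um = 6 * 4.3)
```

`protocol_k_sweep()` and `protocol_lattice_escape()` run the two standard
sweeps (field-strength dependence of the order parameter; escape success
vs lattice depth). A thin command-line front end with `simulate`,
`analyze`, `ctmc` and `sweep` subcommands is installed at
`inst/scripts/mmpsim`, with example YAML configs under `inst/extdata/`.

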