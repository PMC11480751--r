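## Finite-size squirmer engine: R-level constructors, single interaction
## evaluators (for inspection and testing) and the run wrapper around the
## compiled resistance-solve integrator.

#' Squirmer interaction parameters
#'
#' Finite-size colony model: spherical squirmers of radius `a` with
#' squirming parameter `beta` (> 0: puller), interacting through
#' leading-order lubrication resistances (normal ~ `1/gap`, tangential ~
#' `log(1/gap)`, both tapered to zero at the neighbour cutoff) evaluated on
#' the relative *surface* velocity — which includes the ciliary slip, so
#' close swimmers drive forces and torques on each other even at rest — and
#' an exponential steric repulsion
#' `rep_strength * exp(-gap/rep_range) / (1 - exp(-gap/rep_range))`.
#' Gaps below `contact_eps * a` are clamped in the resistance and steric
#' laws.  With `eta` in Pa s, lengths in um and speeds in um/s, forces come
#' out directly in pN (1 Pa s x um^2 / s = 1 pN), so water is
#' `eta_Pa_s = 1e-3`.
#'
#' @param beta squirming parameter (dimensionless), default 1 (puller).
#' @param a_um colony radius (um).
#' @param eta_Pa_s fluid viscosity (Pa s).
#' @param contact_eps minimum-gap regularisation, fraction of `a`.
#' @param rep_strength_pN steric repulsion amplitude (pN).
#' @param rep_range_um steric decay length (um).
#' @param neighbor_cutoff centre-to-centre interaction cutoff (units of `a`),
#'   must exceed 2.
#' @param lub_normal,lub_tangential order-one multipliers on the two
#'   lubrication resistances.
#' @param domain_width_um periodic width in `y` (`NULL` or <= 0: open).
#' @return an object of class `"squirmer_params"`.
#' @export
squirmer_params <- function(beta = 1, a_um = 4.3, eta_Pa_s = 1e-3,
                            contact_eps = 1e-3, rep_strength_pN = 2,
                            rep_range_um = 0.215, neighbor_cutoff = 3,
                            lub_normal = 1, lub_tangential = 1,
                            domain_width_um = NULL) {
  stopifnot(is.finite(beta), a_um > 0, eta_Pa_s > 0, contact_eps > 0,
            rep_strength_pN >= 0, rep_range_um > 0, neighbor_cutoff > 2)
  structure(list(beta = beta, a_um = a_um, eta_Pa_s = eta_Pa_s,
                 contact_eps = contact_eps, rep_strength_pN = rep_strength_pN,
                 rep_range_um = rep_range_um,
                 neighbor_cutoff = neighbor_cutoff, lub_normal = lub_normal,
                 lub_tangential = lub_tangential,
                 domain_width_um = domain_width_um),
            class = "squirmer_params")
}

## internal: parameter list in the layout the C++ side expects
sq_par_list <- function(p) {
  list(a = p$a_um, eta = p$eta_Pa_s, beta = p$beta,
       contact_eps = p$contact_eps, rep_strength = p$rep_strength_pN,
       rep_range = p$rep_range_um, cutoff = p$neighbor_cutoff,
       lub_n = p$lub_normal, lub_t = p$lub_tangential,
       width = if (is.null(p$domain_width_um)) -1 else p$domain_width_um)
}

#' Hexagonal lattice initial placement
#'
#' Places `n_layers` rows of `n_per_layer` colonies in hexagonal close
#' packing against the wall at `x = 0`: row `r` sits at
#' `wall_offset + (r-1) * spacing * a * sqrt(3)/2`, with alternate rows
#' offset laterally by half a spacing.  All orientations are set to `phi_B`
#' (facing the wall in the escape geometry).
#'
#' @param n_layers number of rows (the lattice "height").
#' @param n_per_layer colonies per row.
#' @param spacing centre-to-centre distance in units of `a`, >= 2.
#' @param a_um colony radius (um).
#' @param wall_offset_um centre `x` of the first row; default
#'   `a * (1 + spacing/20)` (just off contact).
#' @param phi0_rad common initial orientation; default `pi` (into the wall).
#' @return data.frame with columns `x_um`, `y_um`, `phi_rad`.
#' @export
hexagonal_lattice <- function(n_layers, n_per_layer = 10, spacing = 2.2,
                              a_um = 4.3, wall_offset_um = NULL,
                              phi0_rad = pi) {
  stopifnot(n_layers >= 1, n_per_layer >= 1)
  if (spacing < 2) stop("spacing < 2 colony radii: colonies would overlap")
  if (is.null(wall_offset_um)) wall_offset_um <- a_um * (1 + spacing / 20)
  s <- spacing * a_um
  rows <- lapply(seq_len(n_layers), function(r) {
    data.frame(
      x_um = wall_offset_um + (r - 1) * s * sqrt(3) / 2,
      y_um = (seq_len(n_per_layer) - 1) * s + ((r - 1) %% 2) * s / 2,
      phi_rad = phi0_rad)
  })
  do.call(rbind, rows)
}

#' Self-propulsion target velocity
#'
#' The velocity an isolated squirmer (far from the wall and neighbours)
#' translates at: `v_signed * (cos(phi), sin(phi))` with `v_signed =
#' +v_jump` in jump mode and `-v_return` in return mode.
#'
#' @param phi_rad orientation (rad).
#' @param mode +1 (jump) or -1 (return).
#' @param params a [motility_params()] object.
#' @return length-2 numeric velocity (um/s).
#' @export
self_propulsion <- function(phi_rad, mode = 1L, params = motility_params()) {
  v <- if (mode == 1L) params$v_jump_um_s else -params$v_return_um_s
  c(v * cos(phi_rad), v * sin(phi_rad))
}

sq_state <- function(s) {
  if (is.data.frame(s)) s <- as.list(s[1, ])
  c(s$x_um, s$y_um, s$phi_rad)
}
sq_B1 <- function(s, params) {
  v <- if (is.null(s$mode) || s$mode == 1L) params$v_jump_um_s else
    -params$v_return_um_s
  1.5 * v
}

#' Pairwise squirmer interaction
#'
#' Force and torque contributions on both bodies of a close pair, for given
#' translational/angular velocities: normal lubrication resisting approach
#' (diverging as `1/gap`), tangential lubrication with `log(1/gap)` scaling
#' coupling sliding, rotation and the ciliary surface slip, and steric
#' repulsion along the line of centres.  Forces on the two bodies are equal
#' and opposite; beyond the neighbour cutoff everything is zero.
#'
#' @param si,sj states: lists/rows with `x_um`, `y_um`, `phi_rad` and
#'   optionally `mode` (+1/-1, default jump).
#' @param vi,vj length-3 velocities `(Ux, Uy, omega)` (um/s, rad/s);
#'   default: each body's self-propulsion target and zero spin.
#' @param params a [squirmer_params()].
#' @param motility a [motility_params()] (sets the slip amplitude via the
#'   mode speeds).
#' @return list with `F_i`, `F_j` (pN), `tau_i`, `tau_j` (pN um).
#' @export
pair_interaction <- function(si, sj, vi = NULL, vj = NULL,
                             params = squirmer_params(),
                             motility = motility_params()) {
  if (is.null(vi)) vi <- c(self_propulsion(si$phi_rad, si$mode %||% 1L,
                                           motility), 0)
  if (is.null(vj)) vj <- c(self_propulsion(sj$phi_rad, sj$mode %||% 1L,
                                           motility), 0)
  out <- squirmer_pair_forces_cpp(sq_state(si), sq_state(sj), vi, vj,
                                  sq_B1(si, motility), sq_B1(sj, motility),
                                  sq_par_list(params))
  list(F_i = out[1:2], tau_i = out[3], F_j = out[4:5], tau_j = out[6])
}

#' Squirmer-wall interaction
#'
#' Same lubrication + steric structure as [pair_interaction()] against the
#' no-slip plane at `x = 0` (the rigid-wall approximation of the air-water
#' interface).  Prevents penetration; a colony swimming into the wall
#' stalls at a small steady gap.
#'
#' @param s state (list/row with `x_um`, `y_um`, `phi_rad`, optional `mode`).
#' @param v length-3 velocity `(Ux, Uy, omega)`; default self-propulsion.
#' @param params a [squirmer_params()].
#' @param motility a [motility_params()].
#' @return list with `F` (pN) and `tau` (pN um).
#' @export
wall_interaction <- function(s, v = NULL, params = squirmer_params(),
                             motility = motility_params()) {
  if (is.null(v)) v <- c(self_propulsion(s$phi_rad, s$mode %||% 1L, motility), 0)
  out <- squirmer_wall_forces_cpp(sq_state(s), v, sq_B1(s, motility),
                                  sq_par_list(params))
  list(F = out[1:2], tau = out[3])
}

#' Magnetic torque on a squirmer
#'
#' Out-of-plane torque from the dipole-field interaction, parameterised
#' through the alignment rate `k` so that an isolated body obeys
#' `dphi/dt = k * sin(phi_B - phi)`: the torque is
#' `8*pi*eta*a^3 * k * sin(phi_B - phi)` (the rotational drag times the
#' target angular velocity).
#'
#' @param s state (needs `phi_rad`).
#' @param env a [magnetic_env()].
#' @param params a [squirmer_params()] (sets the rotational drag).
#' @return torque in pN um.
#' @export
magnetic_torque <- function(s, env = magnetic_env(), params = squirmer_params()) {
  zr <- 8 * pi * params$eta_Pa_s * params$a_um^3
  zr * env$k_per_s * sin(env$phi_B_rad - s$phi_rad)
}

#' Advance squirmer states by one or more steps
#'
#' Assembles self-propulsion, pairwise, wall and magnetic contributions,
#' solves the overdamped force/torque balance for every body's velocity
#' (each body always has zero net force and torque), advances the
#' configuration, and applies the same oxygen-gated reversal process as the
#' point engine.  This front end advances deterministically (Brownian noise
#' off; the reversal process still draws from the RNG) — useful for
#' inspecting the dynamics; [run_squirmer_simulation()] is the configured,
#' noisy front end.
#'
#' @param states data.frame with `x_um`, `y_um`, `phi_rad`, `mode`.
#' @param params a [squirmer_params()].
#' @param motility a [motility_params()].
#' @param oxy an [oxygen_env()].
#' @param mag a [magnetic_env()].
#' @param dt_s timestep (s).
#' @param nsteps number of steps.
#' @param t0_s time at the start (for the oxygen profile).
#' @return list: `states` (updated data.frame), `velocities` (data.frame
#'   `Ux_um_s`, `Uy_um_s`, `omega_rad_s` from the final solve), `events`,
#'   `min_gap_um` (smallest pair/wall gap seen).
#' @export
step_squirmers <- function(states, params = squirmer_params(),
                           motility = motility_params(),
                           oxy = oxygen_env(), mag = magnetic_env(),
                           dt_s = 5e-4, nsteps = 1, t0_s = 0) {
  stopifnot(is.data.frame(states))
  if (nrow(states) > 0 && any(states$x_um < params$a_um))
    stop("squirmer centre inside the wall (x < a)")
  res <- squirmer_engine_run(
    states$x_um, states$y_um, states$phi_rad, as.integer(states$mode),
    sq_par_list(params),
    motility$v_jump_um_s, motility$v_return_um_s, 0, 0,
    motility$lambda_minus_per_s, motility$lambda_plus_per_s,
    mag$phi_B_rad, mag$k_per_s,
    oxy$C0_uM, oxy$D_C_um2_s, oxy$c_star_uM, oxy$enabled,
    dt_s, nsteps, max(nsteps, 1L))
  last <- if (length(res$time_s)) res$time_s == max(res$time_s) else logical(0)
  st <- data.frame(x_um = res$x_um[last], y_um = res$y_um[last],
                   phi_rad = res$phi_rad[last], mode = res$mode[last])
  list(states = st,
       velocities = data.frame(Ux_um_s = res$Ux_um_s, Uy_um_s = res$Uy_um_s,
                               omega_rad_s = res$omega_rad_s),
       events = data.frame(time_s = res$ev_time_s,
                           colony_id = res$ev_colony_id,
                           mode = res$ev_mode, x_um = res$ev_x_um),
       min_gap_um = res$min_gap_um)
}

#' Run the finite-size squirmer simulation
#'
#' Simulates colonies from the configured hexagonal lattice placement with
#' near-field hydrodynamic, steric and magnetic interactions near the wall,
#' plus the oxygen-gated reversal process.  Reproducible for a fixed seed.
#'
#' @param config a run configuration with `engine = "squirmer"`
#'   (see [default_config()]).
#' @return a `trajectory_set`; the reversal log is available via
#'   [events()] and the smallest gap encountered as
#'   `attr(ts, "min_gap_um")`.
#' @export
run_squirmer_simulation <- function(config = default_config("squirmer")) {
  config <- validate_config(config)
  if (!identical(config$engine, "squirmer"))
    stop("config$engine must be 'squirmer'")
  set.seed(config$seed)
  oxy <- config$environment$oxygen
  mag <- config$environment$magnetic
  mot <- config$motility
  clk <- config$clock
  sq <- config$squirmer
  lat <- config$lattice
  a <- sq$a_um
  width <- sq$domain_width_um
  if (is.null(width)) width <- lat$n_per_layer * lat$spacing * a
  init <- hexagonal_lattice(lat$n_layers, lat$n_per_layer, lat$spacing, a,
                            lat$wall_offset_um, phi0_rad = mag$phi_B_rad)
  n <- nrow(init)
  nsteps <- round(clk$t_final_s / clk$dt_s)
  par <- sq_par_list(squirmer_params(
    beta = sq$beta, a_um = a, eta_Pa_s = sq$eta_Pa_s,
    contact_eps = sq$contact_eps, rep_strength_pN = sq$rep_strength_pN,
    rep_range_um = sq$rep_range_um, neighbor_cutoff = sq$neighbor_cutoff,
    lub_normal = sq$lub_normal, lub_tangential = sq$lub_tangential,
    domain_width_um = width))
  res <- squirmer_engine_run(
    init$x_um, init$y_um, init$phi_rad, rep(1L, n), par,
    mot$v_jump_um_s, mot$v_return_um_s, mot$D_um2_s, mot$D_r_rad2_s,
    mot$lambda_minus_per_s, mot$lambda_plus_per_s,
    mag$phi_B_rad, mag$k_per_s,
    oxy$C0_uM, oxy$D_C_um2_s, oxy$c_star_uM, oxy$enabled,
    clk$dt_s, nsteps, clk$record_every)
  df <- data.frame(time_s = res$time_s, colony_id = res$colony_id,
                   x_um = res$x_um, y_um = res$y_um, phi_rad = res$phi_rad,
                   mode = res$mode, rate_per_s = res$rate_per_s)
  ev <- data.frame(time_s = res$ev_time_s, colony_id = res$ev_colony_id,
                   mode = res$ev_mode, x_um = res$ev_x_um)
  new_trajectory_set(df, ev, config, "squirmer",
                     extra = list(min_gap_um = res$min_gap_um))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
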