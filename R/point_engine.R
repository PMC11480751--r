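## Point-particle engine: N non-interacting colonies, Euler-Maruyama
## integration of position/orientation plus the oxygen-gated reversal
## process.  The time loop runs in C++; step_point() is the one-step R
## reference implementation used to pin down the update semantics.

#' Motility parameters
#'
#' Swim speeds of the two modes, diffusivities and the two reversal rates.
#' A colony in jump mode travels at `+v_jump` along its orientation, in
#' return mode at `-v_return` (antiparallel).  Fitted defaults:
#' `v_jump = 26.6` and `v_return = 7.6` um/s, `lambda_minus = 0.0413` and
#' `lambda_plus = 0.4186` s^-1.  Default diffusivities are Stokes-Einstein
#' values for a 4.3 um sphere in water at 298 K.
#'
#' @param v_jump_um_s jump-mode speed (um/s), >= 0.
#' @param v_return_um_s return-mode speed (um/s), >= 0.
#' @param D_um2_s translational diffusivity (um^2/s), >= 0.
#' @param D_r_rad2_s rotational diffusivity (rad^2/s), >= 0.
#' @param lambda_minus_per_s basal reversal rate (s^-1), > 0.
#' @param lambda_plus_per_s increased reversal rate (s^-1),
#'   >= `lambda_minus_per_s`.
#' @return an object of class `"motility_params"`.
#' @export
motility_params <- function(v_jump_um_s = 26.6, v_return_um_s = 7.6,
                            D_um2_s = 0.05, D_r_rad2_s = 0.002,
                            lambda_minus_per_s = 0.0413,
                            lambda_plus_per_s = 0.4186) {
  vals <- c(v_jump_um_s, v_return_um_s, D_um2_s, D_r_rad2_s,
            lambda_minus_per_s, lambda_plus_per_s)
  if (any(!is.finite(vals))) stop("motility parameters must be finite")
  if (v_jump_um_s < 0 || v_return_um_s < 0) stop("speeds must be >= 0")
  if (D_um2_s < 0 || D_r_rad2_s < 0) stop("diffusivities must be >= 0")
  if (lambda_minus_per_s <= 0 || lambda_plus_per_s < lambda_minus_per_s)
    stop("need 0 < lambda_minus_per_s <= lambda_plus_per_s")
  structure(list(v_jump_um_s = v_jump_um_s, v_return_um_s = v_return_um_s,
                 D_um2_s = D_um2_s, D_r_rad2_s = D_r_rad2_s,
                 lambda_minus_per_s = lambda_minus_per_s,
                 lambda_plus_per_s = lambda_plus_per_s),
            class = "motility_params")
}

#' Simulation clock
#'
#' @param dt_s integration timestep (s), > 0.
#' @param t_final_s run duration (s), >= `dt_s`.
#' @param record_every output decimation: record every this many steps.
#' @return an object of class `"sim_clock"`.
#' @export
sim_clock <- function(dt_s = 1e-3, t_final_s = 17, record_every = 33) {
  stopifnot(is.numeric(dt_s), dt_s > 0, is.numeric(t_final_s),
            t_final_s >= dt_s, record_every >= 1)
  structure(list(dt_s = dt_s, t_final_s = t_final_s,
                 record_every = as.integer(record_every)),
            class = "sim_clock")
}

#' Direction indicator
#'
#' Classifies whether a colony is swimming along (+1) or against (-1) the
#' magnetic field: the sign of `v_signed * cos(phi - phi_B)` (the planar
#' reduction of the dot product of swimming velocity and field).  The tie
#' (perpendicular orientation) goes to +1.
#'
#' @param v_signed signed speed: `+v_jump` in jump mode, `-v_return` in
#'   return mode.
#' @param phi_rad orientation angle (rad).
#' @param env a [magnetic_env()] (or a numeric `phi_B` in rad).
#' @return integer +1 or -1, vectorised.
#' @export
direction_indicator <- function(v_signed, phi_rad, env = magnetic_env()) {
  phi_B <- if (inherits(env, "magnetic_env")) env$phi_B_rad else env
  ifelse(v_signed * cos(phi_rad - phi_B) >= 0, 1L, -1L)
}

#' Oxygen-gated decision rate
#'
#' The reversal rate as a function of the locally sensed concentration and
#' the direction indicator: the increased rate `lambda_plus` when the colony
#' senses high oxygen while swimming against the field, or low oxygen while
#' swimming along it; the basal rate `lambda_minus` otherwise.  The
#' concentration tie `c == c_star` counts as high.  When oxygen sensing is
#' off (`sensing = FALSE`, the oil-interface control) the reversal machinery
#' is silent and the rate is 0.
#'
#' @param c_uM sensed concentration (uM), >= 0.
#' @param d direction indicator, +1 or -1.
#' @param params a [motility_params()] object.
#' @param c_star_uM threshold concentration (uM).
#' @param sensing logical; `FALSE` disables the reversal process.
#' @return reversal rate (s^-1), vectorised over `c_uM` and `d`.
#' @export
decision_rate <- function(c_uM, d, params = motility_params(),
                          c_star_uM = 2.5, sensing = TRUE) {
  stopifnot(all(c_uM >= 0), all(d %in% c(-1L, 1L)))
  if (!sensing) return(rep(0, length.out = max(length(c_uM), length(d))))
  hi <- (c_uM >= c_star_uM & d == -1) | (c_uM < c_star_uM & d == 1)
  ifelse(hi, params$lambda_plus_per_s, params$lambda_minus_per_s)
}

#' Sample reversal events over one timestep
#'
#' Bernoulli hazard with success probability `1 - exp(-rate * dt)`; exact
#' for a rate held constant over the step, so inter-reversal times over
#' constant-rate windows are exponential with mean `1/rate`.
#'
#' @param rate_per_s reversal rate (s^-1), >= 0.
#' @param dt_s timestep (s).  Errors when `rate * dt > 1`, warns above 0.1.
#' @param n number of independent draws.
#' @return logical vector of length `n`.
#' @export
sample_reversal <- function(rate_per_s, dt_s, n = 1) {
  stopifnot(rate_per_s >= 0, dt_s > 0)
  if (rate_per_s * dt_s > 1)
    stop("timestep too coarse: rate * dt > 1")
  if (rate_per_s * dt_s > 0.1)
    warning("rate * dt exceeds 0.1; reversal hazard is coarse")
  runif(n) < -expm1(-rate_per_s * dt_s)
}

#' One Euler-Maruyama step of the point engine (reference implementation)
#'
#' Advances a collection of colony states by one timestep: orientation by
#' the magnetic alignment term `k * sin(phi_B - phi)` plus rotational noise,
#' position ballistically along the (old) orientation plus translational
#' noise, reflection at the interface (`x` clamped to `>= 0`), then the
#' reversal process re-evaluates the rate from the local concentration and
#' flips the mode with probability `1 - exp(-rate * dt)`.
#'
#' This is the R reference for the compiled engine used by
#' [run_point_simulation()]; with the same RNG state the two produce
#' identical updates.
#'
#' @param states data.frame with columns `x_um`, `y_um`, `phi_rad`, `mode`
#'   (+1 jump / -1 return), `rate_per_s`.
#' @param params a [motility_params()] object.
#' @param oxy an [oxygen_env()].
#' @param mag a [magnetic_env()].
#' @param dt_s timestep (s); must satisfy `k * dt < 0.5`.
#' @param t_s time at the *end* of the step (used for the oxygen profile).
#' @return updated states data.frame.
#' @export
step_point <- function(states, params = motility_params(), oxy = oxygen_env(),
                       mag = magnetic_env(), dt_s = 1e-3, t_s = dt_s) {
  stopifnot(is.data.frame(states),
            all(c("x_um", "y_um", "phi_rad", "mode") %in% names(states)))
  k <- mag$k_per_s
  if (k * dt_s >= 0.5) stop("stability guard violated: k * dt must be < 0.5")
  n <- nrow(states)
  vt <- ifelse(states$mode == 1L, params$v_jump_um_s, -params$v_return_um_s)
  z_phi <- rnorm(n); z_x <- rnorm(n); z_y <- rnorm(n); u <- runif(n)
  phi_old <- states$phi_rad
  phi <- wrap_angle(phi_old + k * sin(mag$phi_B_rad - phi_old) * dt_s +
                    sqrt(2 * params$D_r_rad2_s * dt_s) * z_phi)
  x <- states$x_um + vt * cos(phi_old) * dt_s +
    sqrt(2 * params$D_um2_s * dt_s) * z_x
  y <- states$y_um + vt * sin(phi_old) * dt_s +
    sqrt(2 * params$D_um2_s * dt_s) * z_y
  x <- pmax(x, 0)
  if (any(!is.finite(c(x, y, phi)))) {
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(phi))[1]
    stop("integrator produced non-finite state for colony ", bad)
  }
  c_loc <- oxygen_concentration(x, t_s, oxy)
  d <- direction_indicator(vt, phi, mag)
  rate <- decision_rate(c_loc, d, params, oxy$c_star_uM, sensing = oxy$enabled)
  flip <- u < -expm1(-rate * dt_s)
  states$phi_rad <- phi
  states$x_um <- x
  states$y_um <- y
  states$mode <- ifelse(flip, -states$mode, states$mode)
  states$rate_per_s <- rate
  states
}

#' Run the point-particle simulation
#'
#' Simulates `n` non-interacting colonies under magnetic alignment,
#' Brownian noise and the oxygen-gated reversal process, from the standard
#' initial condition: all colonies at the interface (with a small uniform
#' jitter in `x` by default), oriented along the field toward the
#' interface, in jump mode with the basal reversal rate.
#'
#' @param config a run configuration from [default_config()] /
#'   [load_config()]; list entries override the point-engine defaults.
#' @return a `trajectory_set` (see [events()] for the reversal log).
#' @examples
#' cfg <- default_config("point")
#' cfg$init$n_colonies <- 5; cfg$clock$t_final_s <- 2
#' ts <- run_point_simulation(cfg)
#' summary(ts)
#' @export
run_point_simulation <- function(config = default_config("point")) {
  config <- validate_config(config)
  if (!identical(config$engine, "point"))
    stop("config$engine must be 'point'")
  set.seed(config$seed)
  oxy <- config$environment$oxygen
  mag <- config$environment$magnetic
  mot <- config$motility
  clk <- config$clock
  ini <- config$init
  n <- ini$n_colonies
  nsteps <- round(clk$t_final_s / clk$dt_s)
  x0 <- rep(ini$x0_um, n)
  if (ini$jitter_um > 0) x0 <- x0 + runif(n, 0, ini$jitter_um)
  phi0 <- rep(if (is.null(ini$phi0_rad)) mag$phi_B_rad else ini$phi0_rad, n)
  mode0 <- rep(if (identical(ini$mode0, "return")) -1L else 1L, n)
  res <- point_engine_run(
    x0, rep(0, n), phi0, mode0,
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
  new_trajectory_set(df, ev, config, "point")
}
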