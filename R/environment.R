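## External fields: 1-D oxygen diffusion profile and uniform magnetic field.

#' Oxygen environment
#'
#' Describes the one-dimensional oxygen field diffusing into the fluid from
#' the interface at `x = 0`.  The concentration profile is the solution of
#' the 1-D diffusion equation with fixed boundary concentration `C0`,
#' `C(x, t) = C0 * erfc(x / (2 * sqrt(D_C * t)))`.
#'
#' Defaults are conventional values for air-saturated water at room
#' temperature: `C0 = 250` uM and `D_C = 2000` um^2/s.  The threshold
#' `c_star = 2.5` uM is the concentration at which the reversal process
#' switches behaviour.  Setting `enabled = FALSE` represents the
#' oil-interface control in which no oxygen enters the drop: all
#' concentration queries then return 0.
#'
#' @param C0_uM boundary concentration at the interface (uM), > 0.
#' @param D_C_um2_s oxygen diffusivity in water (um^2 s^-1), > 0.
#' @param c_star_uM threshold concentration (uM), > 0.
#' @param enabled logical; `FALSE` disables oxygen sensing (oil control).
#' @return an object of class `"oxygen_env"`.
#' @examples
#' env <- oxygen_env()
#' oxygen_concentration(0, 5, env)    # boundary value C0
#' oxygen_concentration(100, 5, env)
#' @export
oxygen_env <- function(C0_uM = 250, D_C_um2_s = 2000, c_star_uM = 2.5,
                       enabled = TRUE) {
  stopifnot(is.numeric(C0_uM), length(C0_uM) == 1L, is.finite(C0_uM),
            is.numeric(D_C_um2_s), length(D_C_um2_s) == 1L, is.finite(D_C_um2_s),
            is.numeric(c_star_uM), length(c_star_uM) == 1L, is.finite(c_star_uM),
            is.logical(enabled), length(enabled) == 1L)
  if (C0_uM <= 0) stop("C0_uM must be > 0")
  if (D_C_um2_s <= 0) stop("D_C_um2_s must be > 0")
  if (c_star_uM <= 0) stop("c_star_uM must be > 0")
  structure(list(C0_uM = C0_uM, D_C_um2_s = D_C_um2_s,
                 c_star_uM = c_star_uM, enabled = enabled),
            class = "oxygen_env")
}

#' Magnetic environment
#'
#' Uniform in-plane magnetic field characterised by its direction
#' `phi_B` (angle with the positive x-axis) and the alignment rate
#' `k = 1/tau_B`, the inverse magnetic reaction timescale with which a
#' colony's orientation relaxes toward `phi_B`.  Convert physical
#' magnetics to `k` with [alignment_rate()].
#'
#' The default `phi_B = 2.7` rad is the fitted escape-jump direction with
#' the interface along `x = 0`; `k = 10` s^-1 corresponds to a field much
#' stronger than the geomagnetic field, confining motion to the field line.
#'
#' @param phi_B_rad field direction angle (rad), wrapped to (-pi, pi].
#' @param k_per_s alignment rate (s^-1), >= 0.
#' @return an object of class `"magnetic_env"`.
#' @export
magnetic_env <- function(phi_B_rad = 2.7, k_per_s = 10) {
  stopifnot(is.numeric(phi_B_rad), length(phi_B_rad) == 1L, is.finite(phi_B_rad),
            is.numeric(k_per_s), length(k_per_s) == 1L, is.finite(k_per_s))
  if (k_per_s < 0) stop("k_per_s must be >= 0")
  structure(list(phi_B_rad = wrap_angle(phi_B_rad), k_per_s = k_per_s),
            class = "magnetic_env")
}

#' Physical magnetic properties of a colony
#'
#' Bundles the quantities entering the magnetic reaction timescale
#' `tau_B = 8 * pi * eta * a^3 / (m * B)`: fluid viscosity, colony radius,
#' magnetic moment magnitude and field magnitude, all in SI units.
#'
#' @param eta_Pa_s dynamic viscosity (Pa s), > 0.
#' @param a_m colony radius (m), > 0.
#' @param m_Am2 magnetic moment magnitude (A m^2), > 0.
#' @param B_T magnetic field magnitude (T), > 0.
#' @return an object of class `"colony_magnetics"`.
#' @seealso [alignment_rate()]
#' @export
colony_magnetics <- function(eta_Pa_s, a_m, m_Am2, B_T) {
  vals <- c(eta_Pa_s = eta_Pa_s, a_m = a_m, m_Am2 = m_Am2, B_T = B_T)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all colony_magnetics fields must be finite and > 0")
  structure(as.list(vals), class = "colony_magnetics")
}

## erfc via the normal CDF; no extra dependency needed.
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

#' Oxygen concentration profile
#'
#' Evaluates `C(x, t) = C0 * erfc(x / (2 * sqrt(D_C * t)))`, the solution of
#' the one-dimensional diffusion equation on `x >= 0` with boundary
#' condition `C(0, t) = C0` and initial condition `C(x, 0) = 0` for
#' `x > 0`.  Vectorised over `x_um` and `t_s`.
#'
#' @param x_um distance from the interface (um), >= 0.
#' @param t_s time since oxygen started diffusing in (s), >= 0.
#' @param env an [oxygen_env()].
#' @return concentration in uM.  If `env$enabled` is `FALSE`, 0 everywhere.
#' @examples
#' env <- oxygen_env(C0_uM = 100)
#' oxygen_concentration(2 * sqrt(env$D_C_um2_s * 1), 1, env)  # 100 * erfc(1)
#' @export
oxygen_concentration <- function(x_um, t_s, env = oxygen_env()) {
  stopifnot(inherits(env, "oxygen_env"))
  if (any(x_um < 0)) stop("x_um must be >= 0")
  if (any(t_s < 0)) stop("t_s must be >= 0")
  if (!env$enabled) return(rep(0, length.out = max(length(x_um), length(t_s))))
  n <- max(length(x_um), length(t_s))
  x <- rep_len(x_um, n); t <- rep_len(t_s, n)
  out <- numeric(n)
  pos <- t > 0
  out[pos] <- env$C0_uM * erfc(x[pos] / (2 * sqrt(env$D_C_um2_s * t[pos])))
  out[pos & x == 0] <- env$C0_uM   # erfc(0) = 1, exact
  out
}

#' Position of the threshold-concentration front
#'
#' Finds the unique distance `x*` at which the oxygen profile crosses the
#' threshold `c_star` at time `t`, i.e. `C(x*, t) = c_star`.  The profile is
#' strictly decreasing in `x`, so the root is bracketed and located with
#' [stats::uniroot()].  By self-similarity of the erfc profile,
#' `x*(4 t) = 2 x*(t)`.
#'
#' @param t_s time (s), > 0.
#' @param env an [oxygen_env()]; requires `c_star_uM < C0_uM`.
#' @param tol absolute root tolerance (um).
#' @return front position `x*` in um.
#' @export
concentration_front <- function(t_s, env = oxygen_env(), tol = 1e-8) {
  stopifnot(inherits(env, "oxygen_env"))
  if (!env$enabled) stop("oxygen sensing is disabled; no front exists")
  if (t_s <= 0) stop("t_s must be > 0")
  if (env$c_star_uM >= env$C0_uM)
    stop("c_star_uM >= C0_uM: the profile never exceeds the threshold away from the boundary")
  ## closed-form bracket: x* = 2 sqrt(D_C t) * erfc^{-1}(c*/C0)
  scale <- 2 * sqrt(env$D_C_um2_s * t_s)
  f <- function(x) oxygen_concentration(x, t_s, env) - env$c_star_uM
  hi <- scale
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, lower = 0, upper = hi, tol = tol)$root
}

#' Alignment rate from physical magnetics
#'
#' Converts SI magnetics into the model alignment rate
#' `k = 1/tau_B = m * B / (8 * pi * eta * a^3)` (s^-1), where `1/(8 pi eta
#' a^3)` is the rotational mobility of a sphere of radius `a`.
#'
#' @param props a [colony_magnetics()] object.
#' @return alignment rate `k` in s^-1.
#' @examples
#' # a 4.3 um colony in water; moment*field chosen so that k = 2 s^-1
#' a <- 4.3e-6
#' props <- colony_magnetics(1e-3, a, m_Am2 = 8 * pi * 1e-3 * a^3 * 2.0, B_T = 1)
#' alignment_rate(props)
#' @export
alignment_rate <- function(props) {
  stopifnot(inherits(props, "colony_magnetics"))
  props$m_Am2 * props$B_T / (8 * pi * props$eta_Pa_s * props$a_m^3)
}

## Wrap angles to (-pi, pi].
wrap_angle <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
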