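## Standard squirmer protocols: the field-strength sweep of the
## dispersal-condensation transition, and the lattice-depth escape-success
## sweep.  Per-run seeds are derived deterministically from the master seed
## with a fixed stride, so adding runs never perturbs existing ones.

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000 + index * 7919) %% 2147483647)
}

#' Field-strength sweep of the alignment order parameter
#'
#' Runs the squirmer engine from a hexagonal lattice of initially
#' field-aligned colonies (`Phi(0) = 1`) for a range of alignment rates
#' `k`, with aerotaxis off, and reports the time-averaged order parameter
#' `<Phi>` and its standard deviation `s` over the trailing window, plus
#' the first time the running order parameter falls below zero.  At `k = 0`
#' hydrodynamic interactions disperse the lattice and `<Phi>` drops below
#' zero; at large `k` the lattice is rigidly aligned; the fluctuation
#' maximum sits at a small non-zero `k` where hydrodynamic and magnetic
#' torques compete.
#'
#' @param k_values alignment rates to sweep (s^-1).
#' @param n_layers,n_per_layer lattice size (default 10 x 10 = 100
#'   colonies).
#' @param duration_s run length (s), default 60.
#' @param window_s trailing averaging window (s), default 50.
#' @param replicates independent runs averaged per `k` (ensemble means of
#'   `<Phi>` and `s`).
#' @param seed master seed; per-run seeds are derived from it.
#' @param dt_s timestep (s).
#' @param config_edits optional list of config overrides applied to every
#'   run (e.g. smaller `clock$record_every`).
#' @return data.frame with one row per `k`: `k_per_s`, `mean_Phi`, `s`
#'   (ensemble means over replicates), `t_first_negative_s` (first
#'   replicate's), `seed`.
#' @export
protocol_k_sweep <- function(k_values = c(0, 0.2, 0.5, 1, 2, 5, 10, 20, 50),
                             n_layers = 10, n_per_layer = 10,
                             duration_s = 60, window_s = 50, replicates = 1,
                             seed = 1, dt_s = 5e-4, config_edits = NULL) {
  out <- data.frame(k_per_s = k_values, mean_Phi = NA_real_, s = NA_real_,
                    t_first_negative_s = NA_real_, seed = NA_integer_)
  run_idx <- 0
  for (i in seq_along(k_values)) {
    mP <- sv <- numeric(replicates)
    for (r in seq_len(replicates)) {
      run_idx <- run_idx + 1
      cfg <- default_config("squirmer")
      cfg$environment$oxygen$enabled <- FALSE   # aerotaxis off
      cfg$environment$magnetic$k_per_s <- k_values[i]
      cfg$lattice$n_layers <- n_layers
      cfg$lattice$n_per_layer <- n_per_layer
      cfg$clock$dt_s <- dt_s
      cfg$clock$t_final_s <- duration_s
      cfg$seed <- derive_seed(seed, run_idx)
      if (!is.null(config_edits)) cfg <- modifyList(cfg, config_edits)
      ts <- run_squirmer_simulation(cfg)
      ops <- order_parameter_series(ts, window_s = window_s)
      mP[r] <- attr(ops, "mean_Phi")
      sv[r] <- attr(ops, "s")
      if (r == 1) {
        out$t_first_negative_s[i] <- first_negative_time(ops)
        out$seed[i] <- cfg$seed
      }
    }
    out$mean_Phi[i] <- mean(mP)
    out$s[i] <- mean(sv)
  }
  out
}

#' Lattice-depth sweep of the escape-success rate
#'
#' Runs the squirmer engine with aerotaxis on and a strong field holding an
#' `n x 10` hexagonal lattice against the interface, and measures the
#' fraction of escape attempts (reversals into the outbound mode initiated
#' inside the interface region) that carry the colony past the success
#' threshold.  Deeper lattices block more attempts.
#'
#' @param n_layers_values lattice depths to sweep.
#' @param n_per_layer colonies per layer (default 10).
#' @param k_per_s alignment rate enforcing the lattice (default 50).
#' @param duration_s run length per replicate (s).
#' @param replicates independent runs pooled per depth.
#' @param success_threshold_um success distance (um).
#' @param attempt_x_max_um wall-adjacent region within which attempts are
#'   counted (um); see [escape_success_rate()].
#' @param seed master seed.
#' @param dt_s timestep (s).
#' @param config_edits optional config overrides for every run.
#' @return data.frame per depth: `n_layers`, `attempts`, `successes`,
#'   `rate`, `conf_low`, `conf_high` (Wilson interval).
#' @export
protocol_lattice_escape <- function(n_layers_values = c(1, 2, 4, 8),
                                    n_per_layer = 10, k_per_s = 50,
                                    duration_s = 60, replicates = 1,
                                    success_threshold_um = 16 * 4.3,
                                    attempt_x_max_um = 2.5 * 4.3,
                                    seed = 1, dt_s = 5e-4,
                                    config_edits = NULL) {
  out <- data.frame(n_layers = n_layers_values, attempts = 0L,
                    successes = 0L, rate = NA_real_, conf_low = NA_real_,
                    conf_high = NA_real_)
  run_idx <- 0
  for (i in seq_along(n_layers_values)) {
    att <- 0L; succ <- 0L
    for (r in seq_len(replicates)) {
      run_idx <- run_idx + 1
      cfg <- default_config("squirmer")
      cfg$environment$magnetic$k_per_s <- k_per_s
      cfg$lattice$n_layers <- n_layers_values[i]
      cfg$lattice$n_per_layer <- n_per_layer
      cfg$clock$dt_s <- dt_s
      cfg$clock$t_final_s <- duration_s
      cfg$seed <- derive_seed(seed, run_idx)
      if (!is.null(config_edits)) cfg <- modifyList(cfg, config_edits)
      ts <- run_squirmer_simulation(cfg)
      esc <- tryCatch(
        escape_success_rate(ts, success_threshold_um = success_threshold_um,
                            attempt_x_max_um = attempt_x_max_um),
        error = function(e) list(successes = 0L, attempts = 0L))
      att <- att + esc$attempts
      succ <- succ + esc$successes
    }
    out$attempts[i] <- att
    out$successes[i] <- succ
    if (att > 0) {
      ci <- wilson_interval(succ, att)
      out$rate[i] <- succ / att
      out$conf_low[i] <- ci[1]
      out$conf_high[i] <- ci[2]
    }
  }
  out
}
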