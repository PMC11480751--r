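## fit_switching_rates(): estimate (lambda_minus, lambda_plus) from a
## trajectory record, the way the rates are fitted from tracking data:
## lambda_minus from the never-departed fraction (exponential waiting times
## censored at t_final) and lambda_plus from the converged left:right
## swimmer ratio, which estimates lambda_plus / lambda_minus.

#' Fit the two reversal rates from trajectory data
#'
#' Combines the two estimators of the switching process:
#' `lambda_minus_hat = -log(n_stayed / n_total) / t_final` from the
#' fraction of colonies that never departed the interface, and
#' `lambda_plus_hat = (n_left / n_right) * lambda_minus_hat` from the
#' left:right swimmer count ratio pooled over the trailing `window_s`
#' seconds (after the two-state chain has converged; relaxation rate
#' `lambda_minus + lambda_plus`).  Colony-level bootstrap confidence
#' intervals are attached.
#'
#' @param traj a `trajectory_set` (or plain trajectory data.frame).
#' @param events optional reversal log; taken from `traj` when available.
#' @param phi_B field direction (rad); `NULL` = from the stored config.
#' @param window_s trailing window for the ratio estimator (s), default 5.
#' @param depart_eps_um departure threshold for the stayed set (um).
#' @param n_boot bootstrap replicates (resampling colonies).
#' @return an object of class `"switching_fit"` with methods
#'   [coef.switching_fit()], [confint.switching_fit()],
#'   [summary.switching_fit()] and [simulate.switching_fit()].
#' @examples
#' cfg <- default_config("point")
#' cfg$init$n_colonies <- 40; cfg$clock$t_final_s <- 8
#' fit <- fit_switching_rates(run_point_simulation(cfg), n_boot = 50)
#' coef(fit)
#' @export
fit_switching_rates <- function(traj, events = NULL, phi_B = NULL,
                                window_s = 5, depart_eps_um = 8.6,
                                n_boot = 200) {
  if (inherits(traj, "trajectory_set") && is.null(events))
    events <- attr(traj, "events")
  if (is.null(phi_B)) {
    cfg <- attr(traj, "config")
    phi_B <- if (!is.null(cfg)) cfg$environment$magnetic$phi_B_rad else
      stop("phi_B must be given for trajectories without a stored config")
  }
  t_final <- max(traj$time_s)
  ids <- sort(unique(traj$colony_id))
  n_total <- length(ids)

  ## per-colony ingredients, so the bootstrap can resample colonies
  departed <- if (!is.null(events) && nrow(events))
    ids %in% events$colony_id
  else {
    ex <- excursion_stats(traj, events = NULL, depart_eps_um = depart_eps_um)
    ids %in% ex$per_colony$colony_id[ex$per_colony$departed]
  }
  win <- traj$time_s >= t_final - window_s
  d <- ifelse(traj$mode * cos(traj$phi_rad - phi_B) >= 0, 1L, -1L)
  left_by_id <- vapply(ids, function(i)
    sum(win & traj$colony_id == i & d == 1L), numeric(1))
  right_by_id <- vapply(ids, function(i)
    sum(win & traj$colony_id == i & d == -1L), numeric(1))

  est <- function(idx) {
    ns <- sum(!departed[idx])
    lm <- if (ns == 0) NA_real_ else
      if (ns == length(idx)) 0 else -log(ns / length(idx)) / t_final
    nl <- sum(left_by_id[idx]); nr <- sum(right_by_id[idx])
    ratio <- if (nr > 0) nl / nr else NA_real_
    c(lambda_minus = lm, lambda_plus = ratio * lm, ratio = ratio)
  }
  point <- suppressWarnings(est(seq_len(n_total)))
  boot <- if (n_boot > 0)
    t(vapply(seq_len(n_boot), function(b)
      suppressWarnings(est(sample.int(n_total, replace = TRUE))),
      numeric(3)))
  else NULL

  structure(list(coefficients = point[c("lambda_minus", "lambda_plus")],
                 ratio = point[["ratio"]],
                 n_stayed = sum(!departed), n_total = n_total,
                 n_left = sum(left_by_id), n_right = sum(right_by_id),
                 t_final_s = t_final, window_s = window_s,
                 boot = boot, call = match.call()),
            class = "switching_fit")
}

#' @rdname fit_switching_rates
#' @param object,x a `switching_fit`.
#' @param ... unused.
#' @export
coef.switching_fit <- function(object, ...) object$coefficients

#' @export
print.switching_fit <- function(x, ...) {
  cat("Two-state switching-rate fit\n")
  cat(sprintf("  lambda_minus = %.4f s^-1  (from %d/%d never-departed over %g s)\n",
              x$coefficients[["lambda_minus"]], x$n_stayed, x$n_total,
              x$t_final_s))
  cat(sprintf("  lambda_plus  = %.4f s^-1  (left:right = %.3f over trailing %g s)\n",
              x$coefficients[["lambda_plus"]], x$ratio, x$window_s))
  invisible(x)
}

#' Bootstrap confidence intervals for the fitted rates
#'
#' @param object a `switching_fit` fitted with `n_boot > 0`.
#' @param parm coefficients to report (default both rates and the ratio).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix of percentile intervals.
#' @export
confint.switching_fit <- function(object, parm = c("lambda_minus",
                                                   "lambda_plus", "ratio"),
                                  level = 0.95, ...) {
  if (is.null(object$boot)) stop("fit has no bootstrap replicates")
  parm <- match.arg(parm, several.ok = TRUE)
  a <- (1 - level) / 2
  out <- t(apply(object$boot[, parm, drop = FALSE], 2, quantile,
                 probs = c(a, 1 - a), na.rm = TRUE))
  colnames(out) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  out
}

#' @export
summary.switching_fit <- function(object, ...) {
  ci <- if (!is.null(object$boot)) confint(object) else NULL
  out <- list(fit = object, ci = ci,
              stationary = ctmc_stationary(ctmc_params(
                max(object$coefficients[["lambda_minus"]], 1e-12),
                max(object$coefficients[["lambda_plus"]], 1e-12))))
  class(out) <- "summary.switching_fit"
  out
}

#' @export
print.summary.switching_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ci)) {
    cat("  bootstrap percentile intervals:\n")
    print(round(x$ci, 4))
  }
  cat(sprintf("  implied stationary law: pi_left = %.4f, pi_right = %.4f\n",
              x$stationary[["pi_left"]], x$stationary[["pi_right"]]))
  cat(sprintf("  implied relaxation rate: %.4f s^-1\n",
              sum(x$fit$coefficients)))
  invisible(x)
}

#' Simulate the fitted switching chain
#'
#' Draws sample paths of the two-state chain at the fitted rates (exact
#' exponential holding times), mirroring [simulate_ctmc()].
#'
#' @param object a `switching_fit`.
#' @param nsim number of chains.
#' @param seed optional RNG seed.
#' @param t_final_s,dt_s duration and sampling interval (s).
#' @param ... unused.
#' @return state matrix as in [simulate_ctmc()].
#' @export
simulate.switching_fit <- function(object, nsim = 1, seed = NULL,
                                   t_final_s = 17, dt_s = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_ctmc(ctmc_params(object$coefficients[["lambda_minus"]],
                            object$coefficients[["lambda_plus"]]),
                n = nsim, t_final_s = t_final_s, dt_s = dt_s)
}
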