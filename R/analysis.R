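## Trajectory statistics: phase segmentation, excursion records (d_jump,
## t_wait), left/right swimmer counts, alignment order parameter, and
## escape-success classification.

#' Segment one trajectory into jump / turnaround / return phases
#'
#' Instantaneous velocity from central differences of a uniformly sampled
#' trajectory; frames with speed below `speed_lo` are "turnaround" (T),
#' faster frames are "jump" (J) when moving away from the interface
#' (increasing `x`) and "return" (R) when moving toward it.  Runs shorter
#' than `min_duration_s` are merged into their longer neighbour to suppress
#' noise flicker.  The phases partition the record exactly.
#'
#' @param traj data.frame for a single colony with `time_s`, `x_um`, `y_um`
#'   (at least 3 uniformly spaced samples).
#' @param speed_lo stationary threshold (um/s); default 2, below the
#'   return-mode speed.
#' @param speed_hi fast-band reference speed (um/s), reported in the output
#'   as the expected jump-phase scale; default the jump-mode speed.
#' @param min_duration_s minimum phase duration (s).
#' @return data.frame with columns `label` (J/T/R), `t_start_s`, `t_end_s`,
#'   `duration_s`, `mean_speed_um_s`.
#' @export
segment_phases <- function(traj, speed_lo = 2, speed_hi = 26.6,
                           min_duration_s = 0.2) {
  stopifnot(speed_lo < speed_hi)
  if (nrow(traj) < 3) stop("insufficient data: need at least 3 samples")
  o <- order(traj$time_s)
  t <- traj$time_s[o]; x <- traj$x_um[o]
  y <- if ("y_um" %in% names(traj)) traj$y_um[o] else rep(0, length(x))
  dt <- diff(t)
  if (any(dt <= 0)) stop("non-monotone time column")
  n <- length(t)
  ## central differences (one-sided at the ends)
  vx <- c(diff(x)[1] / dt[1],
          (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
          diff(x)[n - 1] / dt[n - 1])
  vy <- c(diff(y)[1] / dt[1],
          (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
          diff(y)[n - 1] / dt[n - 1])
  speed <- sqrt(vx^2 + vy^2)
  lab <- ifelse(speed < speed_lo, "T", ifelse(vx > 0, "J", "R"))
  ## merge sub-threshold runs into the longer neighbour
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    dur <- t[ends] - t[starts]
    short <- which(dur < min_duration_s)
    if (!length(short)) break
    i <- short[which.min(dur[short])]
    nb <- if (i == 1) 2 else if (i == length(r$lengths)) i - 1 else
      if (dur[i - 1] >= dur[i + 1]) i - 1 else i + 1
    lab[starts[i]:ends[i]] <- r$values[nb]
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ## contiguous partition: each phase ends where the next begins
  t_start <- t[starts]
  t_end <- c(t[starts[-1]], t[n])
  data.frame(label = r$values,
             t_start_s = t_start,
             t_end_s = t_end,
             duration_s = t_end - t_start,
             mean_speed_um_s = vapply(seq_along(starts), function(i)
               mean(speed[starts[i]:ends[i]]), numeric(1)))
}

#' Excursion statistics: d_jump, t_wait, success flags
#'
#' An excursion opens when a colony's distance from the interface exceeds
#' `interface_x + depart_eps` and closes when it drops back below it.  Per
#' colony, `d_jump` is the mean of the per-excursion maximum distances and
#' `t_wait` the mean interface-residence duration preceding a departure;
#' colonies that never depart are reported separately (they feed
#' [estimate_lambda_minus()] and are excluded from `d_jump` summaries).
#' An excursion is a "success" when its maximum distance reaches
#' `success_threshold` (default 16 colony radii, roughly the edge of a
#' packed eight-layer lattice).
#'
#' When the trajectory's reversal event log is available (a
#' `trajectory_set`, or via `events`), departure is dated by the reversal
#' that initiates it and the never-departed set is the set of colonies with
#' no reversal at all — the model-level reading of "performs an escape
#' jump", free of the travel-distance censoring a pure position threshold
#' induces.  For plain tables (e.g. external tracking) the position
#' threshold alone is used.
#'
#' @param traj a `trajectory_set` or plain trajectory data.frame.
#' @param events optional reversal log (`time_s`, `colony_id`, `mode`).
#' @param interface_x_um interface position (um).
#' @param depart_eps_um departure threshold above the interface (um);
#'   default one colony diameter, 8.6.
#' @param success_threshold_um success distance (um); default 16 * 4.3.
#' @return list with
#'   `excursions` (one row per excursion: `colony_id`, `t_depart_s`,
#'   `t_return_s` (NA while open), `d_max_um`, `success`),
#'   `per_colony` (`colony_id`, `n_excursions`, `d_jump_um`, `t_wait_s`,
#'   `departed`), `stayed_ids`, `n_stayed`, `n_total`, `t_final_s`.
#' @export
excursion_stats <- function(traj, events = NULL, interface_x_um = 0,
                            depart_eps_um = 8.6,
                            success_threshold_um = 16 * 4.3) {
  if (depart_eps_um <= 0) stop("depart_eps_um must be > 0")
  if (inherits(traj, "trajectory_set") && is.null(events))
    events <- attr(traj, "events")
  ids <- sort(unique(traj$colony_id))
  t_final <- max(traj$time_s)
  exc_list <- list()
  per <- data.frame(colony_id = ids, n_excursions = 0L,
                    d_jump_um = NA_real_, t_wait_s = NA_real_,
                    departed = FALSE)
  for (irow in seq_along(ids)) {
    id <- ids[irow]
    sel <- traj$colony_id == id
    t <- traj$time_s[sel]; x <- traj$x_um[sel] - interface_x_um
    o <- order(t); t <- t[o]; x <- x[o]
    if (any(diff(t) <= 0)) stop("non-monotone time column for colony ", id)
    out <- x > depart_eps_um
    r <- rle(out)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    exc_idx <- which(r$values)
    waits <- numeric(0)
    if (length(exc_idx)) {
      exc <- data.frame(
        colony_id = id,
        t_depart_s = t[starts[exc_idx]],
        t_return_s = ifelse(ends[exc_idx] < length(t),
                            t[pmin(ends[exc_idx] + 1L, length(t))], NA_real_),
        d_max_um = vapply(exc_idx, function(i)
          max(x[starts[i]:ends[i]]), numeric(1)))
      exc$success <- exc$d_max_um >= success_threshold_um
      exc_list[[length(exc_list) + 1L]] <- exc
      ## waiting times: residence duration before each departure
      res_idx <- which(!r$values)
      for (i in res_idx) {
        if (i + 1L <= length(r$values) && r$values[i + 1L]) {
          t0 <- t[starts[i]]
          t1 <- t[ends[i]]
          ## date the departure by the initiating reversal when available
          if (!is.null(events) && nrow(events)) {
            evt <- events$time_s[events$colony_id == id &
                                   events$mode == -1L &
                                   events$time_s >= t0 &
                                   events$time_s <= t[starts[i + 1L]]]
            if (length(evt)) t1 <- evt[1]
          }
          waits <- c(waits, t1 - t0)
        }
      }
      per$n_excursions[irow] <- nrow(exc)
      per$d_jump_um[irow] <- mean(exc$d_max_um)
      per$t_wait_s[irow] <- if (length(waits)) mean(waits) else NA_real_
      per$departed[irow] <- TRUE
    }
    if (!is.null(events) && nrow(events))
      per$departed[irow] <- per$departed[irow] ||
        any(events$colony_id == id)
  }
  excursions <- if (length(exc_list)) do.call(rbind, exc_list) else
    data.frame(colony_id = integer(), t_depart_s = numeric(),
               t_return_s = numeric(), d_max_um = numeric(),
               success = logical())
  stayed <- per$colony_id[!per$departed]
  list(excursions = excursions, per_colony = per, stayed_ids = stayed,
       n_stayed = length(stayed), n_total = length(ids),
       t_final_s = t_final)
}

#' Left/right swimmer counts per frame
#'
#' Counts colonies swimming along (+1, "left": toward the interface) and
#' against (-1, "right") the field in every recorded frame, using the sign
#' of `v_signed * cos(phi - phi_B)` with ties going left.  The converged
#' ratio estimates `lambda_plus / lambda_minus`.
#'
#' @param traj a `trajectory_set` or data.frame with `time_s`, `phi_rad`,
#'   `mode`.
#' @param phi_B field direction (rad) or a [magnetic_env()]; when `NULL`,
#'   taken from the trajectory's stored configuration.
#' @return data.frame with `time_s`, `n_left`, `n_right`, `ratio`
#'   (NA where `n_right` is 0).
#' @export
left_right_series <- function(traj, phi_B = NULL) {
  if (inherits(phi_B, "magnetic_env")) phi_B <- phi_B$phi_B_rad
  if (is.null(phi_B)) {
    cfg <- attr(traj, "config")
    phi_B <- if (!is.null(cfg)) cfg$environment$magnetic$phi_B_rad else
      stop("phi_B must be given for trajectories without a stored config")
  }
  d <- ifelse(traj$mode * cos(traj$phi_rad - phi_B) >= 0, 1L, -1L)
  left <- tapply(d == 1L, traj$time_s, sum)
  right <- tapply(d == -1L, traj$time_s, sum)
  out <- data.frame(time_s = as.numeric(names(left)),
                    n_left = as.integer(left),
                    n_right = as.integer(right))
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  out$ratio <- ifelse(out$n_right > 0, out$n_left / out$n_right, NA_real_)
  out
}

#' Magnetic alignment order parameter
#'
#' `Phi(t) = mean_i cos(phi_i(t) - phi_B)`: 1 = perfect alignment with the
#' field, 0 = isotropic, -1 = anti-alignment.  `mean_Phi` and the standard
#' deviation `s` are computed over the trailing `window_s` seconds.
#'
#' @param traj a `trajectory_set` or data.frame with `time_s`, `phi_rad`.
#' @param phi_B field direction (rad) or [magnetic_env()]; `NULL` = from
#'   the stored config.
#' @param window_s trailing averaging window (s), default 50; must not
#'   exceed the record length.
#' @return object of class `"order_parameter_series"`: data.frame
#'   `time_s`, `Phi` with attributes `mean_Phi`, `s`, `window_s`.
#' @export
order_parameter_series <- function(traj, phi_B = NULL, window_s = 50) {
  if (inherits(phi_B, "magnetic_env")) phi_B <- phi_B$phi_B_rad
  if (is.null(phi_B)) {
    cfg <- attr(traj, "config")
    phi_B <- if (!is.null(cfg)) cfg$environment$magnetic$phi_B_rad else
      stop("phi_B must be given for trajectories without a stored config")
  }
  if (!nrow(traj)) stop("empty trajectory")
  if (window_s <= 0) stop("empty averaging window")
  Phi <- tapply(cos(traj$phi_rad - phi_B), traj$time_s, mean)
  out <- data.frame(time_s = as.numeric(names(Phi)), Phi = as.numeric(Phi))
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  t_max <- max(out$time_s)
  window_s <- min(window_s, t_max - min(out$time_s))
  w <- out$time_s >= t_max - window_s
  attr(out, "mean_Phi") <- mean(out$Phi[w])
  attr(out, "s") <- sd(out$Phi[w])
  attr(out, "window_s") <- window_s
  class(out) <- c("order_parameter_series", "data.frame")
  out
}

#' @export
print.order_parameter_series <- function(x, ...) {
  cat(sprintf(
    "<order_parameter_series: %d frames; <Phi> = %.4f, s = %.4f over trailing %g s>\n",
    nrow(x), attr(x, "mean_Phi"), attr(x, "s"), attr(x, "window_s")))
  invisible(x)
}

#' @export
plot.order_parameter_series <- function(x, ...) {
  graphics::plot(x$time_s, x$Phi, type = "l", ylim = c(-1, 1),
                 xlab = "time (s)", ylab = expression(Phi(t)), ...)
  graphics::abline(h = attr(x, "mean_Phi"), lty = 2)
  invisible(x)
}

#' First time the running order parameter falls below zero
#'
#' Trailing running mean of `Phi(t)` over `smooth_s` seconds; returns the
#' first time it drops below zero (NA if it never does).
#'
#' @param ops an [order_parameter_series()].
#' @param smooth_s trailing smoothing window (s).
#' @return time in s, or NA.
#' @export
first_negative_time <- function(ops, smooth_s = 1) {
  t <- ops$time_s; p <- ops$Phi
  run <- vapply(seq_along(t), function(i) {
    w <- t >= t[i] - smooth_s & t <= t[i]
    mean(p[w])
  }, numeric(1))
  idx <- which(run < 0)
  if (length(idx)) t[idx[1]] else NA_real_
}

#' Escape-success rate from the reversal event log
#'
#' An *attempt* is a reversal into the outbound mode initiated while the
#' colony is resident in the wall-adjacent interface region (`x` at the
#' event below `attempt_x_max`, default 2.5 colony radii — the first
#' lattice layer, so that deeper lattices must be traversed); it
#' *succeeds* if the colony's distance from the interface reaches
#' `success_threshold` before its next reversal back.  Reports
#' successes/attempts with a Wilson score interval.
#'
#' @param traj a `trajectory_set` (the event log is taken from it), or a
#'   plain trajectory data.frame with `events` supplied.
#' @param events optional reversal log.
#' @param success_threshold_um success distance (um); default 16 * 4.3.
#' @param attempt_x_max_um attempts are counted only when initiated below
#'   this distance (um); default 2.5 * 4.3.
#' @param conf confidence level for the Wilson interval.
#' @return list `successes`, `attempts`, `rate`, `conf_low`, `conf_high`.
#' @export
escape_success_rate <- function(traj, events = NULL,
                                success_threshold_um = 16 * 4.3,
                                attempt_x_max_um = 2.5 * 4.3,
                                conf = 0.95) {
  if (inherits(traj, "trajectory_set") && is.null(events))
    events <- attr(traj, "events")
  if (is.null(events) || !nrow(events))
    stop("no reversal attempts recorded")
  att <- events[events$mode == -1L & events$x_um <= attempt_x_max_um, ]
  if (!nrow(att)) stop("no reversal attempts recorded")
  succ <- 0L
  for (i in seq_len(nrow(att))) {
    id <- att$colony_id[i]; t0 <- att$time_s[i]
    back <- events$time_s[events$colony_id == id & events$mode == 1L &
                            events$time_s > t0]
    t1 <- if (length(back)) back[1] else Inf
    sel <- traj$colony_id == id & traj$time_s >= t0 & traj$time_s <= t1
    if (any(sel) && max(traj$x_um[sel]) >= success_threshold_um)
      succ <- succ + 1L
  }
  ci <- wilson_interval(succ, nrow(att), conf)
  list(successes = succ, attempts = nrow(att), rate = succ / nrow(att),
       conf_low = ci[1], conf_high = ci[2])
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes; @param n trials; @param conf confidence level.
#' @return length-2 vector (lower, upper).
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
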