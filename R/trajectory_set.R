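## TrajectorySet: tidy time-indexed table of colony states, shared by both
## engines, plus the reversal event log and run metadata as attributes.

new_trajectory_set <- function(df, events, config, engine, extra = list()) {
  stopifnot(is.data.frame(df))
  attr(df, "events") <- events
  attr(df, "config") <- config
  attr(df, "engine") <- engine
  attr(df, "seed") <- config$seed
  attr(df, "config_hash") <- config_hash(config)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("trajectory_set", "data.frame")
  df
}

#' Reversal event log of a simulation
#'
#' @param ts a `trajectory_set` returned by [run_point_simulation()] or
#'   [run_squirmer_simulation()].
#' @return data.frame with columns `time_s`, `colony_id`, `mode`
#'   (mode after the reversal: +1 jump, -1 return) and `x_um`.
#' @export
events <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  attr(ts, "events")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n_col <- length(unique(x$colony_id))
  cat(sprintf("<trajectory_set: %s engine, %d colonies, %d frames, t = 0..%g s>\n",
              attr(x, "engine"), n_col,
              length(unique(x$time_s)), max(x$time_s)))
  cat(sprintf("  seed %s, config hash %s, %d reversal events\n",
              format(attr(x, "seed")), attr(x, "config_hash"),
              nrow(attr(x, "events"))))
  invisible(x)
}

#' @export
summary.trajectory_set <- function(object, ...) {
  ev <- attr(object, "events")
  cfg <- attr(object, "config")
  phi_B <- cfg$environment$magnetic$phi_B_rad
  lr <- left_right_series(object, phi_B = phi_B)
  out <- list(
    engine = attr(object, "engine"),
    n_colonies = length(unique(object$colony_id)),
    t_final_s = max(object$time_s),
    n_reversals = nrow(ev),
    final_left_right = c(left = lr$n_left[nrow(lr)], right = lr$n_right[nrow(lr)]),
    x_range_um = range(object$x_um)
  )
  class(out) <- "summary.trajectory_set"
  out
}

#' @export
print.summary.trajectory_set <- function(x, ...) {
  cat(sprintf("%s-engine run: %d colonies over %g s, %d reversals\n",
              x$engine, x$n_colonies, x$t_final_s, x$n_reversals))
  cat(sprintf("  final left/right swimmers: %d/%d\n",
              x$final_left_right[["left"]], x$final_left_right[["right"]]))
  cat(sprintf("  x range: [%.2f, %.2f] um\n", x$x_range_um[1], x$x_range_um[2]))
  invisible(x)
}

#' Plot colony trajectories
#'
#' Distance from the interface against time, one line per colony.
#'
#' @param x a `trajectory_set`.
#' @param max_colonies cap on the number of colonies drawn.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trajectory_set <- function(x, max_colonies = 30, ...) {
  ids <- unique(x$colony_id)
  if (length(ids) > max_colonies) ids <- ids[seq_len(max_colonies)]
  times <- sort(unique(x$time_s))
  m <- sapply(ids, function(i) x$x_um[x$colony_id == i])
  graphics::matplot(times, m, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "distance from interface (um)",
                    ...)
  invisible(x)
}

#' Write a trajectory set (and its event log) to CSV
#'
#' The trajectory file carries the engine, seed and config hash in `#`
#' comment headers; the event log goes to a sibling `*_events.csv`.
#'
#' @param ts a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_set <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  con <- file(path, "w")
  writeLines(c("# mmpsim trajectory_set",
               paste0("# engine: ", attr(ts, "engine")),
               paste0("# seed: ", attr(ts, "seed")),
               paste0("# config_hash: ", attr(ts, "config_hash"))), con)
  write.csv(as.data.frame(ts), con, row.names = FALSE)
  close(con)
  ev_path <- sub("\\.csv$", "_events.csv", path)
  if (identical(ev_path, path)) ev_path <- paste0(path, "_events.csv")
  write.csv(attr(ts, "events"), ev_path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory set written by [write_trajectory_set()]
#'
#' Also accepts plain CSV trajectory tables from external trackers with
#' columns `time_s`, `colony_id`, `x_um`, `y_um`, `phi_rad`, `mode`.
#'
#' @param path CSV path.
#' @return a `trajectory_set` (with empty metadata if headers are absent).
#' @export
read_trajectory_set <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  df <- read.csv(path, comment.char = "#")
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  ev_path <- sub("\\.csv$", "_events.csv", path)
  ev <- if (file.exists(ev_path) && ev_path != path) read.csv(ev_path) else
    data.frame(time_s = numeric(), colony_id = integer(),
               mode = integer(), x_um = numeric())
  attr(df, "events") <- ev
  attr(df, "engine") <- meta("engine")
  attr(df, "seed") <- suppressWarnings(as.integer(meta("seed")))
  attr(df, "config_hash") <- meta("config_hash")
  class(df) <- c("trajectory_set", "data.frame")
  df
}
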