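# Trajectory statistics: phases, excursions, counts, order parameter

make_excursion_traj <- function(v_out = 26.6, t_out = 2, t_stop = 1,
                                v_in = 7.6, dt = 0.05) {
  # piecewise trajectory: out, stationary, back to the start
  d <- v_out * t_out
  t_in <- d / v_in
  t <- seq(0, t_out + t_stop + t_in, by = dt)
  x <- ifelse(t <= t_out, v_out * t,
              ifelse(t <= t_out + t_stop, d,
                     pmax(0, d - v_in * (t - t_out - t_stop))))
  data.frame(time_s = t, colony_id = 1L, x_um = x, y_um = 0)
}

test_that("constructed out/stop/back trajectory segments into J, T, R", {
  tr <- make_excursion_traj()
  ph <- segment_phases(tr, speed_lo = 2)
  expect_identical(ph$label, c("J", "T", "R"))
  expect_equal(ph$duration_s[1], 2, tolerance = 0.1)
  expect_equal(ph$duration_s[2], 1, tolerance = 0.1)
  expect_equal(ph$duration_s[3], 26.6 * 2 / 7.6, tolerance = 0.15)
  expect_equal(ph$mean_speed_um_s[1], 26.6, tolerance = 0.05 * 26.6)
  expect_equal(ph$mean_speed_um_s[3], 7.6, tolerance = 0.05 * 7.6)
  # phases partition the record exactly
  expect_equal(ph$t_start_s[1], min(tr$time_s))
  expect_equal(ph$t_end_s[nrow(ph)], max(tr$time_s))
  expect_equal(ph$t_start_s[-1], ph$t_end_s[-nrow(ph)])
})

test_that("pure-noise stationary trajectory is a single turnaround phase", {
  set.seed(4)
  t <- seq(0, 10, by = 0.1)
  tr <- data.frame(time_s = t, colony_id = 1L,
                   x_um = 50 + cumsum(rnorm(length(t), 0, 0.02)),
                   y_um = cumsum(rnorm(length(t), 0, 0.02)))
  ph <- segment_phases(tr, speed_lo = 2)
  expect_identical(ph$label, "T")
  expect_error(segment_phases(tr[1:2, ]), "insufficient")
})

test_that("sawtooth trajectory yields two successful excursions", {
  a <- 4.3
  t <- seq(0, 40, by = 0.1)
  period <- 20
  x <- 20 * a * (1 - abs(2 * ((t %% period) / period) - 1))  # 0 -> 20a -> 0
  tr <- data.frame(time_s = t, colony_id = 1L, x_um = x, y_um = 0)
  ex <- excursion_stats(tr, depart_eps_um = 2 * a,
                        success_threshold_um = 16 * a)
  expect_equal(nrow(ex$excursions), 2)
  expect_true(all(ex$excursions$success))
  expect_equal(ex$per_colony$d_jump_um, 20 * a, tolerance = 1e-6)
  expect_equal(ex$n_stayed, 0)
})

test_that("colonies that never leave are reported in the stayed set", {
  t <- seq(0, 10, by = 0.1)
  tr <- rbind(
    data.frame(time_s = t, colony_id = 1L, x_um = 1 + 0.5 * sin(t), y_um = 0),
    data.frame(time_s = t, colony_id = 2L, x_um = pmin(30, 30 * t), y_um = 0))
  ex <- excursion_stats(tr, depart_eps_um = 8.6)
  expect_identical(ex$stayed_ids, 1L)
  expect_equal(ex$n_stayed, 1)
  expect_equal(ex$n_total, 2)
  expect_false(1L %in% ex$excursions$colony_id)
})

test_that("waiting times on engine output are consistent with Exp(lambda_minus)", {
  cfg <- quick_point_cfg(n = 200, t_final = 17, seed = 31)
  ts <- run_point_simulation(cfg)
  ex <- excursion_stats(ts)
  # survival estimator on the never-departed fraction recovers lambda_minus
  lam_hat <- estimate_lambda_minus(ex$n_stayed, ex$n_total, ex$t_final_s)
  se <- sqrt((1 - exp(-0.0413 * 17)) / (200 * exp(-0.0413 * 17))) / 17
  expect_lt(abs(lam_hat - 0.0413), 4 * se)
  # phase speeds of a long excursion: under the printed dynamics the
  # outbound leg runs at the return-mode speed and the inbound leg at the
  # jump-mode speed (the orientation stays field-aligned; only the sign of
  # the propulsion flips)
  dep <- ex$excursions[!is.na(ex$excursions$t_return_s) &
                         ex$excursions$d_max_um > 20, ]
  expect_gt(nrow(dep), 5)
  big <- dep[which.max(dep$d_max_um), ]
  sl <- ts[ts$colony_id == big$colony_id &
             ts$time_s >= big$t_depart_s - 0.5 &
             ts$time_s <= big$t_return_s + 0.3, ]
  ph <- segment_phases(sl, speed_lo = 2)
  expect_equal(ph$mean_speed_um_s[ph$label == "J"][1], 7.6, tolerance = 0.2)
  expect_equal(ph$mean_speed_um_s[ph$label == "R"][1], 26.6, tolerance = 0.2)
})

test_that("d_jump and t_wait are stable under output decimation", {
  cfg <- quick_point_cfg(n = 60, t_final = 10, seed = 13)
  cfg$clock$record_every <- 10L
  ts1 <- run_point_simulation(cfg)
  cfg$clock$record_every <- 40L
  ts2 <- run_point_simulation(cfg)
  e1 <- excursion_stats(ts1); e2 <- excursion_stats(ts2)
  d1 <- mean(e1$per_colony$d_jump_um, na.rm = TRUE)
  d2 <- mean(e2$per_colony$d_jump_um, na.rm = TRUE)
  expect_lt(abs(d1 - d2) / d1, 0.15)
  expect_equal(e1$n_stayed, e2$n_stayed)
})

test_that("left/right counts follow the sign convention", {
  tr <- data.frame(time_s = 0, colony_id = 1:4,
                   phi_rad = c(2.7, 2.7, 2.7 + pi / 2, 2.7 + pi),
                   mode = c(1L, -1L, 1L, -1L), x_um = 0, y_um = 0)
  lr <- left_right_series(tr, phi_B = 2.7)
  # modes: along, against, tie (-> left), against-field flipped (-> left)
  expect_equal(lr$n_left, 3L)
  expect_equal(lr$n_right, 1L)
})

test_that("order parameter matches direct evaluation and its moments", {
  t <- rep(0:9, each = 100)
  set.seed(8)
  phis <- runif(1000, -pi, pi)
  tr <- data.frame(time_s = t, colony_id = rep(1:100, 10), phi_rad = phis)
  ops <- order_parameter_series(tr, phi_B = 1.1, window_s = 9)
  direct <- vapply(0:9, function(tt)
    mean(cos(phis[t == tt] - 1.1)), numeric(1))
  expect_equal(ops$Phi, direct)
  expect_true(all(ops$Phi >= -1 & ops$Phi <= 1))
  # uniform angles: E[Phi] = 0, SD(Phi) = 1/sqrt(2 N)
  expect_lt(abs(mean(ops$Phi)), 4 / sqrt(2 * 1000))
  aligned <- data.frame(time_s = t, colony_id = rep(1:100, 10),
                        phi_rad = 1.1)
  opsA <- order_parameter_series(aligned, phi_B = 1.1, window_s = 9)
  expect_equal(opsA$Phi, rep(1, 10))
  expect_equal(attr(opsA, "s"), 0)
  anti <- data.frame(time_s = 0, colony_id = 1:5, phi_rad = 1.1 + pi)
  expect_equal(order_parameter_series(anti, phi_B = 1.1, window_s = 0.1)$Phi,
               -1)
})

test_that("uniform-angle fluctuations of Phi have SD 1/sqrt(2N)", {
  set.seed(12)
  phis <- matrix(runif(100 * 400, -pi, pi), nrow = 400)
  Phi <- rowMeans(cos(phis))
  expect_equal(sd(Phi), 1 / sqrt(2 * 100), tolerance = 0.12)
})

test_that("escape success rate is monotone in the threshold and edge cases work", {
  t <- seq(0, 10, by = 0.1)
  x <- 40 * (1 - abs(2 * (t / 10) - 1))          # one excursion to 40 um
  tr <- data.frame(time_s = t, colony_id = 1L, x_um = x, y_um = 0,
                   phi_rad = 2.7, mode = 1L)
  ev <- data.frame(time_s = c(0.1, 9.9), colony_id = 1L,
                   mode = c(-1L, 1L), x_um = c(0.5, 0.5))
  all_pass <- escape_success_rate(tr, ev, success_threshold_um = 30)
  expect_equal(all_pass$rate, 1)
  none_pass <- escape_success_rate(tr, ev, success_threshold_um = 50)
  expect_equal(none_pass$rate, 0)
  ths <- c(10, 20, 30, 39, 41, 60)
  rates <- vapply(ths, function(th)
    escape_success_rate(tr, ev, success_threshold_um = th)$rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_error(escape_success_rate(tr, ev[0, ]), "no reversal attempts")
})

test_that("Wilson interval brackets the point estimate and stays in [0, 1]", {
  ci <- wilson_interval(31, 100)
  expect_lt(ci[1], 0.31); expect_gt(ci[2], 0.31)
  expect_gte(wilson_interval(0, 10)[1], 0)
  expect_lte(wilson_interval(10, 10)[2], 1)
})
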