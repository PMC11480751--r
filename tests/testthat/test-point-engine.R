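# Point engine: decision logic, reversal sampling, integration semantics

test_that("direction indicator follows the signed projection with ties going +1", {
  mag <- magnetic_env(phi_B_rad = 2.7)
  expect_identical(direction_indicator(26.6, 2.7, mag), 1L)
  expect_identical(direction_indicator(-7.6, 2.7, mag), -1L)
  # exactly perpendicular: dot product 0, printed inequality is >=
  expect_identical(direction_indicator(26.6, 2.7 + pi / 2, mag), 1L)
  expect_identical(direction_indicator(-7.6, 2.7 + pi, mag), 1L)
  expect_identical(direction_indicator(26.6, 2.7 + pi, mag), -1L)
})

test_that("decision rate selects the increased rate in the two printed branches", {
  p <- motility_params()
  expect_equal(decision_rate(3.0, -1L, p, 2.5), 0.4186)
  expect_equal(decision_rate(1.0, 1L, p, 2.5), 0.4186)
  expect_equal(decision_rate(3.0, 1L, p, 2.5), 0.0413)
  expect_equal(decision_rate(1.0, -1L, p, 2.5), 0.0413)
  expect_equal(decision_rate(2.5, -1L, p, 2.5), 0.4186)  # boundary counts >=
  expect_equal(decision_rate(3.0, -1L, p, 2.5, sensing = FALSE), 0)
})

test_that("reversal sampling reproduces the per-step hazard and exponential law", {
  set.seed(5)
  n <- 1e6
  hits <- sum(sample_reversal(0.0413, 0.01, n))
  p_exact <- -expm1(-0.0413 * 0.01)   # 4.129e-4, computed independently
  expect_equal(p_exact, 4.129e-4, tolerance = 1e-3)
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(hits / n - p_exact), 4 * se)
  # inter-event times over constant-rate windows are Exp(rate)
  set.seed(6)
  dt <- 0.01
  steps <- sample_reversal(0.4186, dt, 3e5)
  gaps <- diff(which(steps)) * dt
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", 0.4186))
  expect_gt(ks$p.value, 0.01)
  # rate 0 never fires; coarse steps are rejected
  expect_false(any(sample_reversal(0, 0.1, 1000)))
  expect_error(sample_reversal(200, 0.01, 1), "too coarse")
})

test_that("reversal counts over a window are Poisson", {
  set.seed(7)
  lam <- 0.4186; T <- 50; dt <- 0.01
  counts <- replicate(300, sum(sample_reversal(lam, dt, T / dt)))
  m <- mean(counts)
  expect_lt(abs(m - lam * T), 4 * sqrt(lam * T / 300))
  expect_lt(abs(var(counts) / m - 1), 0.35)   # index of dispersion ~ 1
})

test_that("deterministic stepping is exact for straight swimming and fixed points", {
  st <- data.frame(x_um = 10, y_um = 0, phi_rad = 0, mode = 1L,
                   rate_per_s = 0)
  p <- motility_params(D_um2_s = 0, D_r_rad2_s = 0)
  out <- step_point(st, p, oxygen_env(enabled = FALSE),
                    magnetic_env(phi_B_rad = 0, k_per_s = 0), dt_s = 0.1)
  expect_equal(out$x_um, 10 + 2.66)
  expect_equal(out$y_um, 0)
  expect_equal(out$phi_rad, 0)
  # phi = phi_B is a fixed point of the alignment term
  st2 <- data.frame(x_um = 10, y_um = 0, phi_rad = 2.7, mode = 1L,
                    rate_per_s = 0)
  out2 <- step_point(st2, p, oxygen_env(enabled = FALSE),
                     magnetic_env(phi_B_rad = 2.7, k_per_s = 8), dt_s = 0.01)
  expect_equal(out2$phi_rad, 2.7)
  expect_error(step_point(st, p, mag = magnetic_env(k_per_s = 10), dt_s = 0.1),
               "stability")
})

test_that("compiled engine agrees with the R reference step for one step", {
  cfg <- quick_point_cfg(n = 12, t_final = 4)
  cfg$clock$record_every <- 1L
  ts <- run_point_simulation(cfg)
  # replay: regenerate the initial condition, then apply R steps
  set.seed(cfg$seed)
  n <- cfg$init$n_colonies
  x0 <- rep(0, n) + runif(n, 0, cfg$init$jitter_um)
  st <- data.frame(x_um = x0, y_um = 0, phi_rad = 2.7, mode = 1L,
                   rate_per_s = cfg$motility$lambda_minus_per_s)
  p <- do.call(motility_params, cfg$motility)
  oxy <- do.call(oxygen_env, cfg$environment$oxygen)
  mag <- do.call(magnetic_env, cfg$environment$magnetic)
  for (s in 1:3)
    st <- step_point(st, p, oxy, mag, cfg$clock$dt_s, t_s = s * cfg$clock$dt_s)
  frame3 <- ts[ts$time_s == 3 * cfg$clock$dt_s, ]
  expect_equal(frame3$x_um, st$x_um, tolerance = 1e-12)
  expect_equal(frame3$phi_rad, st$phi_rad, tolerance = 1e-12)
  expect_equal(frame3$mode, st$mode)
  expect_equal(frame3$rate_per_s, st$rate_per_s, tolerance = 1e-12)
})

test_that("deterministic alignment follows the tangent-half-angle closed form", {
  cfg <- deterministic_point_cfg(k = 5, phi0 = 0.7, dt = 1e-3)
  ts <- run_point_simulation(cfg)
  phi_num <- ts$phi_rad[nrow(ts)]
  phi_exact <- alignment_closed_form(1, 0.7, 2.7, 5)
  err1 <- abs(phi_num - phi_exact)
  cfg2 <- deterministic_point_cfg(k = 5, phi0 = 0.7, dt = 5e-4)
  err2 <- abs(utils::tail(run_point_simulation(cfg2)$phi_rad, 1) - phi_exact)
  expect_lt(err1, 5 * 1e-3)        # O(dt) error bound
  expect_lt(err2, err1)            # halving dt reduces the error
  # independent high-order oracle for the same ODE
  sol <- deSolve::ode(c(phi = 0.7), c(0, 1),
                      function(t, y, parms) list(5 * sin(2.7 - y)), NULL,
                      method = "ode45")
  expect_equal(phi_exact, unname(sol[2, "phi"]), tolerance = 1e-6)
  # relaxation time scales as 1/k: time to halve the tangent deviation
  t_half <- function(k) log(2) / k
  expect_equal(t_half(10) / t_half(5), 0.5)
  phi_k10 <- alignment_closed_form(t_half(10), 0.7, 2.7, 10)
  expect_equal(tan((2.7 - phi_k10) / 2), tan((2.7 - 0.7) / 2) / 2,
               tolerance = 1e-12)
})

test_that("ballistic limit: strong field, no noise, no reversals", {
  cfg <- deterministic_point_cfg(k = 40, phi0 = 2.7, dt = 1e-3, t_final = 2)
  ts <- run_point_simulation(cfg)
  last <- ts[nrow(ts), ]
  disp <- sqrt((last$x_um - ts$x_um[1])^2 + (last$y_um - ts$y_um[1])^2)
  expect_equal(disp, 26.6 * 2, tolerance = 1e-6)
})

test_that("free diffusion: MSD grows as 4 D t, orientations decay as exp(-Dr t)", {
  cfg <- quick_point_cfg(n = 400, t_final = 4, seed = 3)
  cfg$motility$v_jump_um_s <- 0
  cfg$motility$v_return_um_s <- 0
  cfg$motility$D_um2_s <- 1
  cfg$motility$D_r_rad2_s <- 0.5
  cfg$environment$magnetic$k_per_s <- 0
  cfg$environment$oxygen$enabled <- FALSE
  cfg$init$x0_um <- 500; cfg$init$jitter_um <- 0; cfg$init$phi0_rad <- 0.3
  ts <- run_point_simulation(cfg)
  t1 <- max(ts$time_s)
  first <- ts[ts$time_s == 0, ]; last <- ts[ts$time_s == t1, ]
  msd <- mean((last$x_um - first$x_um)^2 + (last$y_um - first$y_um)^2)
  se <- sqrt(2) * 4 * 1 * t1 / sqrt(400)   # chi-square spread
  expect_lt(abs(msd - 4 * 1 * t1), 4 * se)
  oc <- mean(cos(last$phi_rad - first$phi_rad))
  expect_lt(abs(oc - exp(-0.5 * t1)), 4 / sqrt(2 * 400))
})

test_that("dynamics are invariant under y-translation", {
  st <- data.frame(x_um = c(10, 10), y_um = c(0, 25), phi_rad = 1.2,
                   mode = 1L, rate_per_s = 0.0413)
  p <- motility_params()
  set.seed(9)
  out1 <- step_point(st[1, ], p, dt_s = 1e-3)
  set.seed(9)
  out2 <- step_point(st[2, ], p, dt_s = 1e-3)
  expect_equal(out1$x_um, out2$x_um)
  expect_equal(out1$phi_rad, out2$phi_rad)
  expect_equal(out2$y_um - out1$y_um, 25)
})

test_that("left fraction converges to the stationary law after the front passes", {
  cfg <- quick_point_cfg(n = 150, t_final = 17, seed = 21)
  ts <- run_point_simulation(cfg)
  lr <- left_right_series(ts)
  tail5 <- lr[lr$time_s >= 12, ]
  frac_left <- sum(tail5$n_left) / (sum(tail5$n_left) + sum(tail5$n_right))
  pi_left <- ctmc_stationary(ctmc_params(0.0413, 0.4186))[["pi_left"]]
  expect_lt(abs(frac_left - pi_left), 0.05)
})

test_that("run is bitwise reproducible for a fixed seed", {
  cfg <- quick_point_cfg(n = 10, t_final = 2, seed = 77)
  ts1 <- run_point_simulation(cfg)
  ts2 <- run_point_simulation(cfg)
  expect_identical(as.data.frame(ts1), as.data.frame(ts2))
  expect_identical(events(ts1), events(ts2))
})
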