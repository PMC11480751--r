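# Squirmer engine: geometry, interaction laws, force bookkeeping, limits

test_that("hexagonal lattice geometry is correct", {
  a <- 4.3
  l1 <- hexagonal_lattice(1, 10, spacing = 2.2, a_um = a)
  expect_equal(nrow(l1), 10)
  dmin <- min(dist(cbind(l1$x_um, l1$y_um)))
  expect_gte(dmin, 2.2 * a - 1e-9)
  l2 <- hexagonal_lattice(2, 10, spacing = 2.2, a_um = a)
  expect_equal(l2$x_um[11] - l2$x_um[1], 2.2 * a * sqrt(3) / 2)
  expect_equal(l2$y_um[11] - l2$y_um[1], 2.2 * a / 2)
  l8 <- hexagonal_lattice(8, 10, spacing = 2.2, a_um = a)
  expect_equal(nrow(l8), 80)
  expect_equal(max(l8$x_um) - min(l8$x_um), 7 * sqrt(3) / 2 * 2.2 * a)
  expect_error(hexagonal_lattice(2, 10, spacing = 1.5), "overlap")
})

test_that("self-propulsion gives the two mode speeds, rotation-invariantly", {
  expect_equal(self_propulsion(0, 1L), c(26.6, 0))
  expect_equal(self_propulsion(0, -1L), c(-7.6, 0))
  for (phi in c(0.3, 1.7, -2.2))
    expect_equal(sqrt(sum(self_propulsion(phi, 1L)^2)), 26.6)
})

test_that("pair forces vanish beyond the cutoff and obey Newton's third law", {
  p <- squirmer_params()
  far <- pair_interaction(list(x_um = 0, y_um = 0, phi_rad = 0),
                          list(x_um = 3.1 * 4.3, y_um = 0, phi_rad = pi))
  expect_equal(far$F_i, c(0, 0))
  expect_equal(far$tau_i, 0)
  set.seed(14)
  for (i in 1:25) {
    r <- runif(1, 2.001, 2.9) * 4.3
    th <- runif(1, -pi, pi)
    si <- list(x_um = 50, y_um = 0, phi_rad = runif(1, -pi, pi),
               mode = sample(c(-1L, 1L), 1))
    sj <- list(x_um = 50 + r * cos(th), y_um = r * sin(th),
               phi_rad = runif(1, -pi, pi), mode = sample(c(-1L, 1L), 1))
    vi <- c(rnorm(2, 0, 10), rnorm(1))
    vj <- c(rnorm(2, 0, 10), rnorm(1))
    f <- pair_interaction(si, sj, vi, vj, p)
    expect_equal(f$F_i + f$F_j, c(0, 0), tolerance = 1e-10)
  }
  expect_error(pair_interaction(list(x_um = 1, y_um = 1, phi_rad = 0),
                                list(x_um = 1, y_um = 1, phi_rad = 0)),
               "coincident")
})

test_that("normal lubrication shuts down head-on approach as the gap closes", {
  # two squirmers driven together: solved relative normal velocity -> 0
  p <- squirmer_params()
  a <- 4.3
  rel_v <- vapply(c(1, 0.3, 0.1, 0.03, 0.01), function(gap_frac) {
    st <- data.frame(x_um = c(300, 300 + 2 * a + gap_frac * a),
                     y_um = 0, phi_rad = c(0, pi), mode = 1L)
    out <- step_squirmers(st, p, oxy = oxygen_env(enabled = FALSE),
                          mag = magnetic_env(k_per_s = 0), nsteps = 1)
    out$velocities$Ux_um_s[1] - out$velocities$Ux_um_s[2]
  }, numeric(1))
  expect_true(all(diff(rel_v) < 0))       # closing speed drops with the gap
  expect_lt(rel_v[5], 0.15 * rel_v[1])
})

test_that("wall interaction: zero far away, stalls head-on swimmers, mirror-symmetric", {
  p <- squirmer_params()
  far <- wall_interaction(list(x_um = 3.5 * 4.3, y_um = 0, phi_rad = pi))
  expect_equal(far$F, c(0, 0))
  # jump-mode colony facing the wall reaches a stationary gap
  st <- data.frame(x_um = 4.3 + 1, y_um = 0, phi_rad = pi, mode = 1L)
  out <- step_squirmers(st, p, oxy = oxygen_env(enabled = FALSE),
                        mag = magnetic_env(phi_B_rad = pi, k_per_s = 20),
                        dt_s = 5e-4, nsteps = 4000)
  expect_lt(abs(out$velocities$Ux_um_s), 0.05)
  expect_gt(out$states$x_um, 4.3)          # no penetration
  expect_lt(out$states$x_um, 4.3 + 0.5)    # pinned near contact
  # mirror symmetry in y
  s1 <- list(x_um = 4.8, y_um = 0, phi_rad = 2.2, mode = 1L)
  s2 <- list(x_um = 4.8, y_um = 0, phi_rad = -2.2, mode = 1L)
  v1 <- c(3, 2, 0.5); v2 <- c(3, -2, -0.5)
  f1 <- wall_interaction(s1, v1, p)
  f2 <- wall_interaction(s2, v2, p)
  expect_equal(f1$F[1], f2$F[1], tolerance = 1e-10)
  expect_equal(f1$F[2], -f2$F[2], tolerance = 1e-10)
})

test_that("magnetic torque vanishes at both equilibria and matches the point engine", {
  env <- magnetic_env(phi_B_rad = 2.7, k_per_s = 5)
  expect_equal(magnetic_torque(list(phi_rad = 2.7), env), 0)
  expect_equal(magnetic_torque(list(phi_rad = 2.7 + pi), env), 0,
               tolerance = 1e-12)
  # isolated squirmer alignment follows the closed form of the point model
  st <- data.frame(x_um = 500, y_um = 0, phi_rad = 0.7, mode = 1L)
  out <- step_squirmers(st, oxy = oxygen_env(enabled = FALSE),
                        mag = env, dt_s = 1e-3, nsteps = 1000)
  expect_equal(out$states$phi_rad, alignment_closed_form(1, 0.7, 2.7, 5),
               tolerance = 5e-3)
})

test_that("isolated squirmer reproduces the point engine trajectory exactly", {
  cfg <- deterministic_point_cfg(k = 5, phi0 = 1.2, dt = 1e-3, t_final = 1)
  ts_point <- run_point_simulation(cfg)
  st <- data.frame(x_um = 500, y_um = 0, phi_rad = 1.2, mode = 1L)
  out <- step_squirmers(st, oxy = oxygen_env(enabled = FALSE),
                        mag = magnetic_env(phi_B_rad = 2.7, k_per_s = 5),
                        dt_s = 1e-3, nsteps = 1000)
  last <- ts_point[nrow(ts_point), ]
  expect_equal(out$states$x_um, last$x_um, tolerance = 1e-9)
  expect_equal(out$states$y_um, last$y_um, tolerance = 1e-9)
  expect_equal(out$states$phi_rad, last$phi_rad, tolerance = 1e-9)
})

test_that("no interpenetration over a crowded aerotactic run", {
  cfg <- quick_squirmer_cfg(n_layers = 2, t_final = 4, seed = 19)
  cfg$environment$magnetic$k_per_s <- 50
  ts <- run_squirmer_simulation(cfg)
  expect_gt(attr(ts, "min_gap_um"), -0.02)   # projection tolerance, ~0.5% of a
  # all wall gaps respected in the recorded frames
  expect_gte(min(ts$x_um), 4.3)
})

test_that("lattice dispersal at k = 0 and stability at large k", {
  cfg0 <- quick_squirmer_cfg(n_layers = 3, t_final = 8, seed = 23)
  cfg0$environment$oxygen$enabled <- FALSE
  cfg0$environment$magnetic$k_per_s <- 0
  ops0 <- order_parameter_series(run_squirmer_simulation(cfg0), window_s = 3)
  cfg50 <- cfg0
  cfg50$environment$magnetic$k_per_s <- 50
  ops50 <- order_parameter_series(run_squirmer_simulation(cfg50), window_s = 3)
  expect_lt(attr(ops0, "mean_Phi"), 0)
  expect_gt(attr(ops50, "mean_Phi"), 0.95)
  expect_lt(first_negative_time(ops0), 8)
})

test_that("zero colonies give empty outputs without error", {
  st <- data.frame(x_um = numeric(), y_um = numeric(), phi_rad = numeric(),
                   mode = integer())
  out <- step_squirmers(st, nsteps = 5)
  expect_equal(nrow(out$states), 0)
  expect_equal(nrow(out$events), 0)
})

test_that("squirmer runs are reproducible for a fixed seed", {
  cfg <- quick_squirmer_cfg(n_layers = 1, t_final = 1, seed = 5)
  ts1 <- run_squirmer_simulation(cfg)
  ts2 <- run_squirmer_simulation(cfg)
  expect_identical(as.data.frame(ts1), as.data.frame(ts2))
})
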