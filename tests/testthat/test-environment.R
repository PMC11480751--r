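# Oxygen profile, threshold front, and the magnetics-to-k conversion

test_that("oxygen profile matches the erfc solution against a quadrature oracle", {
  env <- oxygen_env(C0_uM = 100, D_C_um2_s = 2000)
  # independent oracle: erfc(1) = 2/sqrt(pi) * int_1^Inf exp(-s^2) ds
  erfc1 <- 2 / sqrt(pi) *
    integrate(function(s) exp(-s^2), 1, Inf, rel.tol = 1e-12)$value
  x <- 2 * sqrt(env$D_C_um2_s * 1)   # similarity variable = 1 at t = 1
  expect_equal(oxygen_concentration(x, 1, env), 100 * erfc1, tolerance = 1e-9)
  expect_equal(100 * erfc1, 15.7299, tolerance = 1e-4)
})

test_that("oxygen profile honours boundary, initial condition and bounds", {
  env <- oxygen_env(C0_uM = 250)
  expect_equal(oxygen_concentration(0, 5, env), 250)      # C(0, t) = C0
  expect_equal(oxygen_concentration(1e9, 5, env), 0)      # far field
  expect_equal(oxygen_concentration(10, 0, env), 0)       # t = 0, x > 0
  xs <- seq(0, 2000, by = 10)
  c1 <- oxygen_concentration(xs, 3, env)
  expect_true(all(c1 >= 0 & c1 <= 250))
  expect_true(all(diff(c1) <= 0))                         # decreasing in x
  c2 <- oxygen_concentration(500, c(1, 5, 20), env)
  expect_true(all(diff(c2) >= 0))                         # increasing in t
  expect_error(oxygen_concentration(-1, 1, env), "x_um")
  expect_error(oxygen_concentration(1, -1, env), "t_s")
})

test_that("disabled oxygen field returns zero everywhere", {
  env <- oxygen_env(enabled = FALSE)
  expect_equal(oxygen_concentration(c(0, 5, 100), 10, env), c(0, 0, 0))
})

test_that("profile satisfies the diffusion PDE under grid refinement", {
  env <- oxygen_env()
  resid <- function(h, dt) {
    x <- seq(50, 250, by = h); t0 <- 4
    ct <- (oxygen_concentration(x, t0 + dt, env) -
             oxygen_concentration(x, t0 - dt, env)) / (2 * dt)
    cxx <- (oxygen_concentration(x + h, t0, env) -
              2 * oxygen_concentration(x, t0, env) +
              oxygen_concentration(x - h, t0, env)) / h^2
    max(abs(ct - env$D_C_um2_s * cxx))
  }
  r1 <- resid(4, 0.04)
  r2 <- resid(2, 0.02)
  expect_lt(r2, r1 / 2)      # second-order residual shrinks under refinement
  expect_lt(r2, 0.05)        # and is small on the scale of C0 ~ 250 uM
})

test_that("concentration front inverts the profile and is self-similar", {
  env <- oxygen_env(C0_uM = 100, D_C_um2_s = 2000, c_star_uM = 100 * 0.15729921)
  # c_star = C0 * erfc(1) puts the front at similarity variable 1
  expect_equal(concentration_front(1, env), 2 * sqrt(2000), tolerance = 1e-4)
  env2 <- oxygen_env()
  for (t in c(0.5, 3, 10)) {
    xf <- concentration_front(t, env2)
    expect_equal(oxygen_concentration(xf, t, env2), env2$c_star_uM,
                 tolerance = 1e-6)
    expect_equal(concentration_front(4 * t, env2), 2 * xf, tolerance = 1e-5)
  }
  expect_error(concentration_front(1, oxygen_env(C0_uM = 2.5, c_star_uM = 2.5)),
               "threshold")
})

test_that("alignment rate follows the rotational mobility formula", {
  a <- 4.3e-6
  props <- colony_magnetics(eta_Pa_s = 1e-3, a_m = a,
                            m_Am2 = 8 * pi * 1e-3 * a^3 * 2.0, B_T = 1)
  expect_equal(alignment_rate(props), 2.0, tolerance = 1e-12)
  p2 <- props; p2$B_T <- 2 * props$B_T
  expect_equal(alignment_rate(p2), 2 * alignment_rate(props))
  p3 <- props; p3$a_m <- 2 * props$a_m
  expect_equal(alignment_rate(p3), alignment_rate(props) / 8)
  expect_error(colony_magnetics(0, a, 1e-15, 1e-3), "> 0")
})
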