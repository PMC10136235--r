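MMHG <- 1333.22

test_that("effective orifice area scales with the valve state and is floored", {
  expect_equal(effective_area(1, 0.6), 0.6)
  expect_equal(effective_area(0.5, 2.0), 1.0)
  expect_equal(effective_area(0, 1.5, zeta_min = 1e-4), 1.5e-4)
  expect_error(effective_area(1.2, 1), "zeta")
})

test_that("inertance and Bernoulli coefficient match hand CGS evaluation", {
  # L = rho * leff / Aeff in CGS, converted through 1 mmHg = 1333.22 dyn/cm^2
  expect_equal(valve_inertance(0.6, 1.5, rho = 1.06) * MMHG,
               1.06 * 1.5 / 0.6, tolerance = 1e-12)
  expect_equal(valve_inertance(1.2, 1.5), valve_inertance(0.6, 1.5) / 2)
  expect_equal(valve_inertance(0.6, 0), 0)

  beta_cgs <- 1.5 * (1.06 / 2) * (1 / 0.6 - 1 / 5.3)^2
  expect_equal(bernoulli_coeff(0.6, 5.3, kt = 1.5, rho = 1.06) * MMHG,
               beta_cgs, tolerance = 1e-12)
  expect_equal(bernoulli_coeff(2, 2), 0)
  # monotone decreasing in the effective area
  b <- bernoulli_coeff(seq(0.4, 2, by = 0.2), 5.3)
  expect_true(all(diff(b) < 0))
})

test_that("gradient decomposition behaves at its limits", {
  expect_equal(valve_dp(0, 0, 1, 1), 0)
  expect_equal(valve_dp(10, 0, 1, 0.02), 0.02 * 100)   # steady: beta Q^2
  expect_lt(valve_dp(-10, 0, 1, 0.02), 0)              # sign preserved
  # turbulent term always dissipates: beta * Q|Q| * Q >= 0
  q <- seq(-100, 100, by = 10)
  expect_true(all(0.02 * q * abs(q) * q >= 0))
})

test_that("valve state ODE matches its closed-form solution", {
  kvo <- 0.3; dp <- 20; dt <- 1e-4
  z <- 0
  tt <- seq(dt, 0.3, by = dt)
  for (i in seq_along(tt)) z[i + 1] <- valve_zeta_step(z[i], dp, dt, kvo)
  exact <- 1 - exp(-kvo * dp * tt)
  expect_lt(max(abs(z[-1] - exact) / pmax(exact, 1e-3)), 1e-3)
  # absorbing ends: fully open valve cannot open further, closed cannot close
  expect_equal(valve_zeta_step(1, 50, 1e-3, 0.3), 1)
  expect_equal(valve_zeta_step(0, -50, 1e-3, 0.3), 0)
})

test_that("flow ODE relaxes to the algebraic Bernoulli balance", {
  vp <- valve_params(ava = 1, ao = 5, kt = 1.5, kvo = 0.3)
  beta <- bernoulli_coeff(1, 5, 1.5)
  dp <- 25
  q <- 0
  for (i in 1:40000) q <- valve_flow_step(q, dp, zeta = 1, dt = 1e-4, vp)
  expect_equal(q, sqrt(dp / beta), tolerance = 1e-6)
  # fixed point at rest, diode when closed against a negative gradient
  expect_equal(valve_flow_step(0, 0, 1, 1e-4, vp), 0)
  expect_equal(valve_flow_step(5, -10, 1e-5, 1e-4, vp), 0)
  # zero effective length: algebraic form, sign following the gradient
  vp0 <- valve_params(ava = 1, ao = 5, leff = 0, kvo = 0.3)
  expect_equal(valve_flow_step(0, 25, 1, 1e-4, vp0), sqrt(25 / beta))
  expect_equal(valve_flow_step(0, -25, 1, 1e-4, vp0), -sqrt(25 / beta))
})

test_that("valve parameter validation enforces the area ordering", {
  expect_error(valve_params(ava = 6, ao = 5.3), "ao")
  expect_error(valve_params(ava = -1), "ava")
})
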