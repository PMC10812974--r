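test_that("activation dynamics reach the closed-form asymptote", {
  p <- activation_profile("ode", u = 0.5, tau_rise = 0.02, tau_fall = 0.2)
  expect_equal(activation_value(0, p), 0)
  expect_equal(activation_steady_state(p), 10 / 11, tolerance = 1e-12)
  expect_equal(round(activation_steady_state(p), 2), 0.91)
  expect_equal(activation_value(100, p), 10 / 11, tolerance = 1e-10)
  expect_error(activation_value(-1, p), "non-negative")
})

test_that("fiber-type time constants change the rate, not the asymptote", {
  fast <- activation_profile("ode", u = 0.5, tau_rise = 0.1, tau_fall = 1.0)
  slow <- activation_profile("ode", u = 0.5, tau_rise = 0.3, tau_fall = 3.0)
  expect_equal(activation_steady_state(fast), activation_steady_state(slow))
  expect_equal(activation_steady_state(fast), 10 / 11, tolerance = 1e-12)
  # rate constants k = u/tau_rise + (1-u)/tau_fall
  expect_equal(musclefem:::ode_rate_constant(fast), 5.5)
  expect_equal(musclefem:::ode_rate_constant(slow), 11 / 6,
               tolerance = 1e-12)
  # the fast-twitch population leads at every finite time
  t <- seq(0.01, 3, by = 0.01)
  expect_true(all(activation_value(t, fast) > activation_value(t, slow)))
})

test_that("activation is monotone in time and in excitation", {
  t <- seq(0, 2, by = 0.01)
  for (u in c(0.1, 0.3, 0.5)) {
    p <- activation_profile("ode", u = u)
    a <- activation_value(t, p)
    expect_true(all(diff(a) >= 0))
    expect_true(all(a >= 0 & a <= activation_steady_state(p) + 1e-12))
  }
  # raising u never decreases activation at fixed time
  a1 <- activation_value(t, activation_profile("ode", u = 0.2))
  a2 <- activation_value(t, activation_profile("ode", u = 0.4))
  expect_true(all(a2 >= a1))
})

test_that("linear ramps rise to the plateau at t_peak", {
  p <- activation_profile("linear_ramp", t_peak = 0.2, alpha_max = 0.91)
  expect_equal(ramp_value(0, p), 0)
  expect_equal(ramp_value(0.1, p), 0.455)
  expect_equal(ramp_value(0.2, p), 0.91)
  expect_equal(ramp_value(5, p), 0.91)
  expect_true(all(ramp_value(seq(0, 1, 0.01), p) <= 0.91))
  expect_error(activation_profile("linear_ramp", alpha_max = 1.5), "alpha_max")
  expect_error(activation_profile("ode", u = 0.7), "0.5")
})
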