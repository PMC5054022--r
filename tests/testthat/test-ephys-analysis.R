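test_that("single-exponential fits recover constructed decays exactly", {
  t <- seq(0, 120, by = 0.5)
  f <- fit_exponential(t, 50 * exp(-t / 23.5))
  expect_true(f$converged)
  expect_equal(f$tau, 23.5, tolerance = 1e-6)
  expect_equal(f$amplitude, 50, tolerance = 1e-6)
  t2 <- seq(0, 40, by = 0.1)
  f2 <- fit_exponential(t2, 100 * exp(-t2 / 7.64))
  expect_equal(f2$tau, 7.64, tolerance = 1e-6)
  # constant trace flagged degenerate, never a silent failure
  fd <- fit_exponential(t, rep(3.2, length(t)))
  expect_true(fd$degenerate)
  expect_equal(fd$amplitude, 0)
  # idempotence: refitting the fitted curve returns the same parameters
  pred <- f$amplitude * exp(-t / f$tau) + f$offset
  f3 <- fit_exponential(t, pred)
  expect_equal(f3$tau, f$tau, tolerance = 1e-6)
  expect_equal(f3$amplitude, f$amplitude, tolerance = 1e-6)
})

test_that("Boltzmann curve fits recover generating parameters and are idempotent", {
  v <- seq(-60, 30, by = 5)
  spec <- boltzmann_spec(-12.3, z = 3.8, amplitude = 8.08)
  g <- boltzmann_eval(spec, v)
  fit <- fit_boltzmann_curve(v, g, direction = "rising")
  expect_equal(fit$v_half, -12.3, tolerance = 1e-6)
  expect_equal(fit$z, 3.8, tolerance = 1e-6)
  expect_equal(fit$amplitude, 8.08, tolerance = 1e-6)
  expect_equal(fit$z * fit$k, 25.69, tolerance = 1e-9)
  # falling form with an additive offset
  yf <- 0.25 + 0.9 / (1 + exp((v + 52.7) / 7.59))
  ff <- fit_boltzmann_curve(v, yf, direction = "falling", with_offset = TRUE)
  expect_equal(ff$v_half, -52.7, tolerance = 1e-5)
  expect_equal(ff$k, 7.59, tolerance = 1e-5)
  expect_equal(ff$offset, 0.25, tolerance = 1e-5)
})

test_that("time-to-peak measurement matches the closed form", {
  # I(t) = (1 - e^(-t/1))^3 e^(-t/20) * 100 peaks at tau_m ln(1 + p tau_h/tau_m)
  dt <- 0.01
  tm <- seq(0, 110, by = dt)
  i <- ifelse(tm < 10, 0,
              (1 - exp(-(tm - 10) / 1))^3 * exp(-(tm - 10) / 20) * 100)
  rec <- fake_vc_recording(tm, i, pre_duration = 10, step_duration = 100)
  pk <- peak_and_ttp(rec)
  expect_equal(pk$ttp, 1 * log(1 + 3 * 20 / 1), tolerance = 0.02)
  expect_false(pk$degenerate)
  # a monotone trace flags its extremum at the window edge
  mono <- fake_vc_recording(tm, pmin(tm, 200), 10, 100)
  expect_true(peak_and_ttp(mono)$at_end)
})

test_that("zero-time extrapolation recovers the open-channel current", {
  dt <- 0.01
  tm <- seq(0, 210, by = dt)
  i <- ifelse(tm < 10, 0,
              100 * (1 - exp(-(tm - 10) / 0.5))^3 * exp(-(tm - 10) / 20))
  rec <- fake_vc_recording(tm, i, 10, 200)
  ttp <- peak_and_ttp(rec)$ttp
  expect_equal(zero_time_current(rec, ttp)$i0, 100, tolerance = 0.02)
  # a pure exponential from the onset extrapolates exactly
  i2 <- ifelse(tm < 10, 0, 80 * exp(-(tm - 10) / 15))
  rec2 <- fake_vc_recording(tm, i2, 10, 200)
  expect_equal(zero_time_current(rec2, 1)$i0, 80, tolerance = 1e-5)
})

test_that("zero-time current of a simulated A step equals the gate identity", {
  m <- a_only_model()
  rec <- run_vc_family(m, -100, 250, 20, 200, dt = 0.01)[[1]]
  ttp <- peak_and_ttp(rec)$ttp
  i0 <- zero_time_current(rec, ttp)$i0
  a_inf <- gate_steady_state(m$channels$A$gates[[1]], 20)
  expect_equal(i0, 8.08 * a_inf^3 * (20 - -101), tolerance = 0.03)
})

test_that("conductance conversion and steady-state extraction behave", {
  expect_equal(conductance_curve(c(-40, 0, 40), c(0, 0, 0), -101)$g,
               c(0, 0, 0))
  expect_warning(conductance_curve(c(-101, 0), c(1, 1), -101), "excluded")
  # linear ohmic relation through the reversal gives a constant conductance
  v <- seq(-60, 40, 10)
  gv <- conductance_curve(v, 2.5 * (v - -101), -101)
  expect_equal(gv$g, rep(2.5, length(v)))
  # cube root at the base half-point
  spec <- boltzmann_spec(-12.3, z = 3.8, amplitude = 8.08)
  grid <- sort(c(seq(-60, 40, 5), -12.3))
  ss <- steady_state_from_conductance(
    data.frame(v = grid, g = boltzmann_eval(spec, grid)), 8.08, root = 3)
  expect_equal(ss$curve$x_inf[ss$curve$v == -12.3], 0.5^(1 / 3),
               tolerance = 1e-9)
  expect_warning(
    steady_state_from_conductance(data.frame(v = 0, g = c(9, 1, 1, 1, 1)),
                                  8.08), "clipped")
})

test_that("activation midpoints extracted by cube root match the analytic fit oracle", {
  # oracle: Boltzmann fit of the exact cube-root curve itself (no simulation)
  oracle_fit <- function(v_half, z, v) {
    base <- 1 / (1 + exp(z * (v_half - v) / 25.69))
    fit_boltzmann_curve(v, base^(1 / 3), direction = "rising")
  }
  a <- analyze_a_current()
  ora <- oracle_fit(-12.3, 3.8, a$ss$curve$v)
  expect_equal(a$ss$fit$v_half, ora$v_half, tolerance = 0.01)
  # the curve itself crosses one half exactly at V0 - k ln 7
  cross <- stats::approx(a$ss$curve$x_inf, a$ss$curve$v, xout = 0.5)$y
  expect_equal(cross, -12.3 - (25.69 / 3.8) * log(7), tolerance = 0.5)
  na <- analyze_na_current()
  ora_na <- oracle_fit(-34.6, 4.3, na$ss$curve$v)
  expect_equal(na$ss$fit$v_half, ora_na$v_half, tolerance = 0.01)
  cross_na <- stats::approx(na$ss$curve$x_inf, na$ss$curve$v, xout = 0.5)$y
  expect_equal(cross_na, -34.6 - (25.69 / 4.3) * log(7), tolerance = 0.5)
})

test_that("availability and recovery fits recover constructed curves", {
  v <- seq(-110, -10, 10)
  peaks <- 230 / (1 + exp((v + 52.7) / 7.59))
  fit <- inactivation_curve(v, peaks)
  expect_equal(fit$v_half, -52.7, tolerance = 1e-5)
  expect_equal(fit$k, 7.59, tolerance = 1e-5)
  gaps <- c(2, 5, 10, 20, 40, 80, 160)
  rfit <- recovery_tau(gaps, 150 * (1 - exp(-gaps / 23.5)))
  expect_equal(rfit$tau, 23.5, tolerance = 1e-5)
  expect_equal(rfit$amplitude, 150, tolerance = 1e-4)
  # gaps all far beyond tau cannot constrain it
  far <- recovery_tau(c(200, 260, 320, 380, 440), 150 * (1 - exp(-c(200, 260, 320, 380, 440) / 20)))
  expect_true(far$poorly_constrained)
  expect_warning(recovery_tau(gaps, rev(seq_along(gaps))), "monotone")
})

test_that("Newton inversion of the time-to-peak equation round-trips", {
  # forward closed form
  ttp <- function(tm, th, p) tm * log(1 + p * th / tm)
  expect_equal(ttp(1, 20.32, 4), log(1 + 4 * 20.32), tolerance = 1e-12)
  expect_equal(tau_m_from_ttp(ttp(1, 20.32, 4), 20.32, p = 4), 1,
               tolerance = 1e-6)
  # special case p = 1, tau_h = tau_m: ttp = tau ln 2
  expect_equal(tau_m_from_ttp(5 * log(2), 5, p = 1), 5, tolerance = 1e-6)
  # round trip across a grid of orders and time constants
  for (p in c(1, 3, 4)) for (tm in c(0.2, 1, 4)) {
    expect_equal(tau_m_from_ttp(ttp(tm, 12, p), 12, p), tm, tolerance = 1e-6)
  }
  expect_error(tau_m_from_ttp(100, 20, p = 4), "no root")
})

test_that("reversal potential extrapolation from the last four points", {
  v <- c(-20, -10, 0, 10, 20, 30, 40)
  i <- 3.1 * (v - 61.4)
  expect_equal(reversal_from_linreg(v, i), 61.4, tolerance = 1e-9)
  expect_equal(reversal_from_linreg(c(0, 10), c(-5, 5), last_n = 2), 5)
  expect_error(reversal_from_linreg(v, rep(1, 7)), "zero slope")
})

test_that("h-current analysis measures amplitudes and handles the null model", {
  h0 <- analyze_h_current(reference_cr_cell(g_h = 0),
                          step_levels = seq(-130, -70, 20),
                          step_duration = 1000, dt = 0.1)
  expect_true(all(abs(h0$amplitudes$i_h) < 0.5))
  h <- analyze_h_current(step_levels = seq(-130, -60, 10),
                         step_duration = 5000, dt = 0.1)
  amp <- h$amplitudes
  expect_gt(abs(amp$i_h[amp$v == -130]), abs(amp$i_h[amp$v == -90]))
  expect_true(all(amp$i_h[amp$v <= -90] < 0))
})

test_that("persistent amplitude averages the late window against baseline", {
  tm <- seq(0, 110, 0.05)
  i <- ifelse(tm < 10, 5, -15)  # constant -20 pA step from a +5 baseline
  rec <- fake_vc_recording(tm, i, 10, 100)
  expect_equal(persistent_amplitude(rec), -20)
  iv0 <- analyze_ca_current(reference_cr_cell(g_ca = 0),
                            step_levels = c(-40, 0, 40), dt = 0.05)
  expect_true(all(abs(iv0$i) < 1e-9))
})

test_that("passive fit refuses spiking traces", {
  m <- reference_cr_cell()
  i_hold <- holding_current(m, -70)
  rheo <- find_rheobase(m, pulse_width = 200, dt = 0.02)
  rec <- simulate(m, protocol("cc", c(50, 200, 50),
                              c(i_hold, i_hold + 2 * rheo, i_hold)), dt = 0.02)
  expect_error(passive_from_step(rec), "spike")
})
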