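test_that("Boltzmann evaluation matches direct arithmetic and its invariants", {
  spec <- boltzmann_spec(v_half = -12.3, z = 3.8, amplitude = 8.08)
  # half-maximum at the half-point
  expect_equal(boltzmann_eval(spec, -12.3), 8.08 / 2, tolerance = 1e-12)
  # direct evaluation at 0 mV
  expect_equal(boltzmann_eval(spec, 0),
               8.08 / (1 + exp(3.8 * (-12.3 - 0) / 25.69)),
               tolerance = 1e-12)
  # saturation
  expect_lt(abs(boltzmann_eval(spec, 100) - 8.08) / 8.08, 0.001)
  # strictly inside (0, amplitude) for finite V
  v <- seq(-140, 100, by = 5)
  y <- boltzmann_eval(spec, v)
  expect_true(all(y > 0 & y < 8.08))
  # z and k tied by the thermal voltage
  expect_equal(spec$z * spec$k, 25.69, tolerance = 1e-9)
  expect_error(boltzmann_spec(-12.3, z = 3.8, k = 10), "inconsistent")
  expect_error(boltzmann_eval(spec, NaN), "non-finite")
})

test_that("rising and falling Boltzmann forms are exact mirrors", {
  for (d in c(0.1, 1, 7, 23, 60)) {
    r <- boltzmann_spec(-30, k = 8, direction = "rising")
    f <- boltzmann_spec(-30, k = 8, direction = "falling")
    expect_equal(boltzmann_eval(r, -30 + d), boltzmann_eval(f, -30 - d),
                 tolerance = 1e-12)
  }
})

test_that("gate steady states, including root-of-Boltzmann forms", {
  m <- reference_cr_cell()
  a <- m$channels$A$gates[[1]]
  ha <- m$channels$A$gates[[2]]
  mg <- m$channels$Na$gates[[1]]
  expect_equal(gate_steady_state(ha, -52.7), 0.5, tolerance = 1e-12)
  expect_equal(gate_steady_state(a, -12.3), 0.5^(1 / 3), tolerance = 1e-12)
  # at strong hyperpolarization the channel is shut: the open fraction is
  # the gate cubed (the cube-root gate itself only falls below ~1e-2)
  expect_lt(gate_steady_state(mg, -120)^3, 1e-5)
  # probabilities over the full range
  v <- seq(-140, 60, by = 2)
  for (g in list(a, ha, mg))
    expect_true(all(gate_steady_state(g, v) >= 0 &
                    gate_steady_state(g, v) <= 1))
})

test_that("cube-root steady state cubed reproduces the conductance equation", {
  # the identity the zero-time analysis round-trips rely on
  m <- reference_cr_cell()
  a <- m$channels$A$gates[[1]]
  eq1 <- boltzmann_spec(-12.3, z = 3.8, amplitude = 8.08)
  v <- seq(-90, 60, by = 1.5)
  expect_equal(8.08 * gate_steady_state(a, v)^3, boltzmann_eval(eq1, v),
               tolerance = 1e-12)
})

test_that("tau laws evaluate the printed equations, bridge the gaps, and floor", {
  m <- reference_cr_cell()
  ha <- m$channels$A$gates[[2]]
  # removal-of-inactivation branch at -70 mV
  expect_equal(gate_tau(ha, -70), 2968.8 * exp(-70 / 15.27) + 11.86,
               tolerance = 1e-9)
  # quadratic development branch at 0 mV
  expect_equal(gate_tau(ha, 0), 20.32, tolerance = 1e-12)
  # branch values at the declared boundaries agree with the bridge
  expect_equal(gate_tau(ha, -30), 20.32 + 0.09846 * -30 + 0.00227 * 900,
               tolerance = 1e-9)
  # linear bridge midway between the two branch endpoints
  y70 <- gate_tau(ha, -70); y30 <- gate_tau(ha, -30)
  expect_equal(gate_tau(ha, -50), (y70 + y30) / 2, tolerance = 1e-9)
  # floor clamps a law that goes negative (the h-current tau at -130 mV)
  n <- m$channels$h$gates[[1]]
  expect_equal(gate_tau(n, -130), 30)
  expect_gt(gate_tau(n, -60), 1000)
  # all reference tau laws positive, finite and continuous on [-140, 60]
  v <- seq(-140, 60, by = 0.05)
  for (ch in m$channels) for (g in ch$gates) {
    tau <- gate_tau(g, v)
    expect_true(all(is.finite(tau) & tau > 0))
    expect_lt(max(abs(diff(tau)) / pmax(tau[-1], 1e-6)), 0.05)
  }
})

test_that("Nernst potential matches high-precision constants and the Na check", {
  # printed solution compositions: 152.25 mM out, 14 mM in
  expect_lt(abs(nernst(152.25, 14, 1, 25) - 61.4), 0.1)
  expect_equal(nernst(7, 7, 1, 25), 0)
  # independent constant set (CODATA R and F), 0.1 mV agreement
  oracle <- 1e3 * 8.314462618 * 298.15 / 96485.33212 * log(2.5 / 120)
  expect_lt(abs(nernst(2.5, 120, 1, 25) - oracle), 0.1)
  expect_error(nernst(-1, 10), "positive")
  # divalent halves the slope
  expect_equal(nernst(10, 1, 2, 25), nernst(10, 1, 1, 25) / 2)
})

test_that("the reference cell carries the printed passive parameters", {
  m <- reference_cr_cell()
  expect_equal(m$g_leak, 1e3 / 1877.7, tolerance = 1e-12)
  expect_equal(m$c_m, 4.07)
  # membrane time constant R_in * C_m
  expect_equal(m$c_m / m$g_leak, 4.07 * 1.8777, tolerance = 1e-3)
  # every channel current vanishes at its reversal potential
  for (ch in m$channels) {
    open <- 1
    for (g in ch$gates) open <- open * gate_steady_state(g, ch$e_rev)^g$p
    expect_equal(ch$g_max * open * (ch$e_rev - ch$e_rev), 0)
  }
})

test_that("with all channels off the cell rests at the leak reversal", {
  m <- passive_model()
  rec <- simulate(m, protocol("cc", 500, 0), dt = 0.05)
  expect_lt(max(abs(rec$data$v - -70)), 1e-9)
  expect_equal(resting_potential(m), -70, tolerance = 1e-6)
})
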