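test_that("passive current-clamp step obeys Ohm's law", {
  m <- passive_model()
  rec <- simulate(m, protocol("cc", c(50, 300), c(0, -15)), dt = 0.01)
  late <- rec$data$v[rec$data$time > 300]
  expect_equal(mean(late) - -70, -15 / m$g_leak, tolerance = 1e-4)
})

test_that("the held reference cell is stationary at -70 mV", {
  m <- reference_cr_cell()
  i_hold <- holding_current(m, -70)
  rec <- simulate(m, protocol("cc", 1000, i_hold), dt = 0.01,
                  record_gates = FALSE)
  expect_lt(max(abs(rec$data$v - -70)), 0.5)
})

test_that("voltage clamp is ideal and bookkeeping is exact", {
  m <- reference_cr_cell()
  rec <- simulate(m, protocol("vc", c(50, 100, 50), c(-100, 0, -70)), dt = 0.01)
  # V equals the command at every sample
  b <- c(0, 50, 150, 200)
  cmd <- ifelse(rec$data$time < 50, -100, ifelse(rec$data$time < 150, 0, -70))
  expect_identical(rec$data$v, cmd)
  # total current equals leak plus the per-channel currents, exactly
  chan_sum <- rowSums(rec$data[, paste0("i_", names(m$channels))])
  expect_equal(rec$data$i, rec$data$i_leak + chan_sum, tolerance = 1e-12)
})

test_that("exponential-Euler gate updates equal the analytic relaxation", {
  m <- a_only_model()
  rec <- simulate(m, protocol("vc", c(50, 80), c(-100, -20)), dt = 0.01)
  sel <- rec$data$time >= 50
  t <- rec$data$time[sel] - 50
  for (g in m$channels$A$gates) {
    x0 <- gate_steady_state(g, -100)
    xinf <- gate_steady_state(g, -20)
    tau <- gate_tau(g, -20)
    analytic <- xinf - (xinf - x0) * exp(-t / tau)
    expect_lt(max(abs(rec$data[[paste0("gate_", g$name)]][sel] - analytic)),
              1e-9)
  }
})

test_that("depolarizations from -100 mV evoke transient currents with no sustained outward component", {
  m <- reference_cr_cell()
  recs <- run_vc_family(m, -100, 250, seq(-40, 40, 10), 200, dt = 0.01)
  for (rec in recs) {
    step <- rec$data$time >= 250
    i <- rec$data$i[step]
    v_step <- rec$segments$level[2]
    # fast transient inward (Na) then transient outward (A)
    expect_lt(min(i[1:5000]), 0)
    if (v_step >= -30) expect_gt(max(i), 0)
    # at the step end no sustained OUTWARD component remains beyond the leak
    # (no delayed rectifier); persistent inward window currents are allowed
    late <- mean(i[(length(i) - 1000):length(i)])
    leak_line <- m$g_leak * (v_step - m$e_leak)
    if (v_step >= -30)
      expect_lt(late - leak_line, 0.12 * max(i))
  }
})

test_that("A-current family grows monotonically and needs hyperpolarized preconditioning", {
  m <- a_only_model()
  steps <- seq(-40, 40, 10)
  recs <- run_vc_family(m, -100, 250, steps, 200, dt = 0.01)
  peaks <- vapply(recs, function(r) peak_and_ttp(r)$peak, 0)
  expect_true(all(diff(peaks) > 0))
  # preconditioning at -50 mV suppresses the family exactly as the
  # availability curve dictates (ha_inf(-50)/ha_inf(-100) ~ 0.41)
  recs50 <- run_vc_family(m, -50, 250, steps, 200, dt = 0.01)
  peaks50 <- vapply(recs50, function(r) peak_and_ttp(r)$peak, 0)
  ha <- m$channels$A$gates[[2]]
  expected_ratio <- gate_steady_state(ha, -50) / gate_steady_state(ha, -100)
  expect_true(all(abs(peaks50 / peaks - expected_ratio) < 0.03))
  expect_true(all(peaks50 < 0.5 * peaks))
  # a step to the reversal potential draws no channel current
  rec_rev <- run_vc_family(m, -100, 250, -101, 200, dt = 0.01)[[1]]
  expect_lt(max(abs(rec_rev$data$i_A[rec_rev$data$time >= 250])), 1e-9)
})

test_that("steady-state inactivation protocol reproduces the availability curve", {
  m <- a_only_model()
  recs <- run_inactivation_protocol(m, c(-100, -52.7, -10), 500, 20, dt = 0.01)
  peaks <- vapply(recs, function(r) peak_and_ttp(r)$peak, 0)
  expect_equal(peaks[2] / peaks[1], 0.5 / gate_steady_state(
    m$channels$A$gates[[2]], -100), tolerance = 0.02)
  expect_lt(peaks[3] / peaks[1], 0.01)
  expect_warning(
    run_inactivation_protocol(m, c(-100, -50), 50, 20, dt = 0.05),
    "steady state")
})

test_that("double-pulse recovery follows the gate relaxation at the recovery potential", {
  m <- a_only_model()
  gaps <- c(0, 5, 10, 20, 35, 55, 80, 120, 180, 260)
  recs <- run_recovery_protocol(m, 20, 150, -90, gaps, 20, dt = 0.01)
  peaks <- vapply(recs, function(r)
    peak_and_ttp(r, step_segment = nrow(r$segments))$peak, 0)
  # no recovery at zero gap; full recovery for long gaps
  expect_lt(peaks[1], 0.03 * max(peaks))
  uncond <- peak_and_ttp(run_vc_family(m, -90, 400, 20, 50, dt = 0.01)[[1]])$peak
  expect_gt(peaks[length(peaks)], 0.95 * uncond)
  expect_true(all(diff(peaks) > -1e-9))
  # single-exponential fit recovers tau_ha(-90) within 10%
  fit <- recovery_tau(gaps, peaks)
  expect_lt(abs(fit$tau - gate_tau(m$channels$A$gates[[2]], -90)) /
            gate_tau(m$channels$A$gates[[2]], -90), 0.10)
})

test_that("spike detection finds single spikes and rejects voltage clamp", {
  m <- reference_cr_cell()
  i_hold <- holding_current(m, -70)
  flat <- simulate(m, protocol("cc", 200, i_hold), dt = 0.01,
                   record_gates = FALSE)
  expect_equal(nrow(detect_spikes(flat)), 0)
  rheo <- find_rheobase(m, pulse_width = 200, dt = 0.01)
  rec <- simulate(m, protocol("cc", c(50, 200, 100),
                              c(i_hold, i_hold + 1.5 * rheo, i_hold)),
                  dt = 0.01, record_gates = FALSE)
  sp <- detect_spikes(rec)
  expect_equal(nrow(sp), 1)
  expect_gt(sp$amplitude, 0)
  expect_lte(sp$onset, sp$peak_time)
  vc <- simulate(m, protocol("vc", 50, -70), dt = 0.05)
  expect_error(detect_spikes(vc), "current-clamp")
})

test_that("ten-fold faster removal of Na inactivation yields two spikes at 50 ms pairing", {
  m <- reference_cr_cell()
  m_fast <- modify_channel(m, "Na", tau_scale = 0.1, gate = "h",
                           tau_branches = 1)
  expect_equal(gate_tau(m_fast$channels$Na$gates[[2]], -90),
               (3853 * exp(-90 / 17.58) + 5.11) / 10, tolerance = 1e-9)
  # development branch untouched
  expect_equal(gate_tau(m_fast$channels$Na$gates[[2]], 0),
               0.0679 * exp(0) + 5.43, tolerance = 1e-9)
  amp <- 1.1 * crpg:::.prompt_rheobase(m_fast, 10)
  rec <- run_paired_pulse_cc(m_fast, amp, 10, 50, dt = 0.01)[[1]]
  expect_equal(nrow(detect_spikes(rec)), 2)
})

test_that("late-phase I-V of the passive cell is a perfect resistor line", {
  m <- passive_model()
  recs <- lapply(seq(-15, 45, 10), function(amp)
    simulate(m, protocol("cc", c(50, 300, 50), c(0, amp, 0)), dt = 0.02,
             record_gates = FALSE))
  iv <- late_phase_iv(recs, window = 50)
  expect_gt(iv$r_squared, 1 - 1e-9)
  expect_equal(iv$slope_mohm, 1877.7, tolerance = 1e-5)
})

test_that("protocol validation rejects bad configurations", {
  m <- passive_model()
  expect_error(simulate(m, protocol("cc", 100, 0), dt = 0),
               "dt must be positive")
  expect_error(protocol("cc", numeric(0), numeric(0)), "durations")
  expect_error(protocol("vc", c(10, -5), c(0, 0)))
  expect_error(run_vc_family(m, -100, 250, numeric(0), 100), "empty")
})
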