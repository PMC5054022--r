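test_that("recording noise is seed-deterministic and zero noise is exact", {
  m <- a_only_model()
  p <- protocol("vc", c(100, 100), c(-100, 20), sweep_segment = 2,
                sweep_levels = c(0, 20))
  clean <- generate_recording_set(m, p, noise_spec(0, 0, seed = 7), dt = 0.02)
  direct <- lapply(protocol_sweeps(p), simulate, model = m, dt = 0.02)
  expect_equal(clean$recordings[[1]]$data$i, direct[[1]]$data$i)
  s1 <- generate_recording_set(m, p, noise_spec(2, 0, seed = 11), dt = 0.02)
  s2 <- generate_recording_set(m, p, noise_spec(2, 0, seed = 11), dt = 0.02)
  s3 <- generate_recording_set(m, p, noise_spec(2, 0, seed = 12), dt = 0.02)
  expect_identical(s1$recordings[[2]]$data$i, s2$recordings[[2]]$data$i)
  expect_false(identical(s1$recordings[[2]]$data$i, s3$recordings[[2]]$data$i))
  expect_equal(s1$recordings[[2]]$noise_sd, 2)
})

test_that("zero-time estimates survive 2 pA recording noise", {
  m <- a_only_model()
  rec <- run_vc_family(m, -100, 250, 20, 200, dt = 0.01)[[1]]
  ttp <- peak_and_ttp(rec)$ttp
  i0_clean <- zero_time_current(rec, ttp)$i0
  set.seed(42)
  for (rep in 1:5) {
    noisy <- rec
    noisy$data$i <- noisy$data$i + rnorm(nrow(noisy$data), 0, 2)
    expect_lt(abs(zero_time_current(noisy, ttp)$i0 - i0_clean) / i0_clean,
              0.05)
  }
})

test_that("Boltzmann recovery stays within 5% under 2% peak current noise", {
  m <- a_only_model()
  steps <- seq(-40, 40, 10)
  recs <- run_vc_family(m, -100, 250, steps, 200, dt = 0.02)
  set.seed(1)
  for (rep in 1:20) {
    i0 <- vapply(recs, function(r) {
      noisy <- r
      sd_i <- 0.02 * abs(peak_and_ttp(r)$peak)
      noisy$data$i <- noisy$data$i + rnorm(nrow(noisy$data), 0, sd_i)
      zero_time_current(noisy, peak_and_ttp(r)$ttp)$i0
    }, 0)
    gv <- conductance_curve(steps, i0, -101)
    fit <- fit_boltzmann_curve(gv$v, gv$g, direction = "rising")
    expect_lt(abs(fit$v_half - -12.3) / 12.3, 0.05)
    expect_lt(abs(fit$z - 3.8) / 3.8, 0.05)
    expect_lt(abs(fit$amplitude - 8.08) / 8.08, 0.05)
  }
})

test_that("population sampling is reproducible and respects its spec", {
  base <- reference_cr_cell()
  none <- sample_population(base, population_spec(4, cv = 0, v_half_sd = 0,
                                                  slope_cv = 0, seed = 3))
  for (m in none) expect_equal(m, base)
  p1 <- sample_population(base, population_spec(20, seed = 5))
  p2 <- sample_population(base, population_spec(20, seed = 5))
  expect_equal(p1, p2)
  big <- sample_population(base, population_spec(280, seed = 9))
  cm <- vapply(big, `[[`, 0, "c_m")
  expect_true(all(cm > 0))
  # sample mean within 2 standard errors of the base capacitance
  expect_lt(abs(mean(cm) - 4.07), 2 * 0.1 * 4.07 / sqrt(280))
  # truncation at 3 sd
  expect_lt(max(abs(cm - 4.07)) / (0.1 * 4.07), 3 + 1e-9)
  gl <- vapply(big, `[[`, 0, "g_leak")
  expect_true(all(gl > 0))
})

test_that("per-cell availability fits pool to the printed midpoint", {
  cells <- sample_population(reference_cr_cell(),
                             population_spec(12, seed = 1))
  mids <- vapply(cells, function(m)
    analyze_a_inactivation(m, pre_levels = seq(-100, -10, 15),
                           pre_duration = 400, dt = 0.05)$fit$v_half, 0)
  # each cell's fit sits near its own generating half-point (no bias from
  # the measurement procedure) ...
  truth <- vapply(cells, function(m)
    m$channels$A$gates[[2]]$steady_state$v_half, 0)
  expect_lt(max(abs(mids - truth)), 0.6)
  expect_lt(abs(mean(mids) - mean(truth)), 0.2)
  # ... and the pooled mean matches the generating midpoint within the
  # 3-sigma sampling bound for 12 cells at the 2 mV between-cell jitter
  expect_lt(abs(mean(mids) - -52.7), 3 * 2 / sqrt(12))
})
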