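#' @name pipelines
#' @title Round-trip characterization pipelines
#'
#' @description Each pipeline simulates the original recording protocol on a
#' channel-isolated model and pushes the synthetic recordings through the
#' corresponding analysis procedure, so the fitted kinetic parameters can be
#' compared with the generating ones. Channel isolation emulates the
#' pharmacological dissection (TTX, 4-AP, Cd2+, choline substitution) by
#' zeroing the other conductances; the leak is also zeroed in the
#' voltage-clamp pipelines, which corresponds to ideal offline linear leak
#' subtraction.
NULL

#' Passive-membrane round trip
#'
#' Sub-threshold current step on the channels-off model, single-exponential
#' fit of the voltage transient.
#'
#' @param model Reference model (channels are switched off internally).
#' @param i_step Step amplitude, pA.
#' @param step_duration Step duration, ms.
#' @param dt Time step, ms.
#' @return A \code{passive_fit}.
#' @export
analyze_passive <- function(model = reference_cr_cell(), i_step = -15,
                            step_duration = 300, dt = 0.01) {
  passive <- isolate_channels(model, character(0))
  rec <- simulate(passive, protocol("cc", c(50, step_duration), c(0, i_step),
                                    label = "passive step"),
                  dt = dt, record_gates = FALSE)
  passive_from_step(rec, i_inj = i_step)
}

#' A-current inactivation round trip
#'
#' Prepulse family on the A-only model; peak test currents, normalized and
#' fitted with a falling Boltzmann.
#'
#' @param model Reference model.
#' @param pre_levels Prepulse potentials, mV.
#' @param pre_duration Prepulse duration, ms.
#' @param test_level Test potential, mV.
#' @param dt Time step, ms.
#' @return List: \code{peaks} (data.frame v_pre, peak), \code{fit}
#'   (\code{boltzmann_fit}).
#' @export
analyze_a_inactivation <- function(model = reference_cr_cell(),
                                   pre_levels = seq(-100, -10, by = 10),
                                   pre_duration = 500, test_level = 20,
                                   dt = 0.01) {
  m <- isolate_channels(model, "A")
  m$g_leak <- 0
  recs <- run_inactivation_protocol(m, pre_levels, pre_duration, test_level,
                                    test_duration = 100, dt = dt)
  peaks <- vapply(recs, function(r) peak_and_ttp(r)$peak, 0)
  list(peaks = data.frame(v_pre = pre_levels, peak = peaks),
       fit = inactivation_curve(pre_levels, peaks))
}

#' A-current activation round trip (zero-time conductance analysis)
#'
#' Voltage-clamp family on the A-only model after full removal of
#' inactivation; for each step the decay is fitted over [2 ttp, step end] and
#' extrapolated to zero time, the open-channel current is divided by the
#' driving force (E_K), the curve is corrected for the residual steady-state
#' inactivation at the conditioning potential (taken from the availability
#' curve fitted in the same session), and the conductance-voltage relation is
#' fitted with the two-state Boltzmann.
#'
#' @param model Reference model.
#' @param pre_level,pre_duration Conditioning potential (mV) and duration (ms).
#' @param step_levels Test potentials, mV.
#' @param step_duration Step duration, ms.
#' @param e_k Reversal potential used for the driving force, mV.
#' @param availability_correction Divide by the fitted availability at the
#'   conditioning potential (default TRUE).
#' @param dt Time step, ms.
#' @return List: \code{iv} (v, zero-time current), \code{gv} (v, g),
#'   \code{fit} (\code{boltzmann_fit} of g(V)), \code{ss} (activation curve,
#'   cube root), \code{inactivation} (the availability analysis),
#'   \code{availability} (scalar used for the correction).
#' @export
analyze_a_current <- function(model = reference_cr_cell(),
                              pre_level = -100, pre_duration = 250,
                              step_levels = seq(-40, 40, by = 10),
                              step_duration = 200, e_k = -101,
                              availability_correction = TRUE, dt = 0.01) {
  m <- isolate_channels(model, "A")
  m$g_leak <- 0
  recs <- run_vc_family(m, pre_level, pre_duration, step_levels,
                        step_duration, dt = dt)
  i0 <- vapply(recs, function(r) {
    pk <- peak_and_ttp(r)
    zero_time_current(r, pk$ttp)$i0
  }, 0)
  gv <- conductance_curve(step_levels, i0, e_rev = e_k)

  avail <- 1
  inact <- NULL
  if (availability_correction) {
    inact <- analyze_a_inactivation(model, dt = dt)
    f <- inact$fit
    avail <- 1 / (1 + exp((pre_level - f$v_half) / f$k))
  }
  gv$g <- gv$g / avail
  fit <- fit_boltzmann_curve(gv$v, gv$g, direction = "rising")
  ss <- steady_state_from_conductance(gv, g_max = fit$amplitude, root = 3)
  list(iv = data.frame(v = step_levels, i0 = i0), gv = gv, fit = fit,
       ss = ss, inactivation = inact, availability = avail)
}

#' A-current recovery-from-inactivation round trip
#'
#' Double-pulse protocol on the A-only model; peak test current versus gap,
#' fitted with an exponential approach to saturation.
#'
#' @param model Reference model.
#' @param recovery_level Recovery potential, mV.
#' @param gaps Gap durations, ms.
#' @param inactivating_level,inactivating_duration First pulse.
#' @param test_level Test potential, mV.
#' @param dt Time step, ms.
#' @return List: \code{peaks} (gap, peak), \code{fit} (recovery
#'   \code{exponential_fit}; \code{$tau} is the removal-of-inactivation time
#'   constant).
#' @export
analyze_a_recovery <- function(model = reference_cr_cell(),
                               recovery_level = -70,
                               gaps = c(5, 10, 15, 25, 40, 60, 90, 130, 180, 250),
                               inactivating_level = 20,
                               inactivating_duration = 150,
                               test_level = 20, dt = 0.01) {
  m <- isolate_channels(model, "A")
  m$g_leak <- 0
  recs <- run_recovery_protocol(m, inactivating_level, inactivating_duration,
                                recovery_level, gaps, test_level,
                                test_duration = 50, dt = dt)
  peaks <- vapply(recs, function(r)
    peak_and_ttp(r, step_segment = nrow(r$segments))$peak, 0)
  list(peaks = data.frame(gap = gaps, peak = peaks),
       fit = recovery_tau(gaps, peaks))
}

#' Na-current round trips (activation, inactivation, reversal)
#'
#' Same zero-time conductance analysis as the A-current, on the Na-only
#' model. The conductance conversion uses the conventional E_Na of +63 mV;
#' the pipeline builds its Na model with the same reversal so the
#' driving-force transform is exact (see the methods vignette). Also returns
#' the availability curve (prepulse family) and the reversal potential
#' extrapolated from the last four points of the peak current-voltage
#' relation.
#'
#' @param model Reference model.
#' @param e_na_analysis Reversal used for the driving force and for the
#'   pipeline's Na model, mV.
#' @param pre_level,pre_duration Conditioning segment.
#' @param step_levels Test potentials, mV.
#' @param step_duration Step duration, ms.
#' @param inact_pre_levels,inact_pre_duration,inact_test_level Availability
#'   protocol.
#' @param availability_correction Divide by fitted availability at the
#'   conditioning potential (default TRUE).
#' @param dt Time step, ms.
#' @return List: \code{gv}, \code{fit}, \code{ss} (cube-root activation
#'   curve), \code{inactivation}, \code{peak_iv}, \code{e_rev_extrapolated}.
#' @export
analyze_na_current <- function(model = reference_cr_cell(),
                               e_na_analysis = 63,
                               pre_level = -100, pre_duration = 250,
                               step_levels = seq(-80, 40, by = 10),
                               step_duration = 50,
                               inact_pre_levels = seq(-110, -30, by = 10),
                               inact_pre_duration = 500,
                               inact_test_level = 0,
                               availability_correction = TRUE, dt = 0.01) {
  m <- isolate_channels(model, "Na")
  m$g_leak <- 0
  m <- modify_channel(m, "Na", e_rev = e_na_analysis)

  recs <- run_vc_family(m, pre_level, pre_duration, step_levels,
                        step_duration, dt = dt)
  res <- lapply(recs, function(r) {
    pk <- peak_and_ttp(r)
    list(peak = pk$peak, i0 = zero_time_current(r, pk$ttp)$i0)
  })
  i0 <- vapply(res, `[[`, 0, "i0")
  peaks <- vapply(res, `[[`, 0, "peak")
  gv <- conductance_curve(step_levels, i0, e_rev = e_na_analysis)

  # availability (steady-state inactivation) family; measured by zero-time
  # extrapolation rather than raw peaks -- activation at the test potential is
  # so fast (tau_m ~ 0.1 ms) that the inactivation decaying before the peak
  # would otherwise couple into the peak amplitudes and compress the slope
  inact_recs <- run_inactivation_protocol(m, inact_pre_levels,
                                          inact_pre_duration,
                                          inact_test_level, dt = dt)
  raw_pk <- lapply(inact_recs, peak_and_ttp)
  # ttp is a property of the (common) test potential: take it from the sweep
  # with the largest response, where it is well defined
  ttp_ref <- raw_pk[[which.max(abs(vapply(raw_pk, `[[`, 0, "peak")))]]$ttp
  inact_peaks <- vapply(inact_recs, function(r)
    zero_time_current(r, ttp_ref)$i0, 0)
  inact_fit <- inactivation_curve(inact_pre_levels, inact_peaks)

  avail <- 1
  if (availability_correction)
    avail <- 1 / (1 + exp((pre_level - inact_fit$v_half) / inact_fit$k))
  gv$g <- gv$g / avail
  fit <- fit_boltzmann_curve(gv$v, gv$g, direction = "rising")
  ss <- steady_state_from_conductance(gv, g_max = fit$amplitude, root = 3)

  e_rev <- reversal_from_linreg(step_levels, peaks, last_n = 4)
  list(gv = gv, fit = fit, ss = ss,
       inactivation = list(
         peaks = data.frame(v_pre = inact_pre_levels, peak = inact_peaks),
         fit = inact_fit),
       peak_iv = data.frame(v = step_levels, peak = peaks),
       e_rev_extrapolated = e_rev, availability = avail)
}

#' h-current round trip (step/tail analysis)
#'
#' Long hyperpolarizing steps from a depolarized holding level on the h-only
#' model; I_ss - I_inst amplitudes and the tail-current activation curve with
#' its Boltzmann fit.
#'
#' @param model Reference model.
#' @param hold Holding potential, mV.
#' @param step_levels Step potentials, mV.
#' @param step_duration Step duration, ms (5 s default: >= 3 tau everywhere on
#'   the explored range).
#' @param tail_level,tail_duration Common tail segment.
#' @param dt Time step, ms (0.05 default for these multi-second sweeps).
#' @return The \code{\link{h_current_analysis}} result.
#' @export
analyze_h_current <- function(model = reference_cr_cell(), hold = -40,
                              step_levels = seq(-130, -60, by = 10),
                              step_duration = 5000, tail_level = -130,
                              tail_duration = 500, dt = 0.05) {
  m <- isolate_channels(model, "h")
  recs <- run_vc_family(m, hold, 500, step_levels, step_duration,
                        tail_level = tail_level, tail_duration = tail_duration,
                        dt = dt)
  h_current_analysis(recs, model = m)
}

#' L-type calcium current round trip (persistent amplitudes)
#'
#' Depolarizing step family on the Ca-only model; late-window mean current
#' per step.
#'
#' @param model Reference model; defaults to the printed 0.6 nS isolated
#'   L-type conductance (the blocked-Na/K recording condition).
#' @param step_levels Step potentials, mV.
#' @param step_duration Step duration, ms.
#' @param hold Holding potential, mV.
#' @param dt Time step, ms.
#' @return data.frame \code{v}, \code{i} (pA, baseline-subtracted late mean).
#' @export
analyze_ca_current <- function(model = reference_cr_cell(g_ca = 0.6),
                               step_levels = seq(-80, 40, by = 10),
                               step_duration = 300, hold = -70, dt = 0.01) {
  m <- isolate_channels(model, "CaL")
  m$g_leak <- 0
  recs <- run_vc_family(m, hold, 100, step_levels, step_duration, dt = dt)
  data.frame(v = step_levels,
             i = vapply(recs, persistent_amplitude, 0))
}

#' Excitability battery (paired pulses, single-spike behavior, ohmic late phase)
#'
#' Runs the current-clamp characterization on the full model: rheobase for a
#' sustained step and for a 10-ms pulse, spike count at 1.5x rheobase, spike
#' width with and without the A-conductance, late-phase I-V linearity,
#' paired-pulse responses across intervals, and the variant with the Na
#' removal-of-inactivation time constant shortened ten-fold.
#'
#' @param model Reference model.
#' @param intervals Paired-pulse onset-to-onset intervals, ms.
#' @param hold_v Holding potential, mV.
#' @param dt Time step, ms.
#' @return List of measurements (see the methods vignette for the full map).
#' @export
excitability_battery <- function(model = reference_cr_cell(),
                                 intervals = c(15, 30, 50, 90, 310),
                                 hold_v = -70, dt = 0.01) {
  i_hold <- holding_current(model, hold_v)

  # sustained step: exactly one spike at 1.5x rheobase
  rheo_step <- find_rheobase(model, pulse_width = 200, hold_v = hold_v, dt = dt)
  rec_step <- simulate(model, protocol(
    "cc", c(50, 200, 100), c(i_hold, i_hold + 1.5 * rheo_step, i_hold),
    label = "sustained step"), dt = dt)
  spikes_step <- detect_spikes(rec_step)

  # spike width with the A-conductance suppressed
  m_noA <- modify_channel(model, "A", g_max = 0)
  rec_noA <- simulate(m_noA, protocol(
    "cc", c(50, 200, 100),
    c(holding_current(m_noA, hold_v),
      holding_current(m_noA, hold_v) + 1.5 * rheo_step,
      holding_current(m_noA, hold_v)), label = "A suppressed"), dt = dt)
  spikes_noA <- detect_spikes(rec_noA)

  # late-phase I-V (ohmic behavior after the transients inactivate)
  iv_recs <- lapply(seq(-15, 45, by = 10), function(amp)
    simulate(model, protocol("cc", c(50, 300, 50),
                             c(i_hold, i_hold + amp, i_hold)),
             dt = dt, record_gates = FALSE))
  late_iv <- late_phase_iv(iv_recs, window = 50)

  # paired pulses just above threshold. Near its absolute rheobase this GOhm
  # cell fires with tens of ms latency, whereas the recorded and simulated
  # traces show the spike elicited during the 10-ms pulse itself; the
  # stimulus is therefore 1.1x the minimal amplitude whose spike peaks
  # within the pulse
  rheo_pulse <- .prompt_rheobase(model, pulse_width = 10, hold_v = hold_v,
                                 dt = dt)
  amp <- 1.1 * rheo_pulse
  i_hold_m <- holding_current(model, hold_v)
  pp <- run_paired_pulse_cc(model, amp, 10, intervals, hold_v = hold_v, dt = dt)
  # single-pulse reference trace, long enough to cover every interval's
  # second-pulse window: the second response is the excess over this trace
  ref <- simulate(model, protocol(
    "cc", c(50, 10, max(intervals) + 130),
    c(i_hold_m, i_hold_m + amp, i_hold_m)), dt = dt, record_gates = FALSE)
  pp_summary <- do.call(rbind, lapply(seq_along(intervals), function(j)
    .second_pulse_measure(pp[[j]], intervals[j], ref)))

  # tau_rh / 10 variant at the shortest failing interval
  # only the removal-of-inactivation branch (V <= -70 mV) of the Na h gate
  # is shortened ten-fold; the development branch stays untouched
  m_fast <- modify_channel(model, "Na", tau_scale = 0.1, gate = "h",
                           tau_branches = 1)
  pp_fast <- run_paired_pulse_cc(m_fast, amp, 10, 50, hold_v = hold_v, dt = dt)
  ref_fast <- simulate(m_fast, protocol(
    "cc", c(50, 10, 180),
    c(holding_current(m_fast, hold_v),
      holding_current(m_fast, hold_v) + amp,
      holding_current(m_fast, hold_v))), dt = dt, record_gates = FALSE)
  fast50 <- .second_pulse_measure(pp_fast[[1]], 50, ref_fast)

  list(rheobase_step = rheo_step, rheobase_pulse = rheo_pulse,
       pulse_amp = amp,
       n_spikes_sustained = nrow(spikes_step),
       spike_width = if (nrow(spikes_step)) spikes_step$half_width[1] else NA,
       spike_width_noA = if (nrow(spikes_noA)) spikes_noA$half_width[1] else NA,
       late_iv = late_iv,
       paired = pp_summary, paired_fast_rh = fast50,
       recordings = list(step = rec_step, noA = rec_noA, paired = pp))
}

# minimal pulse amplitude whose spike peaks within the pulse (bisection)
.prompt_rheobase <- function(model, pulse_width = 10, hold_v = -70,
                             bounds = c(1, 80), tol = 0.25, dt = 0.01) {
  i_hold <- holding_current(model, hold_v)
  prompt <- function(amp) {
    rec <- simulate(model, protocol(
      "cc", c(50, pulse_width, 40),
      c(i_hold, i_hold + amp, i_hold)), dt = dt, record_gates = FALSE)
    sp <- detect_spikes(rec)
    nrow(sp) > 0 && sp$peak_time[1] <= 50 + pulse_width
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (prompt(lo)) return(lo)
  if (!prompt(hi)) stop("no prompt spike even at the upper search bound")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (prompt(mid)) hi <- mid else lo <- mid
  }
  hi
}

# second-pulse response of a paired-pulse recording (segments: pre, pulse,
# gap, pulse, post). amplitude2 is the peak depolarization relative to the
# membrane potential at the second pulse's onset (the graded response to
# pulse 2): at short intervals the first spike's repolarization tail
# dominates any baseline-referenced peak. excess2 is the peak excess over
# the single-pulse reference trace, a second view of the same response.
.second_pulse_measure <- function(rec, interval, ref) {
  b <- .seg_bounds(rec)
  onset2 <- b[4]
  sel <- which(rec$data$time >= onset2 & rec$data$time <= onset2 + 25)
  baseline <- mean(rec$data$v[rec$data$time <= b[2]])
  pk <- max(rec$data$v[sel])
  v_on2 <- rec$data$v[sel[1]]
  excess <- max(rec$data$v[sel] - ref$data$v[sel])
  sp <- detect_spikes(rec)
  sp1 <- sp[sp$onset >= b[2] & sp$onset < onset2, , drop = FALSE]
  sp2 <- sp[sp$onset >= onset2, , drop = FALSE]
  data.frame(interval = interval, peak_v2 = pk, amplitude2 = pk - v_on2,
             excess2 = excess, spike2 = nrow(sp2) > 0,
             amp_ratio = if (nrow(sp1)) (pk - baseline) / sp1$amplitude[1]
                         else NA_real_)
}
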