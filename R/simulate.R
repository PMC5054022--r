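#' Integrate the membrane equation under a stimulus protocol
#'
#' Current clamp integrates \code{c_m dV/dt = I_inj - I_leak - sum(I_chan)}
#' with forward Euler for V; gating variables are advanced with the
#' exponential-Euler closed form \code{x <- x_inf - (x_inf - x) exp(-dt/tau)}
#' evaluated at the instantaneous potential, which is exact for
#' piecewise-constant V. Voltage clamp is ideal (no series resistance, no
#' capacitive transient): V equals the command at every sample and the
#' reported current is the algebraic total membrane current (outward
#' positive). The initial state is the steady state at the first segment's
#' level, so there are no settling artifacts.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param proto A single-sweep \code{\link{protocol}}.
#' @param dt Time step, ms (default 0.01).
#' @param record_gates Record gate trajectories (default TRUE).
#' @return An object of class \code{recording}: a list with \code{data} (a
#'   data.frame with columns \code{time}, \code{v}, \code{i} -- total membrane
#'   current in vc, injected current in cc -- \code{i_leak}, one
#'   \code{i_<channel>} column per channel, and \code{gate_<name>} columns),
#'   plus \code{dt}, \code{mode}, \code{segments}, and metadata.
#' @export
simulate <- function(model, proto, dt = 0.01, record_gates = TRUE) {
  stopifnot(inherits(model, "membrane_model"), inherits(proto, "protocol"))
  if (!is.null(proto$sweep_segment))
    stop("protocol has an unexpanded sweep axis; use protocol_sweeps()")
  if (!(dt > 0)) stop("dt must be positive")
  if (length(proto$durations) == 0) stop("empty protocol")

  mode <- if (proto$mode == "vc") 1L else 0L
  v0 <- if (mode == 1L) proto$levels[1]
        else resting_potential(model, proto$levels[1])
  raw <- simulate_cpp(.model_flat(model), mode, proto$durations, proto$levels,
                      dt, v0, record_gates)
  df <- data.frame(time = raw$time, v = raw$v, i = raw$i, i_leak = raw$i_leak)
  ic <- raw$i_chan
  colnames(ic) <- paste0("i_", names(model$channels))
  df <- cbind(df, as.data.frame(ic))
  if (record_gates) {
    gm <- raw$gates
    colnames(gm) <- make.unique(paste0("gate_", raw$gate_names))
    df <- cbind(df, as.data.frame(gm))
  }
  structure(list(
    data = df, dt = dt, mode = proto$mode,
    segments = data.frame(duration = proto$durations, level = proto$levels),
    label = proto$label, seed = NA_integer_, noise_sd = 0,
    model_fingerprint = .model_fingerprint(model)),
    class = "recording")
}

.model_fingerprint <- function(model) {
  paste0("cm=", format(model$c_m, digits = 8),
         ";gl=", format(model$g_leak, digits = 8),
         ";el=", format(model$e_leak, digits = 8), ";",
         paste(vapply(model$channels, function(ch)
           sprintf("%s:g=%s,E=%s", ch$name, format(ch$g_max, digits = 8),
                   format(ch$e_rev, digits = 8)), ""), collapse = ";"))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording (%s): %d samples, dt = %g ms, %d segments%s\n",
              x$mode, nrow(x$data), x$dt, nrow(x$segments),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Voltage-clamp step family
#'
#' Preconditioning segment followed by a family of test steps (and an optional
#' tail segment), one recording per step level.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param pre_level,pre_duration Conditioning potential (mV) and duration (ms).
#' @param step_levels Test potentials, mV.
#' @param step_duration Test step duration, ms.
#' @param tail_level Optional tail potential, mV.
#' @param tail_duration Tail duration, ms (used when \code{tail_level} given).
#' @param dt Time step, ms.
#' @return List of \code{recording} objects, one per step level.
#' @export
run_vc_family <- function(model, pre_level, pre_duration, step_levels,
                          step_duration, tail_level = NULL,
                          tail_duration = 100, dt = 0.01) {
  if (length(step_levels) == 0) stop("empty step list")
  lapply(step_levels, function(sv) {
    dur <- c(pre_duration, step_duration)
    lev <- c(pre_level, sv)
    if (!is.null(tail_level)) {
      dur <- c(dur, tail_duration)
      lev <- c(lev, tail_level)
    }
    simulate(model, protocol("vc", dur, lev,
                             label = sprintf("step %g mV", sv)), dt = dt)
  })
}

#' Steady-state inactivation protocol
#'
#' Family of long conditioning prepulses followed by a fixed test pulse; the
#' peak test current as a function of prepulse potential traces the
#' steady-state availability curve.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param pre_levels Prepulse potentials, mV.
#' @param pre_duration Prepulse duration, ms. Warns when shorter than 5x the
#'   slowest gate relaxation over the prepulse range.
#' @param test_level Test potential, mV.
#' @param test_duration Test pulse duration, ms.
#' @param dt Time step, ms.
#' @return List of \code{recording} objects, one per prepulse level.
#' @export
run_inactivation_protocol <- function(model, pre_levels, pre_duration,
                                      test_level, test_duration = 100,
                                      dt = 0.01) {
  tau_max <- 0
  for (ch in model$channels) {
    if (ch$g_max <= 0) next
    for (g in ch$gates)
      tau_max <- max(tau_max, gate_tau(g, pre_levels))
  }
  if (pre_duration < 5 * tau_max)
    warning(sprintf(
      "prepulse duration %g ms < 5 x slowest gate tau (%.1f ms): availability not at steady state",
      pre_duration, tau_max))
  lapply(pre_levels, function(pv)
    simulate(model, protocol("vc", c(pre_duration, test_duration),
                             c(pv, test_level),
                             label = sprintf("prepulse %g mV", pv)), dt = dt))
}

#' Double-pulse recovery-from-inactivation protocol
#'
#' An inactivating pulse, a variable recovery gap at a hyperpolarized
#' potential, then a test pulse; the growth of the peak test current with gap
#' duration measures the removal of inactivation at the recovery potential.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param inactivating_level,inactivating_duration First pulse (mV, ms).
#' @param recovery_level Potential during the gap, mV (also the initial
#'   holding level).
#' @param gaps Gap durations, ms, sorted ascending (0 allowed).
#' @param test_level Test pulse potential, mV.
#' @param test_duration Test pulse duration, ms.
#' @param hold_duration Initial settling segment at the recovery level, ms.
#' @param dt Time step, ms.
#' @return List of \code{recording} objects, one per gap.
#' @export
run_recovery_protocol <- function(model, inactivating_level,
                                  inactivating_duration, recovery_level,
                                  gaps, test_level, test_duration = 50,
                                  hold_duration = 50, dt = 0.01) {
  stopifnot(!is.unsorted(gaps), all(gaps >= 0))
  lapply(gaps, function(gp) {
    dur <- c(hold_duration, inactivating_duration, gp, test_duration)
    lev <- c(recovery_level, inactivating_level, recovery_level, test_level)
    keep <- dur > 0
    simulate(model, protocol("vc", dur[keep], lev[keep],
                             label = sprintf("gap %g ms", gp)), dt = dt)
  })
}

#' Paired-pulse current-clamp protocol
#'
#' Two identical depolarizing pulses separated by a variable interval
#' (onset-to-onset), riding on the holding current that pins the cell at
#' \code{hold_v}; one recording per interval.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param pulse_amp Pulse amplitude above holding, pA.
#' @param pulse_width Pulse width, ms.
#' @param intervals Onset-to-onset intervals, ms (each > pulse_width).
#' @param hold_v Holding potential, mV.
#' @param pre_duration,post_duration Padding before the first and after the
#'   second pulse, ms.
#' @param dt Time step, ms.
#' @return List of \code{recording} objects, one per interval.
#' @export
run_paired_pulse_cc <- function(model, pulse_amp, pulse_width, intervals,
                                hold_v = -70, pre_duration = 50,
                                post_duration = 100, dt = 0.01) {
  stopifnot(all(intervals > pulse_width))
  i_hold <- holding_current(model, hold_v)
  lapply(intervals, function(isi) {
    dur <- c(pre_duration, pulse_width, isi - pulse_width, pulse_width,
             post_duration)
    lev <- c(i_hold, i_hold + pulse_amp, i_hold, i_hold + pulse_amp, i_hold)
    simulate(model, protocol("cc", dur, lev,
                             label = sprintf("interval %g ms", isi)), dt = dt)
  })
}

#' Detect action potentials in a current-clamp recording
#'
#' Upward threshold crossings, merged when closer than
#' \code{min_separation}; spike amplitude is measured from the pre-stimulus
#' baseline (mean V over the first protocol segment).
#'
#' @param rec A current-clamp \code{recording}.
#' @param threshold Crossing threshold, mV (default 0: these cells fire
#'   overshooting spikes).
#' @param min_separation Minimum separation between events, ms.
#' @return data.frame with one row per spike: \code{onset}, \code{peak_time},
#'   \code{peak_v}, \code{amplitude}, \code{half_width}.
#' @export
detect_spikes <- function(rec, threshold = 0, min_separation = 2) {
  stopifnot(inherits(rec, "recording"))
  if (rec$mode != "cc") stop("spike detection requires a current-clamp recording")
  v <- rec$data$v; tm <- rec$data$time
  base_end <- .seg_bounds(rec)[2]
  baseline <- mean(v[tm <= base_end])
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (length(up) == 0)
    return(data.frame(onset = numeric(0), peak_time = numeric(0),
                      peak_v = numeric(0), amplitude = numeric(0),
                      half_width = numeric(0)))
  # merge crossings closer than min_separation
  keep <- c(TRUE, diff(tm[up]) >= min_separation)
  up <- up[keep]
  res <- lapply(seq_along(up), function(j) {
    i0 <- up[j]
    i1 <- if (j < length(up)) up[j + 1] - 1 else length(v)
    # event window: until v falls back below threshold (or next event)
    below <- which(v[i0:i1] < threshold)
    i_end <- if (length(below) > 1) i0 + below[min(which(below > 1))] - 1 else i1
    seg <- i0:i_end
    ipk <- seg[which.max(v[seg])]
    amp <- v[ipk] - baseline
    half <- baseline + amp / 2
    # half-width: interpolated crossings of the half-amplitude level
    li <- ipk; while (li > 1 && v[li - 1] > half) li <- li - 1
    ri <- ipk; while (ri < length(v) && v[ri + 1] > half) ri <- ri + 1
    t_l <- if (li > 1)
      stats::approx(v[(li - 1):li], tm[(li - 1):li], xout = half)$y else tm[li]
    t_r <- if (ri < length(v))
      stats::approx(v[ri:(ri + 1)], tm[ri:(ri + 1)], xout = half)$y else tm[ri]
    data.frame(onset = tm[i0], peak_time = tm[ipk], peak_v = v[ipk],
               amplitude = amp, half_width = t_r - t_l)
  })
  do.call(rbind, res)
}

#' Late-phase current-voltage relation of a current-clamp family
#'
#' Mean membrane potential over the final \code{window} ms of the step
#' segment, against the injected current, with a least-squares line -- the
#' "ohmic late phase" measurement (after the transient conductances have
#' inactivated the membrane is purely resistive).
#'
#' @param recordings List of current-clamp step recordings (step = segment
#'   \code{step_segment}).
#' @param window Averaging window at the end of the step, ms.
#' @param step_segment Index of the step segment (default 2).
#' @return List with \code{iv} (data.frame i, v), \code{slope_mohm} (fitted
#'   resistance, MOhm), \code{intercept_mv}, and \code{r_squared}.
#' @export
late_phase_iv <- function(recordings, window = 50, step_segment = 2) {
  pts <- lapply(recordings, function(rec) {
    stopifnot(rec$mode == "cc")
    b <- .seg_bounds(rec)
    if (window > rec$segments$duration[step_segment])
      stop("window exceeds the step duration")
    t0 <- b[step_segment + 1] - window; t1 <- b[step_segment + 1]
    sel <- rec$data$time >= t0 & rec$data$time <= t1
    data.frame(i = rec$segments$level[step_segment],
               v = mean(rec$data$v[sel]))
  })
  iv <- do.call(rbind, pts)
  fit <- stats::lm(v ~ i, data = iv)
  list(iv = iv,
       slope_mohm = unname(stats::coef(fit)[2]) * 1e3,  # mV/pA = GOhm
       intercept_mv = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Rheobase of a pulse stimulus
#'
#' Minimal pulse amplitude (above holding) that evokes a spike, found by
#' bisection.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param pulse_width Pulse width, ms.
#' @param hold_v Holding potential, mV.
#' @param bounds Search interval for the amplitude, pA.
#' @param tol Bisection tolerance, pA.
#' @param dt Time step, ms.
#' @return Rheobase amplitude, pA.
#' @export
find_rheobase <- function(model, pulse_width = 10, hold_v = -70,
                          bounds = c(0.5, 60), tol = 0.25, dt = 0.01) {
  i_hold <- holding_current(model, hold_v)
  spikes <- function(amp) {
    rec <- simulate(model, protocol(
      "cc", c(20, pulse_width, 30),
      c(i_hold, i_hold + amp, i_hold)), dt = dt, record_gates = FALSE)
    nrow(detect_spikes(rec)) > 0
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (spikes(lo)) return(lo)
  if (!spikes(hi)) stop("no spike even at the upper search bound")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes(mid)) hi <- mid else lo <- mid
  }
  hi
}
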