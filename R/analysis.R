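#' Passive membrane properties from a sub-threshold current step
#'
#' Single-exponential fit of the voltage transient: the fitted time constant
#' is tau_m, the steady-state deflection over the injected current gives R_in,
#' and C_m = tau_m / R_in. Errors if the trace contains a spike.
#'
#' @param rec A current-clamp step \code{recording}.
#' @param i_inj Injected step amplitude, pA; defaults to the step-segment
#'   level minus the first-segment level.
#' @param step_segment Index of the step segment (default 2).
#' @return List of class \code{passive_fit}: \code{tau_m} (ms), \code{r_in}
#'   (MOhm), \code{c_m} (pF), plus the underlying \code{exponential_fit}.
#' @export
passive_from_step <- function(rec, i_inj = NULL, step_segment = 2) {
  stopifnot(inherits(rec, "recording"), rec$mode == "cc")
  if (nrow(detect_spikes(rec)) > 0)
    stop("spike detected: passive fit requires a sub-threshold step")
  b <- .seg_bounds(rec)
  onset <- b[step_segment]; step_end <- b[step_segment + 1]
  if (is.null(i_inj))
    i_inj <- rec$segments$level[step_segment] - rec$segments$level[1]
  sel <- rec$data$time >= onset & rec$data$time <= step_end
  t <- rec$data$time[sel] - onset
  v <- rec$data$v[sel]
  v_base <- mean(rec$data$v[rec$data$time < onset])
  f <- fit_exponential(t, v, with_offset = TRUE)
  dv_ss <- f$offset - v_base
  r_in <- dv_ss / i_inj * 1e3          # mV/pA = GOhm -> MOhm
  structure(list(tau_m = f$tau, r_in = r_in, c_m = f$tau / r_in * 1e3,
                 v_rest = v_base, fit = f),
            class = "passive_fit")
}

#' @export
print.passive_fit <- function(x, ...) {
  cat(sprintf("Passive fit: tau_m = %.4g ms, R_in = %.5g MOhm, C_m = %.4g pF\n",
              x$tau_m, x$r_in, x$c_m))
  invisible(x)
}

#' Peak current and time-to-peak within a step
#'
#' Signed extremum of the current relative to the pre-step baseline, and its
#' latency from the step onset.
#'
#' @param rec A voltage-clamp \code{recording}.
#' @param step_segment Index of the step segment (default 2).
#' @param window Optional \code{c(from, to)} in ms from step onset restricting
#'   the search (default: the whole step).
#' @return List: \code{peak} (pA, baseline-subtracted, signed), \code{ttp}
#'   (ms), \code{baseline} (pA), flags \code{degenerate} and \code{at_end}
#'   (TRUE when the extremum sits on the window edge, e.g. a monotone trace).
#' @export
peak_and_ttp <- function(rec, step_segment = 2, window = NULL) {
  stopifnot(inherits(rec, "recording"))
  b <- .seg_bounds(rec)
  onset <- b[step_segment]; step_end <- b[step_segment + 1]
  if (is.null(window)) window <- c(0, step_end - onset)
  if (window[2] > step_end - onset + 1e-9) stop("window exceeds the step")
  base_sel <- rec$data$time >= max(0, onset - 5) & rec$data$time < onset
  baseline <- mean(rec$data$i[base_sel])
  sel <- which(rec$data$time >= onset + window[1] &
               rec$data$time <= onset + window[2])
  dev <- rec$data$i[sel] - baseline
  k <- which.max(abs(dev))
  list(peak = dev[k], ttp = rec$data$time[sel[k]] - onset, baseline = baseline,
       degenerate = max(abs(dev)) < 1e-9,
       at_end = k == length(sel) || k == 1L)
}

#' Open-channel current by zero-time extrapolation
#'
#' Fits \code{A exp(-t/tau) + C} to the current decay over the window from
#' twice the time-to-peak to the end of the step (t measured from step onset)
#' and extrapolates to t = 0: the returned \code{A + C} is the open-channel
#' current corrected for the inactivation that developed during the pulse.
#'
#' @param rec A voltage-clamp \code{recording}.
#' @param ttp Time-to-peak, ms (from \code{\link{peak_and_ttp}}).
#' @param step_segment Index of the step segment (default 2).
#' @return List: \code{i0} (pA at zero time), \code{fit} (the
#'   \code{exponential_fit}).
#' @export
zero_time_current <- function(rec, ttp, step_segment = 2) {
  b <- .seg_bounds(rec)
  onset <- b[step_segment]; step_end <- b[step_segment + 1]
  sel <- which(rec$data$time >= onset + 2 * ttp & rec$data$time <= step_end)
  if (length(sel) < 8) stop("decay window [2*ttp, step end] has fewer than 8 samples")
  t <- rec$data$time[sel] - onset
  f <- fit_exponential(t, rec$data$i[sel], with_offset = TRUE)
  if (!f$converged && !f$degenerate) stop("zero-time decay fit did not converge")
  list(i0 = f$amplitude + f$offset, fit = f)
}

#' Conductance-voltage curve from a current-voltage relation
#'
#' Pointwise \code{g = I / (V - e_rev)}. A point at the reversal potential is
#' excluded with a warning.
#'
#' @param v Voltages, mV.
#' @param i Currents, pA.
#' @param e_rev Reversal potential used for the driving force, mV.
#' @return data.frame with columns \code{v}, \code{g} (nS).
#' @export
conductance_curve <- function(v, i, e_rev) {
  stopifnot(length(v) == length(i))
  at_rev <- abs(v - e_rev) < 1e-9
  if (any(at_rev)) {
    warning("point(s) at the reversal potential excluded")
    v <- v[!at_rev]; i <- i[!at_rev]
  }
  data.frame(v = v, g = i / (v - e_rev))
}

#' Steady-state activation from a conductance curve
#'
#' Extracts \code{x_inf = (g / g_max)^(1/r)} (the r-th root undoes the gate
#' exponent) and fits a rising Boltzmann to the resulting curve. Conductances
#' exceeding g_max are clipped with a warning.
#'
#' @param gv data.frame with \code{v}, \code{g} (from
#'   \code{\link{conductance_curve}}).
#' @param g_max Maximal conductance, nS.
#' @param root Gate exponent r (3 for a cubic activation).
#' @param tol Relative tolerance above g_max before clipping warns.
#' @return List: \code{curve} (data.frame v, x_inf), \code{fit} (a
#'   \code{boltzmann_fit} of the curve).
#' @export
steady_state_from_conductance <- function(gv, g_max, root = 3, tol = 1e-3) {
  ratio <- gv$g / g_max
  if (any(ratio > 1 + tol))
    warning("conductance exceeds g_max; ratio clipped to 1")
  ratio <- pmin(pmax(ratio, 0), 1)
  x <- ratio^(1 / root)
  curve <- data.frame(v = gv$v, x_inf = x)
  list(curve = curve,
       fit = fit_boltzmann_curve(curve$v, curve$x_inf, direction = "rising"))
}

#' Steady-state inactivation (availability) curve
#'
#' Normalizes peak test currents to their maximum and fits a falling
#' Boltzmann with a free amplitude (so the normalization convention does not
#' bias the midpoint).
#'
#' @param v_pre Prepulse potentials, mV (>= 5 levels).
#' @param peaks Peak test currents (signed or magnitudes).
#' @return A \code{boltzmann_fit}; its \code{v_half} and \code{k} are the
#'   availability midpoint and slope.
#' @export
inactivation_curve <- function(v_pre, peaks) {
  stopifnot(length(v_pre) == length(peaks), length(v_pre) >= 5)
  m <- max(abs(peaks))
  if (m == 0) {
    f <- structure(list(v_half = NA_real_, k = NA_real_, z = NA_real_,
                        amplitude = 0, offset = 0, se = NULL, rss = 0,
                        direction = "falling", thermal_voltage = 25.69,
                        converged = FALSE), class = "boltzmann_fit")
    return(f)
  }
  fit_boltzmann_curve(v_pre, abs(peaks) / m, direction = "falling")
}

#' h-current step/tail analysis
#'
#' For each hyperpolarizing step: the instantaneous current I_inst (mean over
#' 5-15 ms after step onset), the steady-state current I_ss (mean over the
#' last 10% of the step) and their difference (the slowly developing
#' h-current). The activation curve comes from the tail currents at the
#' common post-step potential: each tail is back-extrapolated to the
#' transition time with a single-exponential fit, normalized, and fitted with
#' a falling Boltzmann carrying a free additive offset (the tail's leak
#' component is identical across sweeps and is absorbed exactly by the
#' offset).
#'
#' @param recordings List of voltage-clamp recordings with segments
#'   hold / step / tail.
#' @param step_segment,tail_segment Segment indices (defaults 2, 3).
#' @param model Optional \code{\link{membrane_model}} used to validate that
#'   step durations allow >= 95% gate relaxation (3 tau); a failed check is
#'   carried as \code{insufficient_duration = TRUE}, not an error.
#' @param tail_fit_span Length of tail used for the back-extrapolation, ms.
#' @return List: \code{amplitudes} (data.frame v, i_h = I_ss - I_inst),
#'   \code{tail} (data.frame v, tail_i0, activation), \code{fit} (a
#'   \code{boltzmann_fit}), \code{insufficient_duration}.
#' @export
h_current_analysis <- function(recordings, step_segment = 2, tail_segment = 3,
                               model = NULL, tail_fit_span = 200) {
  rows <- lapply(recordings, function(rec) {
    b <- .seg_bounds(rec)
    onset <- b[step_segment]; step_end <- b[step_segment + 1]
    tail_on <- b[tail_segment]; tail_end <- b[tail_segment + 1]
    tm <- rec$data$time; cur <- rec$data$i
    i_inst <- mean(cur[tm >= onset + 5 & tm <= onset + 15])
    last10 <- 0.1 * (step_end - onset)
    i_ss <- mean(cur[tm >= step_end - last10 & tm <= step_end])
    sel <- which(tm >= tail_on & tm <= min(tail_on + tail_fit_span, tail_end))
    f <- fit_exponential(tm[sel] - tail_on, cur[sel], with_offset = TRUE)
    tail_i0 <- if (f$degenerate) mean(cur[sel]) else f$amplitude + f$offset
    data.frame(v = rec$segments$level[step_segment],
               i_h = i_ss - i_inst, tail_i0 = tail_i0)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$v), ]

  insufficient <- FALSE
  if (!is.null(model)) {
    for (ch in model$channels) {
      if (ch$g_max <= 0) next
      for (g in ch$gates) {
        tau3 <- 3 * max(gate_tau(g, df$v))
        step_dur <- recordings[[1]]$segments$duration[step_segment]
        if (step_dur < tau3) insufficient <- TRUE
      }
    }
    if (insufficient)
      warning("step duration < 3x slowest gate tau: <95% relaxation")
  }

  if (diff(range(df$tail_i0)) < 1e-9 * max(1, max(abs(df$tail_i0)))) {
    # tails identical across sweeps (e.g. conductance absent, leaving only
    # the leak component): degenerate, no activation curve to fit
    df$activation <- 0
    return(list(amplitudes = df[, c("v", "i_h")],
                tail = df[, c("v", "tail_i0", "activation")],
                fit = structure(list(v_half = NA_real_, k = NA_real_,
                                     z = NA_real_, amplitude = 0, offset = 0,
                                     se = NULL, rss = 0,
                                     direction = "falling",
                                     thermal_voltage = 25.69,
                                     converged = FALSE),
                                class = "boltzmann_fit"),
                insufficient_duration = insufficient))
  }
  # orient so the curve falls with depolarization (inward tails at a
  # hyperpolarized tail potential come out negative), then normalize
  s <- if (df$tail_i0[1] >= df$tail_i0[nrow(df)]) 1 else -1
  y <- s * df$tail_i0 / max(abs(df$tail_i0))
  fit <- fit_boltzmann_curve(df$v, y, direction = "falling", with_offset = TRUE)
  df$activation <- if (fit$converged) (y - fit$offset) / fit$amplitude else y
  list(amplitudes = df[, c("v", "i_h")],
       tail = df[, c("v", "tail_i0", "activation")],
       fit = fit, insufficient_duration = insufficient)
}

#' Persistent current amplitude at the end of a step
#'
#' Mean current over the final \code{window} ms of the step minus the
#' pre-step baseline.
#'
#' @param rec A voltage-clamp \code{recording}.
#' @param window Averaging window, ms (default 10).
#' @param step_segment Index of the step segment (default 2).
#' @return Current, pA.
#' @export
persistent_amplitude <- function(rec, window = 10, step_segment = 2) {
  b <- .seg_bounds(rec)
  onset <- b[step_segment]; step_end <- b[step_segment + 1]
  if (step_end - onset < window) stop("step shorter than the averaging window")
  tm <- rec$data$time
  baseline <- mean(rec$data$i[tm >= max(0, onset - 5) & tm < onset])
  mean(rec$data$i[tm >= step_end - window & tm <= step_end]) - baseline
}
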