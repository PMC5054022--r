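#' Least-squares single-exponential fit
#'
#' Fits \code{y = A exp(-t/tau) + C} (C fixed at 0 when \code{with_offset} is
#' FALSE). The initial guess is deterministic: C from the tail mean, then a
#' log-linear regression of \code{|y - C|} against t seeds A and tau, refined
#' by Levenberg-Marquardt. Non-convergence and degenerate inputs are flagged
#' in the result, never silent.
#'
#' @param t Time, ms, strictly increasing (>= 8 samples).
#' @param y Trace values.
#' @param with_offset Fit the additive constant C (default TRUE).
#' @return An object of class \code{exponential_fit}: \code{amplitude},
#'   \code{tau} (ms), \code{offset}, \code{rss}, \code{window},
#'   \code{converged}, \code{degenerate}.
#' @export
fit_exponential <- function(t, y, with_offset = TRUE) {
  stopifnot(length(t) == length(y), length(t) >= 8, !is.unsorted(t, strictly = TRUE))
  out <- structure(list(amplitude = NA_real_, tau = NA_real_, offset = 0,
                        rss = NA_real_, window = range(t),
                        converged = FALSE, degenerate = FALSE),
                   class = "exponential_fit")
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-12) || stats::sd(y) == 0) {
    out$amplitude <- 0
    out$offset <- mean(y)
    out$degenerate <- TRUE
    return(out)
  }
  c0 <- if (with_offset) mean(y[t >= stats::quantile(t, 0.9)]) else 0
  s <- y - c0
  sgn <- sign(s[1])
  if (sgn == 0) sgn <- sign(mean(s[1:3]))
  use <- which(sgn * s > 0.05 * max(abs(s)))
  if (length(use) < 3) use <- which(sgn * s > 0)
  if (length(use) < 3) {
    out$degenerate <- TRUE
    return(out)
  }
  ll <- stats::lm(log(sgn * s[use]) ~ t[use])
  tau0 <- unname(-1 / stats::coef(ll)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  a0 <- unname(sgn * exp(stats::coef(ll)[1]))
  fit <- if (with_offset)
    .lm_fit(c(A = a0, tau = tau0, C = c0),
            function(p) y - (p["A"] * exp(-t / p["tau"]) + p["C"]),
            lower = c(-Inf, 1e-6, -Inf))
  else
    .lm_fit(c(A = a0, tau = tau0),
            function(p) y - p["A"] * exp(-t / p["tau"]),
            lower = c(-Inf, 1e-6))
  if (!fit$converged) return(out)
  out$amplitude <- fit$par[["A"]]
  out$tau <- fit$par[["tau"]]
  out$offset <- if (with_offset) fit$par[["C"]] else 0
  out$rss <- fit$rss
  out$converged <- TRUE
  out
}

# Levenberg-Marquardt core shared by the fit operations: works directly on
# the residual function, so perfect (zero-residual) synthetic data does not
# trip the model-object construction that plain nls-based wrappers perform
.lm_fit <- function(par0, resid_fn, lower = NULL, upper = NULL) {
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      lower = if (is.null(lower)) rep(-Inf, length(par0)) else lower,
      upper = if (is.null(upper)) rep(Inf, length(par0)) else upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(res) || !(res$info %in% 1:4))
    return(list(par = par0, rss = NA_real_, converged = FALSE, se = NULL,
                message = if (is.null(res)) "optimizer error" else res$message))
  se <- tryCatch({
    cf <- summary(res)$coefficients
    stats::setNames(cf[, "Std. Error"], rownames(cf))
  }, error = function(e) NULL)
  list(par = res$par, rss = res$deviance, converged = TRUE, se = se,
       message = res$message)
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: A = %.6g, tau = %.6g ms, C = %.6g (rss %.3g)%s\n",
              x$amplitude, x$tau, x$offset, x$rss,
              if (!x$converged) " [NOT CONVERGED]"
              else if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Least-squares Boltzmann fit
#'
#' Fits \code{y = offset + amplitude / (1 + exp(+-(v_half - V)/k))} to a
#' curve of values against voltage (conductance-voltage relations,
#' availability curves, tail-current activation curves). Seeding is
#' deterministic: v_half from the half-maximum crossing, k from the 25-75%
#' width. The offset is fitted only when \code{with_offset} is TRUE.
#'
#' @param v Voltages, mV (>= 5 points spanning the rise).
#' @param y Values (nS for conductance curves, dimensionless for normalized
#'   availability).
#' @param direction \code{"rising"} or \code{"falling"} with depolarization.
#' @param with_offset Fit an additive baseline (default FALSE).
#' @param thermal_voltage kT/e, mV, used to convert the fitted slope to an
#'   equivalent valence.
#' @return An object of class \code{boltzmann_fit}: \code{v_half}, \code{k},
#'   \code{z}, \code{amplitude}, \code{offset}, standard errors \code{se},
#'   \code{rss}, \code{converged}.
#' @export
fit_boltzmann_curve <- function(v, y, direction = c("rising", "falling"),
                                with_offset = FALSE, thermal_voltage = 25.69) {
  direction <- match.arg(direction)
  stopifnot(length(v) == length(y), length(v) >= 5)
  o <- order(v); v <- v[o]; y <- y[o]
  sgn <- if (direction == "rising") 1 else -1

  y0 <- min(y); amp0 <- max(y) - y0
  yn <- (y - y0) / amp0
  if (direction == "falling") yn <- 1 - yn
  cross <- function(level) {
    j <- which(yn[-1] >= level & yn[-length(yn)] < level)
    if (length(j) == 0) return(NA_real_)
    j <- j[1]
    stats::approx(yn[j:(j + 1)], v[j:(j + 1)], xout = level, ties = "ordered")$y
  }
  vh0 <- cross(0.5)
  if (!is.finite(vh0)) vh0 <- stats::median(v)
  w <- cross(0.75) - cross(0.25)
  k0 <- if (is.finite(w) && w > 0) w / (2 * log(3)) else diff(range(v)) / 10

  fit <- if (with_offset)
    .lm_fit(c(off = if (direction == "rising") y0 else min(y),
              amp = amp0, vh = vh0, k = k0),
            function(p) y - (p["off"] + p["amp"] /
                               (1 + exp(sgn * (p["vh"] - v) / p["k"]))),
            lower = c(-Inf, 0, -200, 0.1), upper = c(Inf, Inf, 100, 100))
  else
    .lm_fit(c(amp = amp0 + y0, vh = vh0, k = k0),
            function(p) y - p["amp"] / (1 + exp(sgn * (p["vh"] - v) / p["k"])),
            lower = c(0, -200, 0.1), upper = c(Inf, 100, 100))

  out <- structure(list(v_half = NA_real_, k = NA_real_, z = NA_real_,
                        amplitude = NA_real_, offset = 0,
                        se = c(v_half = NA_real_, k = NA_real_,
                               amplitude = NA_real_),
                        rss = NA_real_, direction = direction,
                        thermal_voltage = thermal_voltage, converged = FALSE),
                   class = "boltzmann_fit")
  if (!fit$converged) return(out)
  out$v_half <- fit$par[["vh"]]
  out$k <- fit$par[["k"]]
  out$z <- thermal_voltage / out$k
  out$amplitude <- fit$par[["amp"]]
  if (with_offset) out$offset <- fit$par[["off"]]
  if (!is.null(fit$se))
    out$se <- c(v_half = unname(fit$se["vh"]), k = unname(fit$se["k"]),
                amplitude = unname(fit$se["amp"]))
  out$rss <- fit$rss
  out$converged <- TRUE
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit (%s): v_half = %.4g mV, k = %.4g mV (z = %.3g), amplitude = %.4g%s\n",
    x$direction, x$v_half, x$k, x$z, x$amplitude,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Time constant of recovery from inactivation
#'
#' Fits the peak test current against the recovery gap with an exponential
#' approach to saturation, \code{peak(gap) = A - B exp(-gap/tau)}; the free
#' pre-factor B accommodates incomplete inactivation at gap zero. Warns when
#' the peaks are not monotone non-decreasing; flags the fit as poorly
#' constrained when every gap greatly exceeds the fitted tau.
#'
#' @param gaps Recovery gap durations, ms (>= 5 values).
#' @param peaks Peak test currents (any consistent sign convention).
#' @return An \code{exponential_fit} whose \code{tau} is the recovery time
#'   constant and \code{amplitude} the saturating peak; extra field
#'   \code{poorly_constrained}.
#' @export
recovery_tau <- function(gaps, peaks) {
  stopifnot(length(gaps) == length(peaks), length(gaps) >= 5)
  o <- order(gaps); gaps <- gaps[o]; peaks <- peaks[o]
  if (any(diff(peaks) < -1e-9 * max(abs(peaks))))
    warning("recovery peaks are not monotone non-decreasing")
  a0 <- max(peaks)
  s <- a0 * 1.02 - peaks
  use <- which(s > 0.01 * max(s))
  ll <- stats::lm(log(s[use]) ~ gaps[use])
  tau0 <- unname(max(-1 / stats::coef(ll)[2], diff(range(gaps)) / 20))
  b0 <- unname(exp(stats::coef(ll)[1]))
  fit <- .lm_fit(c(A = a0, B = b0, tau = tau0),
                 function(p) peaks - (p["A"] - p["B"] * exp(-gaps / p["tau"])),
                 lower = c(-Inf, 0, 1e-3))
  out <- structure(list(amplitude = NA_real_, tau = NA_real_, offset = NA_real_,
                        rss = NA_real_, window = range(gaps),
                        converged = FALSE, degenerate = FALSE,
                        poorly_constrained = FALSE),
                   class = "exponential_fit")
  if (!fit$converged) {
    # a saturated curve (all gaps far beyond tau) carries no information on
    # the time constant: flag it rather than failing silently
    if (stats::sd(peaks) < 0.05 * abs(mean(peaks)))
      out$poorly_constrained <- TRUE
    return(out)
  }
  out$amplitude <- fit$par[["A"]]
  out$offset <- fit$par[["A"]] - fit$par[["B"]]  # fitted peak at gap 0
  out$tau <- fit$par[["tau"]]
  out$rss <- fit$rss
  out$converged <- TRUE
  if (min(gaps) > 3 * out$tau) out$poorly_constrained <- TRUE
  out
}

#' Activation time constant from time-to-peak (Newton inversion)
#'
#' For a current with kinetics \code{(1 - exp(-t/tau_m))^p exp(-t/tau_h)} the
#' time-to-peak satisfies \code{ttp = tau_m log(1 + p tau_h / tau_m)}, which
#' is monotone increasing in tau_m; this solves for tau_m by Newton iteration
#' with a bisection safeguard.
#'
#' @param ttp Measured time-to-peak, ms (> 0, and < p*tau_h for a root to
#'   exist).
#' @param tau_h Inactivation time constant, ms.
#' @param p Activation kinetic order (default 4, the convention used when the
#'   inversion was introduced; the model itself uses order 3).
#' @return tau_m in ms.
#' @export
tau_m_from_ttp <- function(ttp, tau_h, p = 4) {
  stopifnot(ttp > 0, tau_h > 0, p >= 1)
  a <- p * tau_h
  if (ttp >= a)
    stop("no root: time-to-peak must be below p * tau_h")
  f <- function(tm) tm * log1p(a / tm) - ttp
  fp <- function(tm) log1p(a / tm) - a / (tm + a)
  # bracket the root: tau_m can exceed ttp when the logarithm is below 1,
  # so grow the upper bound until the sign flips
  lo <- ttp * 1e-8; hi <- ttp
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > ttp * 1e6) stop("no root found while bracketing")
  }
  tm <- (lo + hi) / 2
  for (it in 1:100) {
    ft <- f(tm)
    if (abs(ft) < 1e-12 * ttp) break
    if (ft > 0) hi <- tm else lo <- tm
    step <- ft / fp(tm)
    tm_new <- tm - step
    if (!is.finite(tm_new) || tm_new <= lo || tm_new >= hi)
      tm_new <- (lo + hi) / 2
    tm <- tm_new
  }
  tm
}

#' Reversal potential by linear extrapolation
#'
#' Least-squares line through the \code{last_n} most depolarized points of a
#' peak current-voltage relation, extrapolated to its zero-current intercept.
#'
#' @param v Voltages, mV (any order).
#' @param i Currents, pA.
#' @param last_n Number of most-depolarized points used (default 4).
#' @return Reversal potential, mV.
#' @export
reversal_from_linreg <- function(v, i, last_n = 4) {
  stopifnot(length(v) == length(i), length(v) >= last_n, last_n >= 2)
  o <- order(v)
  v <- utils::tail(v[o], last_n)
  i <- utils::tail(i[o], last_n)
  cf <- stats::coef(stats::lm(i ~ v))
  if (abs(cf[2]) < 1e-12) stop("zero slope: reversal undefined")
  unname(-cf[1] / cf[2])
}
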