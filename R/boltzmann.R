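#' Boltzmann voltage-dependence specification
#'
#' A sigmoidal dependence on membrane potential, used both for steady-state
#' gating probabilities (amplitude 1) and for whole-cell conductance curves
#' (amplitude in nS). Steepness may be given either as an equivalent gating
#' valence \code{z} (dimensionless charge of the voltage sensor) or as a slope
#' factor \code{k} in mV; the two are tied by \code{k * z = kT/e}
#' (25.69 mV at 25 degrees C).
#'
#' The rising form is \code{amplitude / (1 + exp((v_half - V)/k))}; the
#' falling form mirrors it, \code{amplitude / (1 + exp((V - v_half)/k))}.
#'
#' @param v_half Half-point voltage (mV) at which the value is amplitude/2.
#' @param z Equivalent valence (> 0). Give exactly one of \code{z}, \code{k}
#'   (or both, consistently).
#' @param k Slope factor in mV (> 0).
#' @param amplitude Saturating value (1 for gating probabilities, nS for
#'   conductance curves).
#' @param direction \code{"rising"} (value grows with depolarization) or
#'   \code{"falling"}.
#' @param thermal_voltage kT/e in mV; default 25.69 (25 degrees C).
#' @return An object of class \code{boltzmann_spec}.
#' @export
boltzmann_spec <- function(v_half, z = NULL, k = NULL, amplitude = 1,
                           direction = c("rising", "falling"),
                           thermal_voltage = 25.69) {
  direction <- match.arg(direction)
  stopifnot(is.finite(v_half), amplitude > 0, thermal_voltage > 0)
  if (is.null(z) && is.null(k)) stop("give at least one of z or k")
  if (is.null(k)) k <- thermal_voltage / z
  if (is.null(z)) z <- thermal_voltage / k
  stopifnot(z > 0, k > 0)
  if (abs(k * z - thermal_voltage) > 1e-9 * thermal_voltage)
    stop("inconsistent steepness: k * z must equal the thermal voltage")
  structure(
    list(v_half = v_half, z = z, k = k, amplitude = amplitude,
         direction = direction, thermal_voltage = thermal_voltage),
    class = "boltzmann_spec")
}

#' Evaluate a Boltzmann curve
#'
#' @param spec A \code{\link{boltzmann_spec}}.
#' @param v Membrane potential(s), mV. Must be finite.
#' @return Value(s) in the units of the spec's amplitude.
#' @export
boltzmann_eval <- function(spec, v) {
  stopifnot(inherits(spec, "boltzmann_spec"))
  if (!all(is.finite(v))) stop("non-finite voltage")
  dir <- if (spec$direction == "rising") 1L else -1L
  boltzmann_eval_cpp(as.numeric(v), spec$v_half, spec$k, dir, spec$amplitude)
}

#' @export
print.boltzmann_spec <- function(x, ...) {
  cat(sprintf("Boltzmann (%s): v_half = %g mV, k = %g mV (z = %g), amplitude = %g\n",
              x$direction, x$v_half, x$k, x$z, x$amplitude))
  invisible(x)
}
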