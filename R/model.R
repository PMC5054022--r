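#' Ion-channel specification
#'
#' @param name Channel label (e.g. "A", "Na", "h", "CaL").
#' @param g_max Maximal conductance, nS (>= 0).
#' @param e_rev Reversal potential, mV.
#' @param gates List of \code{\link{gate_spec}} objects.
#' @return An object of class \code{channel_spec}.
#' @export
channel_spec <- function(name, g_max, e_rev, gates) {
  stopifnot(g_max >= 0, is.finite(e_rev),
            all(vapply(gates, inherits, TRUE, "gate_spec")))
  structure(list(name = name, g_max = g_max, e_rev = e_rev, gates = gates),
            class = "channel_spec")
}

#' Single-compartment membrane model
#'
#' @param c_m Membrane capacitance, pF (> 0).
#' @param g_leak Leak conductance, nS (>= 0).
#' @param e_leak Leak reversal potential, mV.
#' @param channels List of \code{\link{channel_spec}} objects.
#' @return An object of class \code{membrane_model}.
#' @export
membrane_model <- function(c_m, g_leak, e_leak, channels = list()) {
  stopifnot(c_m > 0, g_leak >= 0, is.finite(e_leak),
            all(vapply(channels, inherits, TRUE, "channel_spec")))
  names(channels) <- vapply(channels, `[[`, "", "name")
  structure(list(c_m = c_m, g_leak = g_leak, e_leak = e_leak,
                 channels = channels), class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("Membrane model: C_m = %.3g pF, R_in = %.4g MOhm, E_leak = %g mV\n",
              x$c_m, 1e3 / x$g_leak, x$e_leak))
  for (ch in x$channels)
    cat(sprintf("  %-4s g_max = %.3g nS, E_rev = %.4g mV, gates: %s\n",
                ch$name, ch$g_max, ch$e_rev,
                paste(vapply(ch$gates, function(g)
                  sprintf("%s^%d", g$name, g$p), ""), collapse = " * ")))
  invisible(x)
}

#' Nernst equilibrium potential
#'
#' @param c_out,c_in Outside / inside concentrations, mM (> 0).
#' @param valence Ionic valence (signed integer).
#' @param temperature Temperature in degrees C (default 25).
#' @return Equilibrium potential in mV.
#' @export
nernst <- function(c_out, c_in, valence = 1L, temperature = 25) {
  if (any(c(c_out, c_in) <= 0)) stop("concentrations must be positive")
  stopifnot(valence != 0)
  R <- 8.314462618; F <- 96485.33212
  1e3 * R * (temperature + 273.15) / (valence * F) * log(c_out / c_in)
}

# model flattened for the compiled integrator
.model_flat <- function(model) {
  list(c_m = model$c_m, g_leak = model$g_leak, e_leak = model$e_leak,
       channels = unname(lapply(model$channels, function(ch)
         list(g_max = ch$g_max, e_rev = ch$e_rev,
              gates = lapply(ch$gates, .gate_flat)))))
}

#' Steady-state total membrane current at a voltage
#'
#' Leak plus every channel evaluated with all gates at their steady state,
#' outward positive. Useful for computing holding currents and resting
#' potentials.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param v Membrane potential(s), mV.
#' @return Current in pA.
#' @export
steady_state_current <- function(model, v) {
  i <- model$g_leak * (v - model$e_leak)
  for (ch in model$channels) {
    open <- rep(1, length(v))
    for (g in ch$gates) open <- open * gate_steady_state(g, v)^g$p
    i <- i + ch$g_max * open * (v - ch$e_rev)
  }
  i
}

#' Resting potential under a constant injected current
#'
#' Solves \code{I_inj = steady_state_current(model, V)} for V, taking the
#' root nearest the leak reversal when several exist.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param i_inj Injected current, pA (default 0).
#' @return Resting potential, mV.
#' @export
resting_potential <- function(model, i_inj = 0) {
  f <- function(v) i_inj - steady_state_current(model, v)
  vg <- seq(-120, 20, by = 0.5)
  fv <- f(vg)
  s <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(s) == 0) stop("no steady state found in [-120, 20] mV")
  roots <- vapply(s, function(j)
    stats::uniroot(f, c(vg[j], vg[j + 1]), tol = 1e-10)$root, 0)
  roots[which.min(abs(roots - model$e_leak))]
}

#' Holding current pinning the membrane at a voltage
#'
#' @param model A \code{\link{membrane_model}}.
#' @param v Target holding potential, mV.
#' @return Current in pA such that v is a steady state.
#' @export
holding_current <- function(model, v) steady_state_current(model, v)

#' Zero or rescale channel conductances
#'
#' Convenience for the pharmacological isolation used throughout the analyses
#' (TTX, 4-AP, nifedipine modelled purely as conductance scaling): channels
#' named in \code{keep} retain their conductance, all others are scaled by
#' \code{factor} (default 0, i.e. full block).
#'
#' @param model A \code{\link{membrane_model}}.
#' @param keep Character vector of channel names to leave untouched.
#' @param factor Scale applied to the other channels' g_max.
#' @return The modified model.
#' @export
isolate_channels <- function(model, keep, factor = 0) {
  for (nm in names(model$channels))
    if (!nm %in% keep)
      model$channels[[nm]]$g_max <- model$channels[[nm]]$g_max * factor
  model
}

#' Scale one channel property
#'
#' @param model A \code{\link{membrane_model}}.
#' @param channel Channel name.
#' @param g_max,e_rev Optional replacement values.
#' @param tau_scale Optional factor applied to tau branches of a gate
#'   (coefficients and floor), e.g. 0.1 for a ten-fold faster gate.
#' @param gate Restrict \code{tau_scale} to this gate name.
#' @param tau_branches Optional integer indices of the tau branches (in
#'   ascending voltage order) to scale; default all. A stitched law fitted
#'   over disjoint ranges can thus be manipulated on one range only -- e.g.
#'   shortening just the removal-of-inactivation branch of the Na h gate.
#' @return The modified model.
#' @export
modify_channel <- function(model, channel, g_max = NULL, e_rev = NULL,
                           tau_scale = NULL, gate = NULL,
                           tau_branches = NULL) {
  ch <- model$channels[[channel]]
  if (is.null(ch)) stop("no channel named ", channel)
  if (!is.null(g_max)) ch$g_max <- g_max
  if (!is.null(e_rev)) ch$e_rev <- e_rev
  if (!is.null(tau_scale)) {
    for (i in seq_along(ch$gates)) {
      if (!is.null(gate) && ch$gates[[i]]$name != gate) next
      tb <- ch$gates[[i]]$tau
      rows <- if (is.null(tau_branches)) seq_len(nrow(tb$branches))
              else tau_branches
      # scale the time-valued coefficients: exp-offset A and C (p2 is a
      # voltage scale and stays); quadratic c0, c1, c2 all carry time units
      tb$branches[rows, c("p1", "p3")] <-
        tb$branches[rows, c("p1", "p3")] * tau_scale
      quad <- intersect(rows, which(tb$branches[, "type"] == 2))
      tb$branches[quad, "p2"] <- tb$branches[quad, "p2"] * tau_scale
      tb$floor <- tb$floor * min(tau_scale, 1)
      ch$gates[[i]]$tau <- tb
    }
  }
  model$channels[[channel]] <- ch
  model
}
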