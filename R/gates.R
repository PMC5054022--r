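#' Gating-variable specification
#'
#' One Hodgkin-Huxley gate: the state variable x relaxes toward a
#' voltage-dependent steady state with a voltage-dependent time constant, and
#' enters the channel open probability as x^p. The steady state is either a
#' Boltzmann curve directly, or the r-th root of a Boltzmann "base" curve --
#' the form that arises when an activation curve is obtained by extracting the
#' r-th root of a fitted conductance-voltage relation (so that x_inf^r,
#' times g_max, reproduces the fitted conductance curve exactly).
#'
#' @param name Gate label (e.g. "m", "h", "a").
#' @param p Integer exponent in 1:4.
#' @param steady_state A \code{\link{boltzmann_spec}} with amplitude 1.
#' @param tau A \code{tau_spec}.
#' @param root Integer r >= 1; steady state is \code{base^(1/r)}.
#' @return An object of class \code{gate_spec}.
#' @export
gate_spec <- function(name, p, steady_state, tau, root = 1L) {
  stopifnot(p %in% 1:4, inherits(steady_state, "boltzmann_spec"),
            inherits(tau, "tau_spec"), root >= 1, root == round(root))
  if (steady_state$amplitude != 1)
    stop("gate steady-state Boltzmann must have amplitude 1")
  structure(list(name = name, p = as.integer(p), steady_state = steady_state,
                 tau = tau, root = as.integer(root)), class = "gate_spec")
}

#' Gate steady-state open probability
#'
#' @param gate A \code{\link{gate_spec}}.
#' @param v Membrane potential(s), mV.
#' @return Probability in [0, 1].
#' @export
gate_steady_state <- function(gate, v) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!all(is.finite(v))) stop("non-finite voltage")
  ss <- gate$steady_state
  dir <- if (ss$direction == "rising") 1L else -1L
  gate_ss_cpp(as.numeric(v), ss$v_half, ss$k, dir, as.numeric(gate$root))
}

#' Gate relaxation time constant
#'
#' @inheritParams gate_steady_state
#' @return tau in ms.
#' @export
gate_tau <- function(gate, v) {
  stopifnot(inherits(gate, "gate_spec"))
  tau_eval(gate$tau, v)
}

# flatten for the compiled integrator
.gate_flat <- function(gate) {
  ss <- gate$steady_state
  list(name = gate$name, p = as.numeric(gate$p),
       ss = c(ss$v_half, ss$k, if (ss$direction == "rising") 1 else -1,
              as.numeric(gate$root)),
       tau_branches = gate$tau$branches, tau_floor = gate$tau$floor)
}
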