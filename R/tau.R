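#' Voltage-dependent time-constant laws
#'
#' Phenomenological tau(V) descriptions, as fitted to measured gate kinetics:
#' an exponential with offset, a quadratic polynomial, or a voltage-stitched
#' piecewise combination (separate laws fitted over disjoint voltage ranges,
#' joined by linear interpolation across the unmeasured gap). Every law
#' carries a positive floor so tau never reaches zero.
#'
#' @name tau_spec
NULL

.tau_branch_row <- function(form) {
  if (form$form == "exp_offset") {
    c(1, form$v_range[1], form$v_range[2], form$A, form$V_s, form$C)
  } else {
    c(2, form$v_range[1], form$v_range[2], form$c0, form$c1, form$c2)
  }
}

.tau_spec <- function(branches, floor) {
  stopifnot(floor > 0)
  m <- do.call(rbind, lapply(branches, .tau_branch_row))
  colnames(m) <- c("type", "vlo", "vhi", "p1", "p2", "p3")
  if (nrow(m) > 1) {
    o <- order(m[, "vlo"])
    m <- m[o, , drop = FALSE]
    if (any(m[-1, "vlo"] < m[-nrow(m), "vhi"]))
      stop("tau branches must cover disjoint voltage ranges")
  }
  structure(list(branches = m, floor = floor,
                 forms = branches), class = "tau_spec")
}

#' Exponential-plus-offset tau law: tau(V) = A * exp(-V / V_s) + C
#'
#' @param A Amplitude, ms.
#' @param V_s Voltage scale, mV (negative values give growth with
#'   depolarization, as in laws printed as \code{exp(-V / -Vs)}).
#' @param C Offset, ms.
#' @param floor Minimum tau, ms.
#' @param v_range Voltage range over which this law was fitted (used only by
#'   stitching); defaults to all voltages.
#' @return A \code{tau_spec}.
#' @export
tau_exp_offset <- function(A, V_s, C, floor = 1e-3, v_range = c(-Inf, Inf)) {
  .tau_spec(list(list(form = "exp_offset", A = A, V_s = V_s, C = C,
                      v_range = .clip_range(v_range))), floor)
}

#' Quadratic tau law: tau(V) = c0 + c1*V + c2*V^2
#'
#' @param c0,c1,c2 Polynomial coefficients (ms, ms/mV, ms/mV^2).
#' @inheritParams tau_exp_offset
#' @return A \code{tau_spec}.
#' @export
tau_quadratic <- function(c0, c1, c2, floor = 1e-3, v_range = c(-Inf, Inf)) {
  .tau_spec(list(list(form = "quadratic", c0 = c0, c1 = c1, c2 = c2,
                      v_range = .clip_range(v_range))), floor)
}

#' Stitch tau laws fitted over disjoint voltage ranges
#'
#' Inside each declared range the corresponding law applies; across a gap
#' between two ranges the evaluation bridges linearly between the flanking
#' branch endpoints, so the combined law is continuous.
#'
#' @param ... \code{tau_spec} objects, each with a finite \code{v_range} on at
#'   most one side.
#' @param floor Minimum tau, ms.
#' @return A \code{tau_spec}.
#' @export
tau_stitched <- function(..., floor = 1e-3) {
  parts <- list(...)
  stopifnot(length(parts) >= 2, all(vapply(parts, inherits, TRUE, "tau_spec")))
  .tau_spec(unlist(lapply(parts, function(p) p$forms), recursive = FALSE), floor)
}

# infinities are encoded as +-1e9 mV in the branch table (C++ side has no Inf
# guard; physiological V never approaches these)
.clip_range <- function(v_range) {
  v_range[v_range == -Inf] <- -1e9
  v_range[v_range == Inf] <- 1e9
  v_range
}

#' Evaluate a tau law
#'
#' @param spec A \code{tau_spec}.
#' @param v Membrane potential(s), mV.
#' @return tau in ms, floored at \code{spec$floor}.
#' @export
tau_eval <- function(spec, v) {
  stopifnot(inherits(spec, "tau_spec"))
  if (!all(is.finite(v))) stop("non-finite voltage")
  tau_eval_cpp(as.numeric(v), spec$branches, spec$floor)
}
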