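#' Recording-noise specification
#'
#' Additive white Gaussian noise on the recorded channel: current noise in
#' voltage clamp, voltage noise in current clamp. Identical seeds give
#' identical traces.
#'
#' @param current_sd Current noise sd, pA (>= 0).
#' @param voltage_sd Voltage noise sd, mV (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(current_sd = 0, voltage_sd = 0, seed = 1L) {
  stopifnot(current_sd >= 0, voltage_sd >= 0)
  structure(list(current_sd = current_sd, voltage_sd = voltage_sd,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Generate a set of noisy synthetic recordings
#'
#' Simulates every sweep of the protocol and adds Gaussian recording noise to
#' the measured channel. The generating model fingerprint, seed and noise sd
#' are embedded in each recording's metadata.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param proto A \code{\link{protocol}} (its sweep axis is expanded).
#' @param noise A \code{\link{noise_spec}}.
#' @param dt Time step, ms.
#' @return An object of class \code{synthetic_set}: list with
#'   \code{recordings}, \code{noise}, \code{model}.
#' @export
generate_recording_set <- function(model, proto, noise = noise_spec(),
                                   dt = 0.01) {
  stopifnot(inherits(noise, "noise_spec"))
  sweeps <- protocol_sweeps(proto)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(noise$seed)
  recs <- lapply(sweeps, function(p) {
    rec <- simulate(model, p, dt = dt)
    n <- nrow(rec$data)
    if (p$mode == "vc" && noise$current_sd > 0)
      rec$data$i <- rec$data$i + stats::rnorm(n, 0, noise$current_sd)
    if (p$mode == "cc" && noise$voltage_sd > 0)
      rec$data$v <- rec$data$v + stats::rnorm(n, 0, noise$voltage_sd)
    rec$seed <- noise$seed
    rec$noise_sd <- if (p$mode == "vc") noise$current_sd else noise$voltage_sd
    rec
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(recordings = recs, noise = noise, model = model),
            class = "synthetic_set")
}

#' Cell-population specification
#'
#' Between-cell variability for sampled model populations: multiplicative
#' parameters (capacitance, conductances) get a truncated-Gaussian coefficient
#' of variation, half-point voltages get an additive mV jitter, slope factors
#' a separate CV. Draws beyond \code{trunc} standard deviations are redrawn.
#'
#' @param n Number of cells.
#' @param cv CV of multiplicative parameters (default 0.10).
#' @param v_half_sd Additive sd on half-point voltages, mV (default 2).
#' @param slope_cv CV of slope factors (default 0.05).
#' @param trunc Truncation, in sd (default 3).
#' @param seed Integer RNG seed.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(n, cv = 0.10, v_half_sd = 2, slope_cv = 0.05,
                            trunc = 3, seed = 1L) {
  stopifnot(n >= 1, cv >= 0, v_half_sd >= 0, slope_cv >= 0, trunc > 0)
  structure(list(n = as.integer(n), cv = cv, v_half_sd = v_half_sd,
                 slope_cv = slope_cv, trunc = trunc, seed = as.integer(seed)),
            class = "population_spec")
}

# truncated standard normal draw (rejection; trunc >= 1 so this terminates fast)
.rtnorm <- function(n, trunc) {
  out <- stats::rnorm(n)
  bad <- abs(out) > trunc
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad))
    bad <- abs(out) > trunc
  }
  out
}

#' Sample a population of cells around a base model
#'
#' @param base A \code{\link{membrane_model}}.
#' @param spec A \code{\link{population_spec}}.
#' @return List of \code{n} jittered \code{membrane_model} objects.
#' @export
sample_population <- function(base, spec) {
  stopifnot(inherits(spec, "population_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  models <- lapply(seq_len(spec$n), function(i) {
    m <- base
    mult <- function(x) x * (1 + spec$cv * .rtnorm(1, spec$trunc))
    m$c_m <- mult(m$c_m)
    m$g_leak <- mult(m$g_leak)
    for (nm in names(m$channels)) {
      ch <- m$channels[[nm]]
      ch$g_max <- mult(ch$g_max)
      for (gi in seq_along(ch$gates)) {
        ss <- ch$gates[[gi]]$steady_state
        ss$v_half <- ss$v_half + spec$v_half_sd * .rtnorm(1, spec$trunc)
        ss$k <- ss$k * (1 + spec$slope_cv * .rtnorm(1, spec$trunc))
        ss$z <- ss$thermal_voltage / ss$k
        ch$gates[[gi]]$steady_state <- ss
      }
      m$channels[[nm]] <- ch
    }
    m
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  models
}
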