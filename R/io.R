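#' Write a model parameterization to a structured text config
#'
#' JSON with full double precision; \code{\link{read_model_config}} restores
#' an identical model (loss-free round trip).
#'
#' @param model A \code{\link{membrane_model}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "membrane_model"))
  as_plain <- list(
    c_m = model$c_m, g_leak = model$g_leak, e_leak = model$e_leak,
    channels = lapply(unname(model$channels), function(ch) list(
      name = ch$name, g_max = ch$g_max, e_rev = ch$e_rev,
      gates = lapply(ch$gates, function(g) {
        ss <- g$steady_state
        list(name = g$name, p = g$p, root = g$root,
             steady_state = list(v_half = ss$v_half, k = ss$k,
                                 amplitude = ss$amplitude,
                                 direction = ss$direction,
                                 thermal_voltage = ss$thermal_voltage),
             tau = list(floor = g$tau$floor,
                        forms = lapply(g$tau$forms, function(fm) fm)))
      })))
  )
  jsonlite::write_json(as_plain, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

.tau_from_forms <- function(forms, floor) {
  parts <- lapply(forms, function(fm) {
    vr <- unlist(fm$v_range)
    if (fm$form == "exp_offset")
      tau_exp_offset(A = fm$A, V_s = fm$V_s, C = fm$C, floor = floor,
                     v_range = vr)
    else
      tau_quadratic(c0 = fm$c0, c1 = fm$c1, c2 = fm$c2, floor = floor,
                    v_range = vr)
  })
  if (length(parts) == 1) parts[[1]]
  else do.call(tau_stitched, c(parts, list(floor = floor)))
}

#' Read a model parameterization from a config file
#'
#' @param path Path written by \code{\link{write_model_config}}.
#' @return A \code{\link{membrane_model}}.
#' @export
read_model_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  chans <- lapply(x$channels, function(ch) {
    gates <- lapply(ch$gates, function(g) {
      ss <- g$steady_state
      gate_spec(g$name, p = g$p, root = g$root,
                steady_state = boltzmann_spec(
                  v_half = ss$v_half, k = ss$k, amplitude = ss$amplitude,
                  direction = ss$direction,
                  thermal_voltage = ss$thermal_voltage),
                tau = .tau_from_forms(g$tau$forms, g$tau$floor))
    })
    channel_spec(ch$name, g_max = ch$g_max, e_rev = ch$e_rev, gates = gates)
  })
  membrane_model(c_m = x$c_m, g_leak = x$g_leak, e_leak = x$e_leak,
                 channels = chans)
}

#' Write a recording as CSV plus a metadata sidecar
#'
#' The trace goes to \code{<prefix>.csv} (full double precision) and the
#' metadata (mode, dt, segments, label, model fingerprint, seed, noise sd) to
#' \code{<prefix>.json}; \code{\link{read_recording}} reconstructs the
#' recording from the pair.
#'
#' @param rec A \code{recording}.
#' @param prefix Output path prefix (no extension).
#' @return \code{prefix}, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "recording"))
  # 17 significant digits: the shortest representation guaranteeing a
  # bit-exact double round trip through text
  txt <- as.data.frame(lapply(rec$data, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col),
    check.names = FALSE)
  data.table::fwrite(txt, paste0(prefix, ".csv"), quote = FALSE)
  meta <- list(dt = rec$dt, mode = rec$mode,
               segments = rec$segments, label = rec$label,
               seed = rec$seed, noise_sd = rec$noise_sd,
               model_fingerprint = rec$model_fingerprint)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns")
  invisible(prefix)
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' @param prefix Path prefix used when writing.
#' @return A \code{recording}.
#' @export
read_recording <- function(prefix) {
  df <- as.data.frame(data.table::fread(paste0(prefix, ".csv")))
  # integer-looking columns (e.g. a clamped command voltage) back to double
  df[] <- lapply(df, function(col) if (is.integer(col)) as.numeric(col) else col)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  seed <- meta$seed
  structure(list(
    data = df, dt = meta$dt, mode = meta$mode,
    segments = as.data.frame(meta$segments), label = meta$label,
    seed = if (is.null(seed) || length(seed) == 0) NA_integer_ else seed,
    noise_sd = meta$noise_sd, model_fingerprint = meta$model_fingerprint),
    class = "recording")
}
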