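#' Run the full reproduction pipeline and tabulate recovered vs. printed values
#'
#' Executes, in order: the passive round trip, the A-current zero-time
#' conductance analysis with its inactivation and recovery protocols, the
#' Na-current analogues, the h-current tail analysis, the calcium persistent
#' amplitudes, the excitability battery, and the Nernst check; each recovered
#' quantity is compared with the corresponding published value at its
#' tolerance. A stage failure is recorded in the report and the run continues.
#'
#' @param config List of options: \code{model} (default
#'   \code{reference_cr_cell()}), \code{dt} (default 0.01 ms), \code{dt_h}
#'   (step for the multi-second h-current sweeps, default 0.05 ms),
#'   \code{tol_param} (relative tolerance for noise-free parameter recovery,
#'   default 0.02), \code{tol_recovery} (default 0.10), \code{stages}
#'   (character subset of \code{c("passive","a","na","h","ca","excitability",
#'   "nernst")}).
#' @return An object of class \code{repro_report}: a data.frame with columns
#'   \code{quantity}, \code{paper}, \code{recovered}, \code{unit},
#'   \code{rel_dev}, \code{tolerance}, \code{pass}, \code{stage},
#'   \code{note}.
#' @export
reproduce_all <- function(config = list()) {
  cfg <- utils::modifyList(list(
    model = reference_cr_cell(), dt = 0.01, dt_h = 0.05,
    tol_param = 0.02, tol_recovery = 0.10,
    stages = c("passive", "a", "na", "h", "ca", "excitability", "nernst")),
    config)
  model <- cfg$model
  rows <- list()
  add <- function(stage, quantity, paper, recovered, unit, tol, note = "") {
    dev <- if (is.finite(paper) && paper != 0)
      (recovered - paper) / abs(paper) else NA_real_
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, paper = paper, recovered = recovered, unit = unit,
      rel_dev = dev, tolerance = tol,
      pass = is.finite(recovered) && is.finite(dev) && abs(dev) <= tol,
      stage = stage, note = note)
  }
  add_bool <- function(stage, quantity, ok, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, paper = NA_real_, recovered = as.numeric(ok),
      unit = "bool", rel_dev = NA_real_, tolerance = NA_real_,
      pass = isTRUE(ok), stage = stage, note = note)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      rows[[length(rows) + 1]] <<- data.frame(
        quantity = paste0(stage, " stage"), paper = NA_real_,
        recovered = NA_real_, unit = "", rel_dev = NA_real_,
        tolerance = NA_real_, pass = FALSE, stage = stage,
        note = paste("stage error:", conditionMessage(e)))
      NULL
    })
  }

  run_stage("passive", function() {
    pf <- analyze_passive(model, dt = cfg$dt)
    add("passive", "C_m", 4.07, pf$c_m, "pF", 0.01)
    add("passive", "R_in", 1877.7, pf$r_in, "MOhm", 0.01)
    add("passive", "tau_m", 4.07 * 1.8777, pf$tau_m, "ms", 0.01,
        note = "product of the printed C_m and R_in")
  })

  run_stage("a", function() {
    a <- analyze_a_current(model, dt = cfg$dt)
    add("a", "A v_half", -12.3, a$fit$v_half, "mV", cfg$tol_param)
    add("a", "A valence z", 3.8, a$fit$z, "", cfg$tol_param)
    add("a", "A g_max", 8.08, a$fit$amplitude, "nS", cfg$tol_param)
    add("a", "A inact midpoint", -52.7, a$inactivation$fit$v_half, "mV",
        cfg$tol_param)
    add("a", "A inact slope", 7.59, a$inactivation$fit$k, "mV", cfg$tol_param)
    rec <- analyze_a_recovery(model, dt = cfg$dt)
    add("a", "A recovery tau (-70 mV)", 41.9, rec$fit$tau, "ms",
        cfg$tol_recovery)
  })

  run_stage("na", function() {
    na <- analyze_na_current(model, dt = cfg$dt)
    add("na", "Na g_max", 12.7, na$fit$amplitude, "nS", cfg$tol_param)
    add("na", "Na valence z", 4.3, na$fit$z, "", cfg$tol_param)
    add("na", "Na v_half", -34.6, na$fit$v_half, "mV", cfg$tol_param)
    add("na", "Na inact midpoint", -70.0, na$inactivation$fit$v_half, "mV",
        cfg$tol_param)
    add("na", "Na inact slope", 9.4, na$inactivation$fit$k, "mV",
        cfg$tol_param)
  })

  run_stage("h", function() {
    h <- analyze_h_current(model, dt = cfg$dt_h)
    add("h", "I_h V_50", -100, h$fit$v_half, "mV", cfg$tol_param)
    add("h", "I_h slope", 9.02, h$fit$k, "mV", cfg$tol_param)
  })

  run_stage("ca", function() {
    iv <- analyze_ca_current(model, dt = cfg$dt)
    add_bool("ca", "I_Ca persistent inward with an I-V optimum",
             min(iv$i) < 0 && which.min(iv$i) > 1 &&
               which.min(iv$i) < nrow(iv))
  })

  run_stage("excitability", function() {
    ex <- excitability_battery(model, dt = cfg$dt)
    add_bool("excitability", "single spike on sustained supra-threshold step",
             ex$n_spikes_sustained == 1)
    add_bool("excitability", "late-phase I-V linear (r^2 >= 0.99)",
             ex$late_iv$r_squared >= 0.99)
    add_bool("excitability", "no second spike at intervals <= 50 ms",
             all(!ex$paired$spike2[ex$paired$interval <= 50]))
    add_bool("excitability", "full second spike at 310 ms (>= 90% of first)",
             ex$paired$spike2[ex$paired$interval == 310] &&
               ex$paired$amp_ratio[ex$paired$interval == 310] >= 0.9)
    add_bool("excitability", "second-pulse amplitude non-decreasing",
             !is.unsorted(ex$paired$amplitude2))
    add_bool("excitability", "tau_rh / 10 restores the 50-ms second spike",
             ex$paired_fast_rh$spike2)
    add_bool("excitability", "A-conductance suppression broadens the spike",
             ex$spike_width_noA > ex$spike_width)
  })

  run_stage("nernst", function() {
    e_na <- nernst(125 + 26 + 1.25, 10 + 2 * 2, valence = 1, temperature = 25)
    add("nernst", "Nernst E_Na", 61.4, e_na, "mV", 0.002,
        note = "printed solution compositions, 25 C")
  })

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("repro_report", "data.frame")
  out
}

#' @export
print.repro_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$paper <- signif(df$paper, 5)
  df$recovered <- signif(df$recovered, 5)
  df$rel_dev <- signif(df$rel_dev, 3)
  print(df[, c("quantity", "paper", "recovered", "unit", "rel_dev",
               "tolerance", "pass")], row.names = FALSE)
  cat(sprintf("\n%d/%d rows pass\n", sum(x$pass), nrow(x)))
  invisible(x)
}

#' Write / read a reproduction report (loss-free CSV)
#'
#' @param report A \code{repro_report}.
#' @param path CSV path.
#' @return \code{path} (write) or the reloaded \code{repro_report} (read).
#' @export
write_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  class(df) <- c("repro_report", "data.frame")
  df
}
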