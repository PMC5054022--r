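#!/usr/bin/env Rscript
# Sodium current characterization on the isolated Na conductance:
# zero-time conductance analysis with E_Na = +63 mV (expect g ~ 12.7 nS,
# z ~ 4.3, V_h ~ -34.6 mV), the availability curve (expect -70.0 / 9.4 mV),
# the cube-root activation curve, and the reversal potential extrapolated
# from the last four points of the peak I-V relation.

suppressPackageStartupMessages(library(crpg))
dir.create("results", showWarnings = FALSE)

na <- analyze_na_current()
cat("-- activation (open-channel conductance) --\n")
print(na$fit)
cat("\n-- steady-state inactivation --\n")
print(na$inactivation$fit)
cat("\n-- cube-root activation curve fit --\n")
print(na$ss$fit)
cat(sprintf("\nreversal by linear extrapolation: %+.1f mV (driving-force convention +63 mV)\n",
            na$e_rev_extrapolated))

write.csv(na$gv, "results/03_na_conductance_curve.csv", row.names = FALSE)
write.csv(na$peak_iv, "results/03_na_peak_iv.csv", row.names = FALSE)
write.csv(data.frame(
  quantity = c("g_max_ns", "valence_z", "v_half_mv", "inact_midpoint_mv",
               "inact_slope_mv", "m_inf_midpoint_mv", "e_rev_extrapolated_mv"),
  value = c(na$fit$amplitude, na$fit$z, na$fit$v_half,
            na$inactivation$fit$v_half, na$inactivation$fit$k,
            na$ss$fit$v_half, na$e_rev_extrapolated)),
  "results/03_na_current.csv", row.names = FALSE)
cat("written results/03_na_*.csv\n")
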