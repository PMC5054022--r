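#!/usr/bin/env Rscript
# h-current step/tail analysis on the isolated h-conductance: 5-s
# hyperpolarizing steps from -40 mV, I_ss - I_inst amplitudes, and the
# tail-current activation curve (expect V_50 ~ -100 mV, slope ~ 9.02 mV).
# These sweeps dominate the pipeline's runtime; dt = 0.05 ms.

suppressPackageStartupMessages(library(crpg))
dir.create("results", showWarnings = FALSE)

h <- analyze_h_current()
cat("-- tail-current activation curve --\n")
print(h$fit)
cat("\n-- I_ss - I_inst amplitudes --\n")
print(h$amplitudes)

write.csv(h$amplitudes, "results/04_h_amplitudes.csv", row.names = FALSE)
write.csv(h$tail, "results/04_h_tail_activation.csv", row.names = FALSE)
write.csv(data.frame(quantity = c("v50_mv", "slope_mv"),
                     value = c(h$fit$v_half, h$fit$k)),
          "results/04_h_current.csv", row.names = FALSE)
cat("written results/04_h_*.csv\n")
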