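#!/usr/bin/env Rscript
# L-type calcium current: persistent (late-window) current-voltage relation
# on the isolated 0.6 nS Ca conductance (the blocked-Na/K recording
# condition). The relation is inward with an optimum where activation and
# driving force trade off, near -10..0 mV.

suppressPackageStartupMessages(library(crpg))
dir.create("results", showWarnings = FALSE)

iv <- analyze_ca_current()
print(iv)
cat(sprintf("maximal persistent inward current: %.1f pA at %+d mV\n",
            min(iv$i), iv$v[which.min(iv$i)]))

write.csv(iv, "results/05_ca_persistent_iv.csv", row.names = FALSE)
cat("written results/05_ca_persistent_iv.csv\n")
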