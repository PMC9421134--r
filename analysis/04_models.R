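#!/usr/bin/env Rscript
# Fit the two multilevel models on the assembled analysis tables:
# a linear mixed model of the RMSSD reactivity difference score, and a
# Poisson generalized linear mixed model of recovery minutes reported as
# incidence rate ratios.
library(hrvstress)

react <- readr::read_csv("results/pipeline/reactivity_table.csv",
                         show_col_types = FALSE)
rec <- readr::read_csv("results/pipeline/recovery_table.csv",
                       show_col_types = FALSE)

fit_r <- fit_reactivity(react)
fit_p <- fit_recovery(rec)

cat("== RMSSD reactivity (linear mixed model) ==\n")
print(fit_r)
cat("\n== RMSSD recovery minutes (Poisson GLMM, IRR scale) ==\n")
print(fit_p)

dir.create("results/fits", showWarnings = FALSE)
readr::write_csv(summarize_fit(fit_r)$fixed, "results/fits/reactivity.csv")
readr::write_csv(summarize_fit(fit_p)$fixed, "results/fits/recovery.csv")
cat("\nfit tables written to results/fits/\n")
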