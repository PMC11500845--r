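#!/usr/bin/env Rscript
# One-way sensitivity analysis: every parameter with a one-way range is set
# to its low and high bound (others at base), the model is rerun, and the
# ICER of each strategy against CBPM is recorded. Outputs are tornado-ready
# tables sorted by swing.

suppressPackageStartupMessages(library(htcue))
dir.create("results", showWarnings = FALSE)

ps <- default_parameter_set(synthetic_spec(seed = 1))

for (intervention in c("HBPM", "Serial1", "Serial2")) {
  tor <- one_way_sensitivity(ps, c(intervention, "CBPM"))
  out <- sprintf("results/tornado_%s_vs_cbpm.csv", tolower(intervention))
  utils::write.csv(tor, out, row.names = FALSE)
  cat(sprintf("%s vs CBPM: base ICER %s baht/QALY; %d parameters varied\n",
              intervention,
              format(round(attr(tor, "icer_base")), big.mark = ","),
              nrow(tor)))
  cat("  top-3 swing parameters:\n")
  for (i in 1:3) {
    cat(sprintf("    %-28s swing %s\n", tor$parameter[i],
                format(round(tor$swing[i]), big.mark = ",")))
  }
}
cat("\nThe published analysis found hypertension incidence at ages 40-49 the",
    "most influential input for all three comparisons; compare the top rows",
    "of the tornado tables (stand-in ranges, so the ordering is indicative,",
    "not a reproduction).\n")
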