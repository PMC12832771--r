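#!/usr/bin/env Rscript
# Scenario analyses: shortened horizons (4/5/10 years), exclusion of
# adverse-event disutilities, accrual restricted to the progression-free
# state, and monotherapy comparators, for both country perspectives.

suppressPackageStartupMessages(library(psmcea))
seed <- 20260928L

for (country in c("US", "China")) {
  out <- file.path("results", tolower(country))
  bundle <- run_pipeline(pipeline_config(country = country,
                                         analyses = c("base", "scenarios"),
                                         out_dir = out, seed = seed))
  cat("\n==", country, "scenario analyses (base ICER",
      sprintf("%.2f", bundle$ce$icer), ") ==\n")
  print(transform(bundle$scenarios,
                  dcost = round(dcost, 2), dqaly = round(dqaly, 4),
                  icer = round(icer, 2))[, c("scenario", "dcost", "dqaly", "icer")],
        row.names = FALSE)
  i4 <- bundle$scenarios$icer[bundle$scenarios$scenario == "horizon_4y"]
  if (i4 > bundle$ce$icer)
    cat("The 4-year horizon inflates the ICER: the incremental survival",
        "benefit accrues late in this realization.\n")
  else
    cat("The 4-year horizon does not inflate the ICER here: in this",
        "realization the incremental benefit is concentrated early.\n")
}
cat("\nScenario tables written under results/us and results/china\n")
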