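#!/usr/bin/env Rscript
# Base-case cost-effectiveness analysis: four-state partitioned survival
# model over the model-averaged survivor functions, discounted cost and
# QALY accrual under each country's parameter set, incremental results.
# Also reproduces the published base-case ICER arithmetic from the printed
# incremental costs and QALYs as a worked example.

suppressPackageStartupMessages(library(psmcea))
seed <- 20260928L

for (country in c("US", "China")) {
  out <- file.path("results", tolower(country))
  bundle <- run_pipeline(pipeline_config(country = country,
                                         analyses = "base",
                                         out_dir = out, seed = seed))
  cat("\n==", country, "synthetic base case ==\n")
  print(bundle$base_table, row.names = FALSE)
  print(bundle$ce)
  verdict <- if (isTRUE(bundle$ce$cost_effective)) "below" else "above"
  cat(sprintf("Synthetic ICER is %s the %s willingness-to-pay of $%s/QALY\n",
              verdict, country, format(bundle$params$wtp, big.mark = ",")))
}
cat("\nNote: each synthetic base case is one trial realization; at these",
    "sample sizes the realized arm separation varies noticeably between",
    "seeds (see the methods vignette).\n")

cat("\n== Worked example: published increments through the icer operation ==\n")
ref <- utils::read.csv(system.file("extdata", "reference_results.csv",
                                   package = "psmcea"))
strat <- function(cost, qaly)
  structure(list(cost = cost, qaly = qaly), class = "strategy_result")
ref$icer_recomputed <- round(vapply(seq_len(nrow(ref)), function(i)
  icer(strat(ref$dcost[i], ref$dqaly[i]), strat(0, 0))$icer, numeric(1)), 2)
ref$consistent <- abs(ref$icer_recomputed - ref$icer_published) < 0.05
print(ref, row.names = FALSE)
utils::write.csv(ref, "results/reference_icer_check.csv", row.names = FALSE)
cat("\nRows marked consistent=FALSE reflect two-decimal rounding of the",
    "published increments, not a computational difference.\n")
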