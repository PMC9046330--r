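#!/usr/bin/env Rscript
# Base-case cost-utility analysis: supervised exercise vs usual care for men
# on ADT, 3-year horizon, 3-month cycles, discounted at 5%/year. Writes the
# per-arm results table and full cohort traces.
suppressPackageStartupMessages(library(adtfalls))
dir.create("results", showWarnings = FALSE)

params <- load_parameters()
ctl <- run_cohort(params, "control")
int <- run_cohort(params, "intervention")
res <- compare_arms(ctl, int)
print(res)

outs <- c("results/base_case.csv", "results/trace_control.csv",
          "results/trace_intervention.csv")
write_result_csv(cua_table(res), outs[1])
write_result_csv(trace_table(ctl), outs[2])
write_result_csv(trace_table(int), outs[3])
write_manifest("results/base_case_manifest.txt", outs)

cat(sprintf("\nExercise dominates usual care: it saves $%.0f per patient and adds %.4f QALYs,\nfor an incremental net monetary benefit of $%.0f at $50,000/QALY.\n",
            -res$delta_cost, res$delta_qalys, res$inmb))
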