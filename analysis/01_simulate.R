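#!/usr/bin/env Rscript
# Generate the default two-cohort study (60 HIE + 35 CHD) and write the
# subject table, outcome table, per-subject connectome CSVs and the
# ground-truth record under results/cohort/.

library(neonconn)

seed <- 20110101
sim <- simulate_cohort(default_scenario(), seed = seed)
write_cohort_csv(sim, "results/cohort")

ge <- exp(sim$truth$log_global_efficiency)
hie <- sim$subjects$cohort == "HIE"
message(sprintf("simulated %d HIE + %d CHD subjects (seed %d)",
                sum(hie), sum(!hie), seed))
message(sprintf("mean global efficiency: HIE %.4f, CHD %.4f",
                mean(ge[hie]), mean(ge[!hie])))
message(sprintf("followup: %d at 12-18 months, %d at 30 months",
                sum(sim$outcomes$timepoint == "12-18 months"),
                sum(sim$outcomes$timepoint == "30 months")))
message("wrote results/cohort/")
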