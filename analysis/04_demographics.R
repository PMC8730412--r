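#!/usr/bin/env Rscript
# Cohort demographics and clinical characteristics with between-cohort
# rank-sum / Fisher tests.

library(neonconn)

seed <- 20110101
sim <- simulate_cohort(default_scenario(), seed = seed)
subj <- sim$subjects
subj$male <- subj$sex == "male"
tab <- demographics_table(subj,
                          continuous = c("ga_birth", "ga_mri", "birth_weight",
                                         "ph", "base_deficit", "apgar1",
                                         "apgar5", "snappe"),
                          binary = c("male", "injury_on_mri"))
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/demographics.csv", row.names = FALSE)
print(tab, row.names = FALSE)
message("wrote results/demographics.csv")
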