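#!/usr/bin/env Rscript
# Outcome protocol: univariate screen of clinical factors and log graph
# metrics against each Bayley-III domain at each timepoint, then one
# multivariate model per screened metric (GA at MRI forced in, GA at
# birth excluded), plus the 5 x 4 tract-outcome regression grid.
# This is the heart of the analysis; it reuses the all-in-one pipeline.

library(neonconn)

man <- run_pipeline(default_scenario(), seed = 20110101,
                    out_dir = "results/pipeline", n_perm = 5000, n_null = 100)

screen <- read.csv("results/pipeline/univariate_screen.csv")
sel <- unique(screen$predictor[screen$selected])
message("predictors passing the p < 0.1 screen in any model: ",
        paste(sel, collapse = ", "))

multi <- tryCatch(read.csv("results/pipeline/multivariate_models.csv"),
                  error = function(e) NULL)
if (!is.null(multi) && nrow(multi) > 0) {
  for (i in which(grepl("^log_", multi$term))) {
    message(sprintf("%s ~ %s: coef %.1f (%.1f-%.1f), p = %.3f",
                    multi$outcome[i], multi$term[i], multi$estimate[i],
                    multi$ci_low[i], multi$ci_high[i], multi$p[i]))
  }
} else {
  message("no graph metric passed the univariate screen in this run")
}

tr <- read.csv("results/pipeline/tract_regressions.csv")
message(sprintf("tract grid: %d cells (%d estimable)",
                nrow(tr), sum(tr$estimable)))
message("wrote results/pipeline/")
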