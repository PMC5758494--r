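#!/usr/bin/env Rscript
# Stage 4: validation summaries for the selected models — temporal
# (fit on census 1, test on new census-2 reports) and 5-fold
# cross-validation with the variogram parameters held at the full fit.

suppressPackageStartupMessages(library(aiskrige))

res <- run_pipeline(landscape_config(seed = 1), do_surface = FALSE)
cov <- res$covariates

report <- list()
for (sp in c("zm", "ewm")) {
  secs <- res$selection[[sp]]$secondaries
  tv <- res$validation[[sp]]
  cv <- kfold_cv(cov$t2, sp, secs, k = 5, seed = 11)
  report[[sp]] <- list(
    secondaries = secs,
    true_validation = list(auc = tv$auc, sens_at_3 = tv$sensitivity,
                           spec_at_3 = tv$specificity),
    kfold = list(k = cv$k, auc = cv$auc, sens_at_3 = cv$sensitivity,
                 spec_at_3 = cv$specificity)
  )
  cat(sprintf("%-3s (%s + %s)\n", sp, secs[1], secs[2]))
  cat(sprintf("  temporal validation: AUC %.3f, sens@3 %.2f, spec@3 %.2f\n",
              tv$auc, tv$sensitivity, tv$specificity))
  cat(sprintf("  5-fold CV:           AUC %.3f, sens@3 %.2f, spec@3 %.2f\n",
              cv$auc, cv$sensitivity, cv$specificity))
}

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(report, "results/validation.json",
                     auto_unbox = TRUE, digits = NA)
cat("written: results/validation.json\n")
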