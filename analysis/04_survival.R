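#!/usr/bin/env Rscript
# Recurrence-free survival stratified by half-life group: Kaplan-Meier
# curves, log-rank test and Cox models. Writes results/km.tsv and
# results/survival_models.tsv.

library(dcpkinetics)

report <- run_pipeline(read_cohort("results/cohort.csv"))

write.table(report$km, "results/km.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
for (g in unique(report$km$group)) {
  sd <- report$survival_data
  cat(sprintf("  %s HL group: n = %d, %d recurrences, S(12) = %.1f%%\n",
              g, sum(sd$group == g), sum(sd$event[sd$group == g]),
              100 * km_survival_at(report$km, 12, g)))
}
cat(sprintf("Log-rank: chi-square = %.2f, p %s\n",
            report$logrank$chi_square, format_p(report$logrank$p_value)))
for (i in seq_len(nrow(report$cox))) {
  r <- report$cox[i, ]
  cat(sprintf("Cox (%s) %s: HR %.2f (95%% CI %.2f-%.2f), p %s\n",
              r$analysis, r$term, r$hr, r$ci_low, r$ci_high,
              format_p(r$p_value)))
}

models <- data.frame(
  analysis = c("logrank", paste0("cox_", report$cox$analysis)),
  term = c("group", report$cox$term),
  estimate = c(report$logrank$chi_square, report$cox$hr),
  ci_low = c(NA, report$cox$ci_low),
  ci_high = c(NA, report$cox$ci_high),
  p = format_p(c(report$logrank$p_value, report$cox$p_value)))
write.table(models, "results/survival_models.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Wrote results/km.tsv, results/survival_models.tsv\n")
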