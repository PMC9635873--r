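#!/usr/bin/env Rscript
# Trial-by-trial effects analysis of the synthetic cohorts written by
# 03_generate_cohorts.R: the 2x2 repeated-measures ANOVAs (adaptation and
# Pavlovian effects) per phase, the binned dynamics of the two effects, the
# compound-probe Friedman analysis, the overshadowing correlation, and the
# pooled singleton-vs-compound ANOVA.

library(adaptcond)

coh1 <- read_trials("results/03_cohort_differential.csv")
coh4 <- read_trials("results/03_cohort_compound.csv")
pre1 <- preprocess_cohort(coh1)
pre4 <- preprocess_cohort(coh4)

sink("results/04_effects_log.txt", split = TRUE)

cat("== Differential conditioning cohort ==\n")
anova_rows <- list()
for (phase in c("acquisition", "probe")) {
  cells <- cohort_cells(pre1, phase)
  an <- rm_anova_2x2(cells)
  cat(sprintf("\n-- %s phase --\n", phase))
  print(an)
  for (eff in c("previous", "current", "interaction"))
    anova_rows[[length(anova_rows) + 1]] <- tibble::tibble(
      phase = phase, effect = eff, F = an[[eff]]$F, p = an[[eff]]$p,
      eta_p2 = an[[eff]]$eta_p2, mean_diff = an[[eff]]$mean_diff,
      ci_lo = an[[eff]]$ci95[1], ci_hi = an[[eff]]$ci95[2])
}
utils::write.csv(do.call(rbind, anova_rows), "results/04_anova.csv",
                 row.names = FALSE)

cat("\n-- dynamics of the two effects over 50-trial bins --\n")
dyn <- cohort_dynamics(pre1, bin_width = 50)
utils::write.csv(dyn$group_weights, "results/04_dynamics_weights.csv",
                 row.names = FALSE)
cat(sprintf("mean slope, Pavlovian (current) weight:  %+.4f per bin (p = %.3g)\n",
            mean(dyn$slopes$slope[dyn$slopes$term == "current"]),
            dyn$tests$current$p.value))
cat(sprintf("mean slope, adaptation (previous) weight: %+.4f per bin (p = %.3g)\n",
            mean(dyn$slopes$slope[dyn$slopes$term == "previous"]),
            dyn$tests$previous$p.value))
cat(sprintf("current vs previous slopes, paired t: p = %.3g\n",
            dyn$tests$current_vs_previous$p.value))

cat("\n\n== Compound conditioning cohort (probe phase) ==\n")
cp <- compound_probe_analysis(pre4)
cat(sprintf("Friedman chi-squared(%d) = %.2f, p = %.4f, Kendall W = %.3f\n",
            cp$friedman$df, cp$friedman$chisq, cp$friedman$p, cp$friedman$W))
cat("condition medians of the per-participant medians (deg):\n")
print(vapply(cp$medians[, c("compound", "tone", "light")], median,
             numeric(1)), digits = 2)
print(as.data.frame(cp$pairwise), digits = 3)
utils::write.csv(cp$medians, "results/04_compound_medians.csv",
                 row.names = FALSE)

el <- elemental_probe_means(pre4)
ov <- overshadow_correlation(el$tone, el$light)
cat(sprintf("\nOvershadowing (tone vs light probe response): r = %.2f, p = %.4g, n = %d\n",
            ov$r, ov$p, ov$n))

cat("\n-- pooled singleton vs compound ANOVA --\n")
print(pooled_singleton_anova(pre4))

sink()
cat("Wrote results/04_anova.csv, results/04_dynamics_weights.csv,",
    "results/04_compound_medians.csv, results/04_effects_log.txt\n")
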