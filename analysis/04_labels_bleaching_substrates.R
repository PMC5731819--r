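#!/usr/bin/env Rscript
# Labelling efficiency, stroboscopic bleach control, and the DNA-substrate
# null comparison.

library(cosmosim)
dir.create("results", showWarnings = FALSE)

cat("== Colocalization-based labelling efficiency (alpha / epsilon) ==\n")
set.seed(41)
n_ev <- 5000
alpha <- runif(n_ev) < 0.67
eps <- runif(n_ev) < 0.71
est <- estimate_label_efficiency(sum(alpha & eps), sum(alpha & !eps),
                                 sum(!alpha & eps))
cat(sprintf(
  "Recovered p_alpha = %.1f%% +/- %.1f, p_eps = %.1f%% +/- %.1f (installed 67 / 71).\n",
  100 * est$p_a, 100 * est$se_a, 100 * est$p_b, 100 * est$se_b))

cat("\n== Why long lifetimes need stroboscopic imaging ==\n")
s3 <- make_schedule(3)
for (dye in c(atto488 = 274.4, atto565 = 145.7, atto647N = 93.0)) {
  h <- calibrate_bleach_hazard(dye, s3)
  strobe <- apparent_bleach_lifetime(h, make_schedule(3,
                                                     interval_mode_period = 10))
  cat(sprintf(
    "  apparent bleach %.1f s continuous -> %.0f s with 10 s interval imaging (x%.1f)\n",
    dye, strobe, strobe / dye))
}
cat("A ~1430 s clamp lifetime is only measurable in interval mode.\n")

cat("\n== DNA substrate null: identical kinetics, different tags ==\n")
tags <- c("matched", "lesion", "mismatched")
runs <- lapply(seq_along(tags), function(i)
  run_scenario(scenario_config("dna_substrates", n_molecules = 400,
                               seed = 40 + i, substrate_tag = tags[i])))
out <- data.frame(
  substrate = tags,
  tau_pol3_s = sapply(runs, function(r) r$estimates[["tau_pol3"]]),
  sem_s = sapply(runs, function(r) r$sems[["tau_pol3"]]),
  pct_ab = sapply(runs, function(r) r$summary$pct_switch_ab),
  pct_ba = sapply(runs, function(r) r$summary$pct_switch_ba),
  pct_coloc = sapply(runs, function(r) r$summary$pct_coloc))
print(out, digits = 4)
for (i in 1:2) for (j in (i + 1):3) {
  z <- abs(out$tau_pol3_s[i] - out$tau_pol3_s[j]) /
    sqrt(out$sem_s[i]^2 + out$sem_s[j]^2)
  cat(sprintf("  %s vs %s: |z| = %.2f\n", tags[i], tags[j], z))
}
cat("The substrate tag never enters the generator; lifetimes and exchange\n")
cat("fractions agree within sampling error, the expected null.\n")
write.table(out, "results/substrate_null.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/substrate_null.tsv\n")
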