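#!/usr/bin/env Rscript
# Polymerase lifetimes on clamp-DNA and bare DNA.
#
# Recovers the replicative polymerase (Pol IIIcore) lifetime on clamp-DNA
# through the 3-colour pipeline, comparing the field's binned one-parameter
# exponential fit with the censored/frame-quantized MLE, raw and
# bleach-corrected; and the Pol I Klenow lifetime on bare DNA.

library(cosmosim)
dir.create("results", showWarnings = FALSE)

cat("== Pol IIIcore on clamp-DNA (3-colour, Atto 488 label) ==\n")
r3 <- run_scenario(scenario_config("pol3_lifetime", n_molecules = 1200,
                                   seed = 21))
print(r3$fits$histogram)
print(r3$fits$mle)
sched3 <- r3$schedule
tau_bleach <- apparent_bleach_lifetime(
  calibrate_bleach_hazard(274.4, make_schedule(3)), sched3)
corr_hist <- bleach_corrected_tau(r3$fits$histogram$tau, tau_bleach)
corr_mle <- bleach_corrected_tau(r3$fits$mle$tau, tau_bleach)
cat(sprintf(
  "Apparent lifetimes carry the fluorophore's bleach rate (apparent bleach %.0f s):\n",
  tau_bleach))
cat(sprintf("  histogram %.2f s raw -> %.2f s bleach-corrected\n",
            r3$fits$histogram$tau, corr_hist))
cat(sprintf("  MLE       %.2f s raw -> %.2f s bleach-corrected (installed 15.7 s)\n",
            r3$fits$mle$tau, corr_mle))

cat("\n== Pol I Klenow fragment on bare DNA (10 s stroboscopic imaging) ==\n")
r1 <- run_scenario(scenario_config("pol1_dna", n_molecules = 600, seed = 22))
print(r1)

out <- data.frame(
  species = c("pol3", "pol3", "pol3", "pol3", "pol1"),
  method = c("histogram_1p", "mle_quantized", "histogram_1p_corrected",
             "mle_quantized_corrected", "mle_quantized"),
  tau_s = c(r3$fits$histogram$tau, r3$fits$mle$tau, corr_hist, corr_mle,
            r1$estimates[["tau_pol1"]]),
  sem_s = c(r3$fits$histogram$tau_sem, r3$fits$mle$tau_sem, NA, NA,
            r1$sems[["tau_pol1"]]),
  installed_s = c(15.7, 15.7, 15.7, 15.7, 42.2),
  n_events = c(r3$fits$histogram$n_events, r3$fits$mle$n_events, NA, NA,
               r1$fits$mle$n_events))
write.table(out, "results/polymerase_lifetimes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/polymerase_lifetimes.tsv\n")
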