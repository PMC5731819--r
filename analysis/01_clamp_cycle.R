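#!/usr/bin/env Rscript
# Clamp-cycle kinetics: loading, ATPgS-arrested loading, and unloading.
#
# Simulates the three clamp-cycle experiments end to end (CTMC -> rendered
# traces -> interval detection -> event classification -> dwell fits) and
# checks that the installed rate constants are recovered through the full
# measurement chain.

library(cosmosim)
dir.create("results", showWarnings = FALSE)
ref <- reference_values()
n_mol <- 1200

cat("== Clamp loading (single-channel, 86 ms frames) ==\n")
r_load <- run_scenario(scenario_config("clamp_loading", n_molecules = n_mol,
                                       seed = 11))
print(r_load)
cat(sprintf("Loader departs alone; mean dwell %.3f s (installed 0.41 s).\n",
            r_load$estimates[["tau_loader"]]))

cat("\n== ATPgS: loader and clamp co-arrive and co-release (2-colour) ==\n")
r_atp <- run_scenario(scenario_config("clamp_loading_atpgs",
                                      n_molecules = n_mol, seed = 12))
print(r_atp)
cat(sprintf(
  "Co-release flagged in %.1f%% of uncensored loading events; complex dwell %.2f s (installed 2.7 s).\n",
  100 * r_atp$estimates[["frac_co_release"]],
  r_atp$estimates[["tau_complex"]]))

cat("\n== Clamp unloading (pre-loaded clamps, 2-colour) ==\n")
r_unl <- run_scenario(scenario_config("clamp_unloading", n_molecules = n_mol,
                                      seed = 13))
print(r_unl)
cat(sprintf(
  "Productive fraction %.2f (installed 0.47); arrival-to-release lag %.2f s (installed 4.1 s).\n",
  r_unl$estimates[["p_productive"]], r_unl$estimates[["release_lag"]]))

rec <- rbind(
  data.frame(experiment = "clamp_loading", r_load$recovery),
  data.frame(experiment = "clamp_loading_atpgs", r_atp$recovery),
  data.frame(experiment = "clamp_unloading", r_unl$recovery))
cmp <- compare_to_reference(
  rec, stats::setNames(ref[c("quantity", "value", "sem")],
                       c("quantity", "value", "sem")))
out <- cbind(rec, cmp[c("reference", "ref_sem", "z", "status")])
write.table(out, "results/clamp_cycle_recovery.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/clamp_cycle_recovery.tsv\n")
cat(sprintf("%d of %d compared quantities within 2 combined SE of the published values.\n",
            sum(out$status == "pass", na.rm = TRUE),
            sum(out$status != "untested", na.rm = TRUE)))
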