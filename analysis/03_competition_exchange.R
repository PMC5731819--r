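#!/usr/bin/env Rscript
# Replicative vs translesion polymerase exchange on clamp-DNA.
#
# Classifies switches and co-localizations between Pol IIIcore and Pol IV
# (independent two-groove co-occupancy), tests the independence model's
# predicted co-localization time, contrasts with the tau-complex (tethered)
# and mutual-exclusion (Pol II-like / groove-mutant) regimes.

library(cosmosim)
dir.create("results", showWarnings = FALSE)

cat("== Pol IIIcore vs Pol IV, 30/30 nM, independent co-occupancy ==\n")
rc <- run_scenario(scenario_config("polymerase_competition",
                                   n_molecules = 800, seed = 31))
print(rc$summary)
pred <- expected_coloc_duration(15.7, 14.2)
cat(sprintf(
  "Independence model predicts %.2f s co-localization; pipeline measures %.2f +/- %.2f s.\n",
  pred, rc$estimates[["coloc_duration"]], rc$sems[["coloc_duration"]]))
cat(sprintf("Measured lifetimes: Pol IIIcore %.2f s, Pol IV %.2f s (installed 15.7 / 14.2 s).\n",
            rc$estimates[["tau_pol3"]], rc$estimates[["tau_pol4"]]))

cat("\n== tau-complex: Pol IIIcore tethered to the loader ==\n")
# Tethered re-delivery keeps the replicative polymerase bound for most of
# the movie; at such occupancy threshold detection loses its background, so
# this regime is classified from ground-truth intervals (per molecule).
sch_t <- build_scheme("tau_complex")
sched_t <- make_schedule(3)
traj_t <- simulate_trajectories(sch_t, 500, sched_t$duration, seed = 32)
a_t <- true_intervals(traj_t, sched_t, "pol3", 1)
b_t <- true_intervals(traj_t, sched_t, "pol4", 2)
rt <- classify_exchange(a_t, b_t, sched_t$cycle_period, c("pol3", "pol4"),
                        per_molecule = TRUE)
print(rt$summary)
first_a <- with(rt$events, ifelse(kind == "switch",
                                  direction == "pol3->pol4",
                                  first_in == "pol3"))
cat(sprintf(
  "Tethering re-delivers Pol IIIcore after release: %.1f%% of molecules' first exchange starts from Pol IIIcore.\n",
  100 * mean(first_a)))

cat("\n== Groove mutant: short-lived Pol IV, strict exclusion ==\n")
rg <- run_scenario(scenario_config("groove_mutants", n_molecules = 500,
                                   seed = 33))
print(rg$summary)
cat(sprintf("Groove-mutant Pol IV lifetime %.2f s (installed 2.7 s); no co-occupancy by construction -> %.1f%% co-localization.\n",
            rg$estimates[["tau_pol4"]], rg$summary$pct_coloc))

grab <- function(r, tag) data.frame(
  scenario = tag,
  n_pairs = r$summary$n_pairs,
  pct_ab = r$summary$pct_switch_ab, pct_ba = r$summary$pct_switch_ba,
  pct_coloc = r$summary$pct_coloc,
  lag_ab_s = r$summary$lag_ab_mean, lag_ab_sem = r$summary$lag_ab_sem,
  coloc_s = r$summary$coloc_duration_mean,
  coloc_sem = r$summary$coloc_duration_sem)
out <- rbind(grab(rc, "competition_30_30"), grab(rt, "tau_complex"),
             grab(rg, "pol4_groove_mutant"))
write.table(out, "results/exchange_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/exchange_summary.tsv\n")
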