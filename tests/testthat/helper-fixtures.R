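# Shared fixtures: small schemes and generators used across test files.

# one-species binding scheme with tunable rates
one_species_scheme <- function(koff, k_arr = 1) {
  build_scheme("pol3_on_clamp",
               list(koff = koff, kon_per_conc = k_arr, conc = 1))
}

# pool of complete (untruncated) bound dwells from a one-species scheme
simulated_dwells <- function(koff, n_target, seed, k_arr = 1) {
  sch <- one_species_scheme(koff, k_arr)
  # expected events per unit time ~ 1 / (1/k_arr + 1/koff)
  per_mol_t <- 400 / koff
  n_mol <- ceiling(n_target * (1 / k_arr + 1 / koff) / per_mol_t * 1.3)
  traj <- simulate_trajectories(sch, n_mol, per_mol_t, seed = seed)
  ev <- species_intervals(traj, "pol3")
  dw <- (ev$t_end - ev$t_start)[ev$t_end < per_mol_t & ev$t_start > 0]
  dw
}

# frame counts from ideal phase-uniform sampling of exponential dwells
sampled_frame_counts <- function(n, tau, period, seed) {
  set.seed(seed)
  u <- stats::runif(n, 0, period)
  t <- stats::rexp(n, 1 / tau)
  k <- floor((u + t) / period)
  k[k >= 1]
}

# build an interval-table row in the detect_intervals_set layout
iv_row <- function(molecule_id, channel, start, end, n_frames = 1000,
                   period = 1, right_censored = end >= n_frames) {
  data.frame(molecule_id = molecule_id, channel = channel,
             start_frame = start, end_frame = end,
             start_time = (start - 1) * period,
             end_time = (end - 1) * period,
             dwell = (end - start + 1) * period,
             left_censored = start <= 1, right_censored = right_censored)
}
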