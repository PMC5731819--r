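# Event classification: co-arrival, loading, unloading, exchange,
# label-efficiency estimation and lag statistics.

test_that("co-arrival means starting within one frame across channels", {
  a <- iv_row(1, 1, 100, 120)
  expect_true(classify_coarrival(a, iv_row(1, 2, 100, 300)))
  expect_true(classify_coarrival(a, iv_row(1, 2, 101, 300)))
  expect_true(classify_coarrival(iv_row(1, 2, 101, 300), a))  # symmetric
  expect_false(classify_coarrival(a, iv_row(1, 2, 102, 300)))
  expect_error(classify_coarrival(a, iv_row(1, 1, 100, 300)), "different")
})

test_that("loading events record dwell, persistence and co-release", {
  ld <- iv_row(1, 1, 10, 12, period = 0.086)
  cl <- iv_row(1, 2, 10, 900, n_frames = 900, period = 0.086)  # censored
  ev <- classify_loading(ld, cl, period = 0.086)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$loader_dwell, 3 * 0.086)
  expect_true(ev$clamp_persists)
  expect_false(ev$co_release)
  # ATPgS-like co-departure within one frame
  ev2 <- classify_loading(iv_row(1, 1, 10, 14), iv_row(1, 2, 11, 15),
                          period = 0.44)
  expect_true(ev2$co_release)
  expect_false(ev2$clamp_persists)
  # no co-arrival, no loading event
  ev3 <- classify_loading(iv_row(1, 1, 50, 55), iv_row(1, 2, 10, 900),
                          period = 0.44)
  expect_equal(nrow(ev3), 0L)
})

test_that("unloading classification separates productive, nonproductive and
           solo encounters", {
  p <- 0.44
  cl <- iv_row(1, 2, 1, 107)
  ld <- iv_row(1, 1, 101, 117)
  ev <- classify_unloading(ld, cl, p)
  expect_equal(ev$kind, "unloading_productive")
  expect_equal(ev$lag, 6 * p)
  cl2 <- iv_row(1, 2, 1, 900, n_frames = 900)
  ev2 <- classify_unloading(iv_row(1, 1, 101, 105), cl2, p)
  expect_equal(ev2$kind, "unloading_nonproductive")
  expect_true(is.na(ev2$lag))
  ev3 <- classify_unloading(iv_row(1, 1, 101, 105),
                            iv_row(1, 2, 300, 400), p)
  expect_equal(ev3$kind, "solo")
})

test_that("unloading branch probability is recovered from classified
           encounters", {
  # ground-truth intervals: >= 2000 loader encounters with a visible clamp
  sch <- build_scheme("clamp_unloading")
  sched <- make_schedule(2, n_frames = 1000)
  traj <- simulate_trajectories(sch, 1300, sched$duration, seed = 61)
  ld <- true_intervals(traj, sched, "loader", 1)
  cl <- true_intervals(traj, sched, "clamp", 2)
  ev <- classify_unloading(ld, cl, sched$cycle_period)
  unl <- ev[ev$kind != "solo", ]
  expect_gt(nrow(unl), 2000)
  p_hat <- mean(unl$kind == "unloading_productive")
  expect_lt(abs(p_hat - 0.47), 3 * sqrt(0.47 * 0.53 / nrow(unl)) + 0.01)
  # the full pipeline (labels, bleaching, noise) stays consistent
  rep <- run_scenario(scenario_config("clamp_unloading", n_molecules = 700,
                                      seed = 61))
  p_pipe <- rep$estimates[["p_productive"]]
  expect_lt(abs(p_pipe - 0.47), 3 * rep$sems[["p_productive"]] + 0.03)
})

test_that("switches and co-localizations are classified with the stated
           lags and durations", {
  p <- 0.66
  a <- iv_row(1, 1, 10, 40); b <- iv_row(1, 2, 45, 60)
  out <- classify_exchange(a, b, p, species = c("III", "IV"))
  expect_equal(out$events$kind, "switch")
  expect_equal(out$events$direction, "III->IV")
  expect_equal(out$events$lag, 4 * p)
  b2 <- iv_row(1, 2, 30, 60)
  out2 <- classify_exchange(a, b2, p, species = c("III", "IV"))
  expect_equal(out2$events$kind, "colocalization")
  expect_equal(out2$events$duration, 11 * p)
  expect_equal(out2$events$first_in, "III")
  expect_equal(out2$events$first_out, "III")
  # partition: the same pair is never both switch and colocalization
  expect_equal(nrow(out2$events), 1L)
  expect_equal(out2$summary$pct_coloc, 100)
})

test_that("exchange percentages partition classified pairs and sum to 100", {
  set.seed(77)
  sch <- build_scheme("competition",
                      list(kon_a = 1 / 40, conc_a = 1, koff_a = 1 / 6,
                           kon_b = 1 / 40, conc_b = 1, koff_b = 1 / 6))
  sched <- make_schedule(2, n_frames = 1000)
  traj <- simulate_trajectories(sch, 150, sched$duration, seed = 78)
  a <- true_intervals(traj, sched, "pol3", 1)
  b <- true_intervals(traj, sched, "pol4", 2)
  out <- classify_exchange(a, b, sched$cycle_period, c("A", "B"))
  s <- out$summary
  expect_equal(s$pct_switch_ab + s$pct_switch_ba + s$pct_coloc, 100)
  expect_equal(s$n_switch_ab + s$n_switch_ba + s$n_coloc, s$n_pairs)
  # symmetric generator: A-first and B-first switches split evenly
  se <- sqrt(0.25 / (s$n_switch_ab + s$n_switch_ba))
  expect_lt(abs(s$n_switch_ab / (s$n_switch_ab + s$n_switch_ba) - 0.5),
            3 * se)
})

test_that("switch lag recovers the partner's arrival rate", {
  # single replicative visit, then the partner arrives at rate 1/20.3
  sch <- build_scheme("competition",
                      list(kon_a = 0, conc_a = 0, koff_a = 1 / 15.7,
                           kon_b = 1 / 20.3, conc_b = 1, koff_b = 1 / 14.2,
                           initial_bound_a = TRUE))
  sched <- make_schedule(2, n_frames = 1000)   # 440 s movie
  traj <- simulate_trajectories(sch, 1200, sched$duration, seed = 81)
  a <- true_intervals(traj, sched, "pol3", 1)
  b <- true_intervals(traj, sched, "pol4", 2)
  out <- classify_exchange(a, b, sched$cycle_period, c("III", "IV"))
  ls <- lag_statistics(out$events, "switch", direction = "III->IV")
  expect_gt(ls$n, 400)
  expect_lt(abs(ls$mean - 20.3), 2 * ls$sem + 0.5)
})

test_that("first-in and first-out species are independent under independent
           co-occupancy", {
  sig <- vapply(1:10, function(s) {
    sch <- build_scheme("competition",
                        list(kon_a = 1 / 25, conc_a = 1, koff_a = 1 / 8,
                             kon_b = 1 / 25, conc_b = 1, koff_b = 1 / 8))
    sched <- make_schedule(2, n_frames = 800)
    traj <- simulate_trajectories(sch, 120, sched$duration, seed = 400 + s)
    a <- true_intervals(traj, sched, "pol3", 1)
    b <- true_intervals(traj, sched, "pol4", 2)
    ev <- classify_exchange(a, b, sched$cycle_period)$events
    co <- ev[ev$kind == "colocalization" & ev$first_in != "tie" &
               ev$first_out != "tie", ]
    tab <- table(co$first_in, co$first_out)
    if (any(dim(tab) < 2) || sum(tab) < 50) return(NA)
    suppressWarnings(stats::chisq.test(tab)$p.value) < 0.01
  }, TRUE)
  sig <- sig[!is.na(sig)]
  expect_gte(mean(!sig), 0.9)   # non-significant in (almost) all seeds
})

test_that("tau-complex tethering makes the replicative polymerase first in
           nearly every molecule's first event", {
  sch <- build_scheme("tau_complex")
  sched <- make_schedule(3, n_frames = 1000)
  traj <- simulate_trajectories(sch, 250, sched$duration, seed = 91)
  a <- true_intervals(traj, sched, "pol3", 1)
  b <- true_intervals(traj, sched, "pol4", 2)
  out <- classify_exchange(a, b, sched$cycle_period, c("III", "IV"),
                           per_molecule = TRUE)
  ev <- out$events
  first_is_a <- ifelse(ev$kind == "switch",
                       ev$direction == "III->IV", ev$first_in == "III")
  expect_gt(mean(first_is_a), 0.9)
})

test_that("label efficiency estimator is exact on counts and consistent in
           simulation", {
  est <- estimate_label_efficiency(100, 50, 50)
  expect_equal(est$p_a, 2 / 3, tolerance = 1e-12)
  expect_equal(est$p_b, 2 / 3, tolerance = 1e-12)
  perf <- estimate_label_efficiency(250, 0, 0)
  expect_equal(perf$p_a, 1.0)
  expect_equal(perf$p_b, 1.0)
  expect_error(estimate_label_efficiency(0, 10, 0), "denominator")
  # consistency: independent label draws, doubly-dark events discarded
  set.seed(101)
  p_alpha <- 0.67; p_eps <- 0.71
  alpha <- runif(5000) < p_alpha
  eps <- runif(5000) < p_eps
  visible <- alpha | eps
  est2 <- estimate_label_efficiency(sum(alpha & eps & visible),
                                    sum(alpha & !eps),
                                    sum(!alpha & eps))
  expect_lt(abs(est2$p_a - p_alpha), 2 * est2$se_a)
  expect_lt(abs(est2$p_b - p_eps), 2 * est2$se_b)
})

test_that("lag statistics: mean, sem, empty selection and bias correction", {
  ev <- data.frame(kind = "switch", lag = c(2, 4, 6), censored = FALSE)
  ls <- lag_statistics(ev, "switch")
  expect_equal(ls$mean, 4.0)
  expect_equal(ls$sem, sd(c(2, 4, 6)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(ls$sem, 3), 1.155)
  empty <- lag_statistics(ev[0, ], "switch")
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
  cens <- data.frame(kind = "switch", lag = c(2, 4, 6), censored = TRUE)
  expect_equal(lag_statistics(cens, "switch")$n, 0L)
  shifted <- lag_statistics(ev, "switch", bias_correction = 0.44)
  expect_equal(shifted$mean, 4.44)
})
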