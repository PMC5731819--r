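# Acquisition schedules, trace rendering, labelling and photobleaching.

test_that("schedule arithmetic matches the published frame rates", {
  s3 <- make_schedule(3, 0.050, 0.220, 1000)
  expect_equal(s3$cycle_period, 0.660)
  expect_equal(s3$duration, 660)
  s2 <- make_schedule(2, 0.050, 0.220, 1000)
  expect_equal(s2$cycle_period, 0.440)
  s1 <- make_schedule(1, 0.050, 0.086, 1000)
  expect_equal(s1$cycle_period, 0.086)
  si <- make_schedule(1, 0.050, 0.086, 140, interval_mode_period = 10)
  expect_equal(sample_times(si, 1)[1:3], c(0, 10, 20))
  expect_error(make_schedule(1, exposure = 0.1, per_frame_period = 0.05),
               "exposure")
  expect_error(make_schedule(4), "n_channels")
})

test_that("sample times equal frame x cycle period + channel offset exactly", {
  for (nc in 1:3) {
    sch <- make_schedule(nc, n_frames = 50)
    for (ch in seq_len(nc)) {
      expect_identical(sample_times(sch, ch),
                       (0:49) * sch$cycle_period +
                         (ch - 1) * sch$per_frame_period)
    }
  }
})

test_that("empty trajectories render as background plus noise only", {
  sch <- build_scheme("pol3_on_clamp", list(kon_per_conc = 0, conc = 1))
  traj <- simulate_trajectories(sch, 5, 66, seed = 1)
  sched <- make_schedule(1, n_frames = 100, per_frame_period = 0.66)
  tr <- render_traces(traj, sched, label_model("pol3", 1, 1), seed = 2)
  expect_equal(mean(tr$intensity), 100, tolerance = 0.05)
  expect_lt(max(abs(tr$intensity - 100)), 60)   # pure noise, no 120-step
})

test_that("noiseless full-label rendering is an exact step function of
           occupancy", {
  sch <- one_species_scheme(koff = 1 / 5, k_arr = 1 / 10)
  traj <- simulate_trajectories(sch, 20, 200, seed = 8)
  sched <- make_schedule(1, n_frames = 500, per_frame_period = 0.4)
  lm <- label_model("pol3", 1, p_label = 1, brightness = 100,
                    background = 0, noise_sd = 0)
  tr <- render_traces(traj, sched, lm, seed = 3)
  ti <- true_intervals(traj, sched, "pol3", 1)
  for (m in unique(tr$molecule_id)) {
    x <- tr$intensity[tr$molecule_id == m]
    expected <- reconstruct_trace(ti[ti$molecule_id == m, ], 500, 100)
    expect_identical(x, expected)
  }
})

test_that("label thinning hides the expected fraction of events", {
  p <- 0.6
  sch <- one_species_scheme(koff = 1 / 4, k_arr = 1 / 30)
  traj <- simulate_trajectories(sch, 90, 400, seed = 13)
  sched <- make_schedule(1, n_frames = 1000, per_frame_period = 0.4)
  lm <- label_model("pol3", 1, p_label = p, noise_sd = 0, background = 0)
  tr <- render_traces(traj, sched, lm, seed = 5)
  iv <- detect_intervals_set(tr, detection_params(high = 1, low = 0.5,
                                                  max_gap = 0), sched)
  ti <- true_intervals(traj, sched, "pol3", 1)
  # detection on noise-free traces is exact, so the visible fraction is the
  # labelled fraction of events that cover at least one sample
  frac <- nrow(iv) / nrow(ti)
  se <- sqrt(p * (1 - p) / nrow(ti))
  expect_lt(abs(frac - p), 3 * se)
})

test_that("bleach hazard calibration inverts the duty-cycle relation", {
  s3 <- make_schedule(3)
  h <- calibrate_bleach_hazard(93.0, s3)
  expect_equal(1 / h, 93.0 * 0.050 / 0.660, tolerance = 1e-12)  # ~7.05 s lit
  expect_equal(apparent_bleach_lifetime(h, s3), 93.0)
  # same hazard on a 10 s stroboscopic schedule: ~15x longer apparent life
  si <- make_schedule(3, interval_mode_period = 10)
  expect_equal(apparent_bleach_lifetime(h, si), 93.0 * 10 / 0.660,
               tolerance = 1e-9)
  expect_equal(calibrate_bleach_hazard(Inf, s3), 0)
  expect_equal(apparent_bleach_lifetime(0, s3), Inf)
  expect_error(calibrate_bleach_hazard(-3, s3), "positive")
})

test_that("simulated apparent bleaching matches the calibrated lifetime", {
  # always-bound fluorophore: apparent on-time is set purely by bleaching
  sch <- build_scheme("pol3_on_clamp",
                      list(kon_per_conc = 1e6, conc = 1, koff = 0))
  sched <- make_schedule(1, n_frames = 800, per_frame_period = 0.4)
  tau_app <- 40   # well inside the 320 s movie
  h <- calibrate_bleach_hazard(tau_app, sched)
  traj <- simulate_trajectories(sch, 400, sched$duration, seed = 31)
  lm <- label_model("pol3", 1, 1)
  tr <- render_traces(traj, sched, lm, bleach_model("pol3", h), seed = 32)
  iv <- detect_intervals_set(tr, detection_params(), sched)
  iv <- iv[!iv$right_censored, ]
  expect_gt(nrow(iv), 300)
  se <- sd(iv$dwell) / sqrt(nrow(iv))
  expect_lt(abs(mean(iv$dwell) - tau_app), 3 * se + 2 * sched$cycle_period)
})

test_that("bleach censoring composes rates: 1/tau_app = 1/tau + 1/tau_b", {
  tau <- 3; tau_b <- 6
  sched <- make_schedule(1, n_frames = 1000)
  h <- calibrate_bleach_hazard(tau_b, sched)
  sch <- one_species_scheme(koff = 1 / tau, k_arr = 1 / 5)
  traj <- simulate_trajectories(sch, 620, sched$duration, seed = 17)
  lm <- label_model("pol3", 1, 1)
  tr <- render_traces(traj, sched, lm, bleach_model("pol3", h), seed = 18)
  iv <- detect_intervals_set(tr, detection_params(), sched)
  iv <- iv[!iv$left_censored, ]
  expect_gt(nrow(iv), 5000)
  fit <- fit_exponential_mle(iv$dwell, iv$right_censored,
                             frame_quantization = sched$cycle_period)
  # the fluorophore still emits during the frame it bleaches in, extending
  # the effective bleach lifetime by about half a cycle
  pred <- 1 / (1 / tau + 1 / (tau_b + sched$cycle_period / 2))
  expect_lt(abs(fit$tau - pred), 2 * fit$tau_sem + 0.02 * pred)
})

test_that("apparent fluorophore lifetime scales with the inverse duty
           cycle", {
  # same hazard, two schedules: continuous vs 10x sparser interval mode
  h <- 0.5
  cont <- make_schedule(1, n_frames = 2000, per_frame_period = 0.2)
  strob <- make_schedule(1, n_frames = 2000, per_frame_period = 0.2,
                         interval_mode_period = 2)
  ratio_pred <- (strob$cycle_period / cont$cycle_period)
  sch <- build_scheme("pol3_on_clamp",
                      list(kon_per_conc = 1e6, conc = 1, koff = 0))
  lm <- label_model("pol3", 1, 1)
  get_mean_on <- function(sched, seed) {
    traj <- simulate_trajectories(sch, 250, sched$duration, seed = seed)
    tr <- render_traces(traj, sched, lm, bleach_model("pol3", h),
                        seed = seed + 1)
    iv <- detect_intervals_set(tr, detection_params(), sched)
    mean(iv$dwell[!iv$right_censored])
  }
  m1 <- get_mean_on(cont, 41)
  m2 <- get_mean_on(strob, 43)
  expect_equal(m2 / m1, ratio_pred, tolerance = 0.15)
})

test_that("traces round-trip through delimited text", {
  sch <- one_species_scheme(1 / 3, 1 / 5)
  sched <- make_schedule(1, n_frames = 50)
  traj <- simulate_trajectories(sch, 3, sched$duration, seed = 1)
  tr <- render_traces(traj, sched, label_model("pol3", 1, 1), seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_traces(tr, f)
  back <- read_traces(f, schedule = sched)
  expect_equal(back$intensity, tr$intensity, tolerance = 1e-9)
  expect_s3_class(back, "trace_set")
  unlink(f)
})
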