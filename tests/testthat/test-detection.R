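# Interval detection from intensity traces.

test_that("flat background-only trace yields no intervals", {
  set.seed(2)
  x <- rnorm(500, 100, 10)
  iv <- detect_intervals(x, period = 0.66)
  expect_equal(nrow(iv), 0L)
})

test_that("a noiseless step is recovered exactly with its dwell", {
  x <- rep(0, 500); x[100:150] <- 50
  iv <- detect_intervals(x, period = 0.66)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start_frame, 100L)
  expect_equal(iv$end_frame, 150L)
  expect_equal(iv$dwell, 51 * 0.66)
  expect_false(iv$left_censored)
  expect_false(iv$right_censored)
})

test_that("events at SNR >= 5 are recovered with endpoints within 1 frame", {
  set.seed(33)
  n_events <- 0; n_good <- 0
  for (rep in 1:50) {
    x <- rnorm(1000, 0, 1)
    # 20 well-separated events of 3-8 frames at amplitude 5 (SNR 5)
    starts <- seq(10, 950, by = 48)
    lens <- sample(3:8, length(starts), replace = TRUE)
    for (i in seq_along(starts))
      x[starts[i]:(starts[i] + lens[i] - 1)] <- x[starts[i]:(starts[i] + lens[i] - 1)] + 5
    iv <- detect_intervals(x, period = 1)
    for (i in seq_along(starts)) {
      n_events <- n_events + 1
      hit <- which(abs(iv$start_frame - starts[i]) <= 1 &
                     abs(iv$end_frame - (starts[i] + lens[i] - 1)) <= 1)
      if (length(hit)) n_good <- n_good + 1
    }
  }
  expect_gte(n_good / n_events, 0.99)
})

test_that("detection is idempotent through reconstruction", {
  set.seed(4)
  x <- rnorm(800, 0, 1)
  for (s in c(50, 300, 600)) x[s:(s + 20)] <- x[s:(s + 20)] + 10
  iv <- detect_intervals(x, period = 1)
  x2 <- reconstruct_trace(iv, 800, 10)
  iv2 <- detect_intervals(x2, period = 1)
  expect_equal(iv2$start_frame, iv$start_frame)
  expect_equal(iv2$end_frame, iv$end_frame)
})

test_that("raising the minimum event length never increases the count", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(600, 0, 1)
    for (s in sample(20:560, 12)) x[s:(s + sample(0:8, 1))] <- 8
    counts <- vapply(1:6, function(ml)
      nrow(detect_intervals(x, 1, detection_params(min_length = ml))),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("on noise-free traces detection equals ground truth sampled at
           schedule times", {
  sch <- one_species_scheme(koff = 1 / 5, k_arr = 1 / 12)
  sched <- make_schedule(2, n_frames = 700)
  traj <- simulate_trajectories(sch, 40, sched$duration, seed = 19)
  lm <- label_model("pol3", 2, p_label = 1, brightness = 80,
                    background = 0, noise_sd = 0)
  tr <- render_traces(traj, sched, lm, seed = 20)
  iv <- suppressWarnings(
    detect_intervals_set(tr, detection_params(high = 1, low = 0.5,
                                              max_gap = 0), sched,
                         background = "global"))
  iv <- iv[iv$channel == 2, ]
  rownames(iv) <- NULL
  ti <- true_intervals(traj, sched, "pol3", channel = 2)
  # ground-truth events separated by less than one frame merge at sampling
  # resolution; collapse them the same way before comparing
  merged <- do.call(rbind, lapply(split(ti, ti$molecule_id), function(d) {
    d <- d[order(d$start_frame), ]
    grp <- cumsum(c(0, as.integer(d$start_frame[-1] >
                                    d$end_frame[-nrow(d)] + 1)))
    data.frame(molecule_id = d$molecule_id[1],
               start_frame = tapply(d$start_frame, grp, min),
               end_frame = tapply(d$end_frame, grp, max))
  }))
  expect_equal(nrow(iv), nrow(merged))
  expect_equal(iv$start_frame, as.integer(merged$start_frame))
  expect_equal(iv$end_frame, as.integer(merged$end_frame))
})

test_that("censoring flags match ground-truth truncation at the movie ends", {
  sch <- one_species_scheme(koff = 1 / 30, k_arr = 1 / 60)
  sched <- make_schedule(1, n_frames = 600, per_frame_period = 0.2)
  traj <- simulate_trajectories(sch, 60, sched$duration, seed = 23)
  lm <- label_model("pol3", 1, 1, background = 0, noise_sd = 0)
  tr <- render_traces(traj, sched, lm, seed = 24)
  iv <- detect_intervals_set(tr, detection_params(high = 1, low = 0.5,
                                                  max_gap = 0), sched,
                             background = "global")
  ti <- true_intervals(traj, sched, "pol3", channel = 1)
  expect_equal(sum(iv$right_censored), sum(ti$right_censored))
  expect_equal(sum(iv$left_censored), sum(ti$left_censored))
})

test_that("right-censoring frequency follows the exponential survival
           function", {
  tau <- 20
  sch <- one_species_scheme(koff = 1 / tau, k_arr = 1 / 40)
  sched <- make_schedule(1, n_frames = 500, per_frame_period = 0.2)  # 100 s
  lm <- label_model("pol3", 1, 1, background = 0, noise_sd = 0)
  obs <- 0; pred <- 0; var_pred <- 0
  for (s in 1:4) {
    traj <- simulate_trajectories(sch, 150, sched$duration, seed = 28 + s)
    tr <- render_traces(traj, sched, lm, seed = 130 + s)
    iv <- detect_intervals_set(tr, detection_params(high = 1, low = 0.5),
                               sched, background = "global")
    ev <- species_intervals(traj, "pol3")
    ev <- ev[ev$t_start > 0, ]
    # per-event censor probability given its start: exp(-(T - t_start)/tau)
    p <- exp(-(sched$duration - ev$t_start) / tau)
    obs <- obs + sum(iv$right_censored)
    pred <- pred + sum(p)
    var_pred <- var_pred + sum(p * (1 - p))
  }
  expect_lt(abs(obs - pred), 2 * sqrt(var_pred) + 3)
})

test_that("a constant trace warns and returns one doubly-censored interval", {
  expect_warning(iv <- detect_intervals(rep(5, 100), 1), "constant")
  expect_equal(nrow(iv), 1L)
  expect_true(iv$left_censored && iv$right_censored)
  expect_true(isTRUE(attr(iv, "degenerate")))
})

test_that("global background detection survives near-full occupancy", {
  # one molecule occupied for 90% of the movie among sparse ones
  set.seed(55)
  mk <- function(m, occ_frames) {
    x <- rnorm(400, 100, 10)
    if (length(occ_frames)) x[occ_frames] <- x[occ_frames] + 120
    data.frame(molecule_id = m, channel = 1, frame = 1:400,
               time_s = (0:399) * 0.44, intensity = x)
  }
  df <- rbind(mk(1, 10:370), mk(2, 50:60), mk(3, integer(0)))
  tr <- structure(df, schedule = make_schedule(2, n_frames = 400),
                  class = c("trace_set", "data.frame"))
  per <- detect_intervals_set(tr, background = "per_trace")
  glob <- detect_intervals_set(tr, background = "global")
  expect_false(any(per$molecule_id == 1 & per$end_frame >= 360))
  expect_true(any(glob$molecule_id == 1 & glob$start_frame == 10 &
                    glob$end_frame == 370))
})
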