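# Named end-to-end scenarios: kinetics -> acquisition -> detection ->
# events -> dwell statistics, with every recovered value paired to the
# generating truth.

# Apparent on-DNA fluorophore lifetimes (s) measured under the standard
# 3-colour continuous schedule; hazards are calibrated against that schedule
# and re-used on whatever schedule a scenario runs.
.dye_lifetimes <- c(atto488 = 274.4, atto565 = 145.7, atto647N = 93.0)

.dye_hazard <- function(dye) {
  calibrate_bleach_hazard(.dye_lifetimes[[dye]], make_schedule(3))
}

scenario_presets <- function() {
  kon <- .default_kon
  list(
    pol3_lifetime = list(
      description = "Pol IIIcore exchanging on loaded clamp-DNA (3-colour)",
      scheme_preset = "pol3_on_clamp",
      rates = list(koff = 1 / 15.7, conc = 30, kon_per_conc = kon),
      schedule = list(n_channels = 3),
      labels = data.frame(species = "pol3", channel = 1, p_label = 0.60,
                          dye = "atto488"),
      analysis = list(type = "dwell", species = "pol3",
                      truth = c(tau_pol3 = 15.7))),
    pol1_dna = list(
      description = "Pol I Klenow fragment on bare DNA (stroboscopic)",
      scheme_preset = "pol1_dna",
      # 5 nM and 10 s interval imaging: a ~42 s lifetime on an Atto 647N
      # label is unmeasurable under continuous illumination (bleach-limited)
      rates = list(koff = 1 / 42.2, conc = 5, kon_per_conc = kon),
      schedule = list(n_channels = 1, n_frames = 200,
                      interval_mode_period = 10),
      labels = data.frame(species = "pol1", channel = 1, p_label = 1.0,
                          dye = "atto647N"),
      # with 10 s between frames a one-frame gap is a real absence, not a
      # dropout: never bridge gaps in interval mode
      detection = detection_params(max_gap = 0),
      analysis = list(type = "dwell", species = "pol1",
                      truth = c(tau_pol1 = 42.2))),
    clamp_loading = list(
      description = "Clamp loading; loader dwell on clamp-DNA (single colour)",
      scheme_preset = "clamp_loading",
      rates = list(loader_koff = 1 / 0.41, conc = 15, kon_per_conc = kon),
      schedule = list(n_channels = 1),
      labels = data.frame(species = "loader", channel = 1, p_label = 0.85,
                          dye = "atto565"),
      # the dwell estimate is dominated by single-frame events, so the entry
      # threshold is raised to keep noise spikes far below that event class
      detection = detection_params(high = 5),
      analysis = list(type = "dwell", species = "loader",
                      truth = c(tau_loader = 0.41))),
    clamp_loading_atpgs = list(
      description = "ATPgS: loader+clamp co-arrive and co-depart (2-colour)",
      scheme_preset = "clamp_loading_atpgs",
      rates = list(complex_koff = 1 / 2.7, conc = 15, kon_per_conc = kon),
      schedule = list(n_channels = 2),
      labels = data.frame(species = c("loader", "clamp"), channel = c(1, 2),
                          p_label = c(0.85, 0.68),
                          dye = c("atto565", "atto647N")),
      analysis = list(type = "atpgs", truth = c(tau_complex = 2.7))),
    clamp_unloading = list(
      description = "Loader encounters pre-loaded clamps; unloading (2-colour)",
      scheme_preset = "clamp_unloading",
      rates = list(p_productive = 0.47, release_rate = 1 / 4.1,
                   loader_total_dwell = 10.8, nonproductive_koff = 1 / 2.5,
                   conc = 15, kon_per_conc = kon),
      schedule = list(n_channels = 2),
      labels = data.frame(species = c("loader", "clamp"), channel = c(1, 2),
                          p_label = c(0.85, 0.68),
                          dye = c("atto565", "atto647N")),
      # pre-loaded clamps can stay bound for most of the movie: pool the
      # background statistics over the whole channel
      background = "global",
      analysis = list(type = "unloading",
                      truth = c(release_lag = 4.1, p_productive = 0.47,
                                tau_loader_total = 10.8))),
    polymerase_competition = list(
      description = "Pol IIIcore vs Pol IV competing on clamp-DNA (3-colour)",
      scheme_preset = "competition",
      rates = list(species_a = "pol3", species_b = "pol4",
                   kon_a = kon, conc_a = 30, koff_a = 1 / 15.7,
                   kon_b = kon, conc_b = 30, koff_b = 1 / 14.2,
                   mutual_exclusion = FALSE),
      schedule = list(n_channels = 3),
      labels = data.frame(species = c("pol3", "pol4"), channel = c(1, 2),
                          p_label = c(0.60, 0.62),
                          dye = c("atto488", "atto565")),
      analysis = list(type = "exchange", species = c("pol3", "pol4"),
                      truth = c(tau_pol3 = 15.7, tau_pol4 = 14.2,
                                coloc_duration =
                                  expected_coloc_duration(15.7, 14.2)))),
    tau_complex = list(
      description = "tau-complex tethers Pol IIIcore; Pol IV competes",
      scheme_preset = "tau_complex",
      rates = list(tether_rate = 1 / 11.3, koff_a = 1 / 14.8,
                   kon_b = kon, conc_b = 30, koff_b = 1 / 14.2),
      schedule = list(n_channels = 3),
      labels = data.frame(species = c("pol3", "pol4"), channel = c(1, 2),
                          p_label = c(0.60, 0.62),
                          dye = c("atto488", "atto565")),
      analysis = list(type = "exchange", species = c("pol3", "pol4"),
                      truth = c(tau_pol3 = 14.8, tau_pol4 = 14.2))),
    groove_mutants = list(
      description = "Clamp-groove/rim mutant competition (variant-driven)",
      scheme_preset = "competition",
      rates = list(species_a = "pol3", species_b = "pol4",
                   kon_a = kon, conc_a = 30, koff_a = 1 / 15.7,
                   kon_b = kon, conc_b = 90, koff_b = 1 / 2.7,
                   mutual_exclusion = TRUE),
      schedule = list(n_channels = 3),
      labels = data.frame(species = c("pol3", "pol4"), channel = c(1, 2),
                          p_label = c(0.60, 0.62),
                          dye = c("atto488", "atto565")),
      analysis = list(type = "exchange", species = c("pol3", "pol4"),
                      truth = c(tau_pol3 = 15.7, tau_pol4 = 2.7))),
    dna_substrates = list(
      description = "Identical kinetics tagged matched/lesion/mismatched",
      scheme_preset = "competition",
      rates = list(species_a = "pol3", species_b = "pol4",
                   kon_a = kon, conc_a = 30, koff_a = 1 / 15.7,
                   kon_b = kon, conc_b = 30, koff_b = 1 / 14.2,
                   mutual_exclusion = FALSE),
      schedule = list(n_channels = 3),
      labels = data.frame(species = c("pol3", "pol4"), channel = c(1, 2),
                          p_label = c(0.60, 0.62),
                          dye = c("atto488", "atto565")),
      analysis = list(type = "exchange", species = c("pol3", "pol4"),
                      truth = c(tau_pol3 = 15.7, tau_pol4 = 14.2)))
  )
}

#' Build a scenario configuration
#'
#' A scenario bundles everything a run needs: the kinetic scheme and its
#' rates, the acquisition schedule, the label and bleach models, detection
#' parameters, the analysis to perform, molecule count and seed. A run is
#' reproducible bit-for-bit from config + seed. Presets:
#' `pol3_lifetime`, `pol1_dna`, `clamp_loading`, `clamp_loading_atpgs`,
#' `clamp_unloading`, `polymerase_competition`, `tau_complex`,
#' `groove_mutants`, `dna_substrates`.
#'
#' @param preset Preset name.
#' @param n_molecules Number of DNA molecules (default 2000).
#' @param seed Integer seed.
#' @param rates Named list merged over the preset's kinetic rates.
#' @param schedule Named list merged over the preset's schedule arguments
#'   (passed to [make_schedule()]).
#' @param detection A [detection_params()]; `NULL` uses the preset's own
#'   default.
#' @param substrate_tag Free-text tag carried into the report (used by the
#'   DNA-substrate null comparison; never enters the generator).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(preset, n_molecules = 2000, seed = 1,
                            rates = list(), schedule = list(),
                            detection = NULL, substrate_tag = NULL) {
  presets <- scenario_presets()
  if (!preset %in% names(presets))
    stop(sprintf("unknown scenario preset '%s'; available: %s", preset,
                 paste(names(presets), collapse = ", ")))
  cfg <- presets[[preset]]
  cfg$preset <- preset
  cfg$rates[names(rates)] <- rates
  cfg$schedule[names(schedule)] <- schedule
  cfg$n_molecules <- n_molecules
  cfg$seed <- as.integer(seed)
  if (!is.null(detection)) cfg$detection <- detection
  if (is.null(cfg$detection)) cfg$detection <- detection_params()
  cfg$substrate_tag <- substrate_tag
  structure(cfg, class = "scenario_config")
}

#' Write / read a scenario config as YAML
#' @param config A `scenario_config`.
#' @param path File path.
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  x$detection <- unclass(x$detection)
  x$labels <- as.list(x$labels)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_config(x$preset, n_molecules = x$n_molecules, seed = x$seed,
                  rates = x$rates[setdiff(names(x$rates), character(0))],
                  schedule = x$schedule,
                  detection = do.call(detection_params, x$detection),
                  substrate_tag = x$substrate_tag)
}

build_label_models <- function(cfg, schedule) {
  lm <- label_model(cfg$labels$species, cfg$labels$channel,
                    cfg$labels$p_label)
  bm <- bleach_model(cfg$labels$species,
                     vapply(cfg$labels$dye, .dye_hazard, numeric(1)))
  list(labels = lm, bleach = bm)
}

#' Run a scenario end to end
#'
#' Simulates the configured kinetic scheme for `n_molecules` molecules,
#' renders traces under the configured schedule/label/bleach models, detects
#' binding intervals, classifies events, and fits dwell distributions. Every
#' recovered quantity is paired with the generating truth.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional directory; when given, the trajectories, traces,
#'   intervals and recovery table are written there as delimited text.
#' @param verbose Log stage progress to stderr.
#' @return A `scenario_report`: list with `config`, `fits` (list of
#'   `exp_fit`), `events`/`summary` where applicable, counts, and `recovery`
#'   (data.frame `quantity, truth, estimate, sem`).
#' @export
run_scenario <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  sched <- do.call(make_schedule, config$schedule)
  scheme <- build_scheme(config$scheme_preset, config$rates)
  say("scenario %s: %d molecules, %.0f s movie", config$preset,
      config$n_molecules, sched$duration)
  traj <- simulate_trajectories(scheme, config$n_molecules, sched$duration,
                                seed = config$seed)
  mods <- build_label_models(config, sched)
  traces <- render_traces(traj, sched, mods$labels, mods$bleach)
  # channel background statistics are shared across a field of view, and
  # pooling them keeps detection stable on molecules whose occupancy
  # approaches or exceeds 50% of the movie
  bg <- if (is.null(config$background)) "global" else config$background
  intervals <- detect_intervals_set(traces, config$detection, sched,
                                    background = bg)
  say("  %d intervals detected", nrow(intervals))
  ch_of <- stats::setNames(config$labels$channel, config$labels$species)
  iv_of <- function(sp) intervals[intervals$channel == ch_of[[sp]], ,
                                  drop = FALSE]
  period <- sched$cycle_period
  an <- config$analysis
  fits <- list(); events <- NULL; summary <- NULL
  est <- c(); sem <- c()

  complete <- function(iv) iv[!iv$right_censored & !iv$left_censored, ,
                              drop = FALSE]
  if (an$type == "dwell") {
    sp <- an$species
    # histogram method: complete dwells only (what a histogram can contain);
    # MLE: right-censored events contribute survival terms, avoiding the
    # length bias of dropping events that outlast the movie
    iv_h <- complete(iv_of(sp))
    iv <- iv_of(sp); iv <- iv[!iv$left_censored, , drop = FALSE]
    fits$histogram <- fit_exponential_histogram(iv_h$dwell,
                                                frame_period = period)
    fits$mle <- fit_exponential_mle(iv$dwell, iv$right_censored,
                                    frame_quantization = period)
    est[paste0("tau_", sp)] <- fits$mle$tau
    sem[paste0("tau_", sp)] <- fits$mle$tau_sem
    est[paste0("tau_", sp, "_histogram")] <- fits$histogram$tau
    sem[paste0("tau_", sp, "_histogram")] <- fits$histogram$tau_sem
  } else if (an$type == "atpgs") {
    events <- classify_loading(iv_of("loader"), iv_of("clamp"), period)
    co <- events[events$co_release & !events$censored, , drop = FALSE]
    fits$mle <- fit_exponential_mle(co$loader_dwell,
                                    frame_quantization = period)
    est["tau_complex"] <- fits$mle$tau
    sem["tau_complex"] <- fits$mle$tau_sem
    est["frac_co_release"] <- mean(events$co_release[!events$censored])
  } else if (an$type == "unloading") {
    events <- classify_unloading(iv_of("loader"), iv_of("clamp"), period)
    unl <- events[events$kind != "solo", , drop = FALSE]
    est["p_productive"] <- mean(unl$kind == "unloading_productive")
    sem["p_productive"] <- sqrt(est[["p_productive"]] *
                                  (1 - est[["p_productive"]]) / nrow(unl))
    # release rounds down and arrival rounds up on the frame grid (+1 cycle),
    # and the two species are read on different channel offsets within the
    # cycle, which shifts cross-channel frame differences by the offset gap
    off <- sched$channel_offsets
    corr <- period + (off[ch_of[["clamp"]]] - off[ch_of[["loader"]]])
    ls <- lag_statistics(events, "unloading_productive",
                         bias_correction = corr)
    est["release_lag"] <- ls$mean
    sem["release_lag"] <- ls$sem
    pr <- unl[unl$kind == "unloading_productive", , drop = FALSE]
    if (nrow(pr) >= 10) {
      fits$loader_total <- fit_exponential_mle(pr$loader_dwell, pr$censored,
                                               frame_quantization = period)
      est["tau_loader_total"] <- fits$loader_total$tau
      sem["tau_loader_total"] <- fits$loader_total$tau_sem
    }
  } else if (an$type == "exchange") {
    sp <- an$species
    cls <- classify_exchange(iv_of(sp[1]), iv_of(sp[2]), period,
                             species = sp)
    events <- cls$events; summary <- cls$summary
    for (s in sp) {
      iv <- iv_of(s); iv <- iv[!iv$left_censored, , drop = FALSE]
      if (nrow(iv) >= 10) {
        f <- fit_exponential_mle(iv$dwell, iv$right_censored,
                                 frame_quantization = period)
        fits[[s]] <- f
        est[paste0("tau_", s)] <- f$tau
        sem[paste0("tau_", s)] <- f$tau_sem
      }
    }
    if (!is.null(summary$coloc_duration_mean) &&
        !is.na(summary$coloc_duration_mean)) {
      est["coloc_duration"] <- summary$coloc_duration_mean
      sem["coloc_duration"] <- summary$coloc_duration_sem
    }
    est["pct_switch_ab"] <- summary$pct_switch_ab
    est["pct_switch_ba"] <- summary$pct_switch_ba
    est["pct_coloc"] <- summary$pct_coloc
    ls <- lag_statistics(events, "switch",
                         direction = paste0(sp[1], "->", sp[2]))
    est["lag_ab"] <- ls$mean; sem["lag_ab"] <- ls$sem
  } else stop("unknown analysis type: ", an$type)

  truth <- an$truth
  rec <- data.frame(quantity = names(truth), truth = as.numeric(truth),
                    estimate = unname(est[match(names(truth), names(est))]),
                    sem = unname(sem[match(names(truth), names(sem))]))
  rownames(rec) <- NULL
  report <- structure(list(config = config, schedule = sched,
                           scheme = scheme, fits = fits, events = events,
                           summary = summary, estimates = est, sems = sem,
                           n_intervals = nrow(intervals),
                           recovery = rec,
                           runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs"))),
                      class = "scenario_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectories(traj, file.path(out_dir, "trajectories.tsv"))
    write_intervals(intervals, file.path(out_dir, "intervals.tsv"))
    utils::write.table(rec, file.path(out_dir, "recovery.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_scenario_config(config, file.path(out_dir, "config.yaml"))
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d molecules, seed %d, %.1f s):\n",
              x$config$preset, x$config$n_molecules, x$config$seed,
              x$runtime_s))
  print(x$recovery, digits = 4)
  invisible(x)
}

#' Compare recovered values with a reference table
#'
#' Computes z-scores of recovered vs reference using the combined standard
#' error and flags each row pass (`|z| <= z_max`), fail, or untested (no
#' matching reference row or missing uncertainty).
#'
#' @param recovery data.frame with `quantity, estimate, sem` (e.g. a
#'   `scenario_report$recovery`, or rows built by hand).
#' @param reference data.frame with `quantity, value, sem`.
#' @param z_max Pass threshold on `|z|` (default 2).
#' @return data.frame `quantity, estimate, sem, reference, ref_sem, z,
#'   status`.
#' @export
compare_to_reference <- function(recovery, reference, z_max = 2) {
  i <- match(recovery$quantity, reference$quantity)
  ref <- reference$value[i]
  ref_sem <- reference$sem[i]
  comb <- sqrt(ifelse(is.na(recovery$sem), 0, recovery$sem^2) +
                 ifelse(is.na(ref_sem), 0, ref_sem^2))
  z <- (recovery$estimate - ref) / comb
  status <- ifelse(is.na(ref) | !is.finite(z), "untested",
                   ifelse(abs(z) <= z_max, "pass", "fail"))
  data.frame(quantity = recovery$quantity, estimate = recovery$estimate,
             sem = recovery$sem, reference = ref, ref_sem = ref_sem,
             z = z, status = status)
}

#' Published reference values bundled with the package
#'
#' Reads the transcription of published single-molecule lifetimes, lags and
#' event fractions for the clamp / polymerase system shipped under
#' `inst/extdata/reference_values.csv` (clearly marked as a transcription of
#' published measurements, with one row per printed value).
#'
#' @return data.frame `experiment, quantity, value, sem, units`.
#' @export
reference_values <- function() {
  path <- system.file("extdata", "reference_values.csv",
                      package = "cosmosim")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
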