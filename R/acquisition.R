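# Forward model of interleaved multi-channel TIRF acquisition: sampling
# schedule, fluorophore labelling, photobleaching and detection noise.

#' Acquisition schedule
#'
#' Describes the camera/laser timing of a CoSMoS movie. In continuous mode
#' the lasers alternate between channels, so each channel is sampled once per
#' cycle of `n_channels * per_frame_period` seconds (660 ms for 3 colours,
#' 440 ms for 2, 86 ms for 1). In interval (stroboscopic) mode the whole
#' cycle is repeated every `interval_mode_period` seconds, with long dark
#' gaps that reduce cumulative photobleaching.
#'
#' @param n_channels Number of colour channels, 1-3.
#' @param exposure Exposure per frame, s (default 0.050).
#' @param per_frame_period Time per frame including channel switching, s.
#'   Defaults to 0.086 for a single channel and 0.220 otherwise.
#' @param n_frames Frames per channel (default 1000).
#' @param interval_mode_period Optional cycle period for stroboscopic
#'   imaging, s (e.g. 10); must exceed `n_channels * per_frame_period`.
#' @return An `acq_schedule` with fields `cycle_period` (per-channel sampling
#'   period), `channel_offsets` (start of each channel's exposure within a
#'   cycle) and `duration` (total movie length).
#' @examples
#' make_schedule(3)                       # 0.66 s per channel, 660 s movie
#' make_schedule(1)                       # 86 ms frames
#' make_schedule(1, interval_mode_period = 10)  # samples at 0, 10, 20, ... s
#' @export
make_schedule <- function(n_channels, exposure = 0.050,
                          per_frame_period = if (n_channels == 1) 0.086
                                             else 0.220,
                          n_frames = 1000, interval_mode_period = NULL) {
  if (!n_channels %in% 1:3)
    stop("make_schedule: n_channels must be 1, 2 or 3")
  if (exposure > per_frame_period)
    stop("make_schedule: exposure cannot exceed per_frame_period")
  base_cycle <- n_channels * per_frame_period
  cycle <- if (is.null(interval_mode_period)) base_cycle
           else interval_mode_period
  if (cycle < base_cycle)
    stop("make_schedule: interval_mode_period shorter than one channel sweep")
  offsets <- (seq_len(n_channels) - 1) * per_frame_period
  structure(list(n_channels = n_channels,
                 exposure = exposure,
                 per_frame_period = per_frame_period,
                 n_frames = as.integer(n_frames),
                 interval_mode = !is.null(interval_mode_period),
                 cycle_period = cycle,
                 channel_offsets = offsets,
                 duration = n_frames * cycle),
            class = "acq_schedule")
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf(paste0("Acquisition schedule: %d channel(s), %g s exposure, ",
                     "%g s per-channel period%s, %d frames (%g s total)\n"),
              x$n_channels, x$exposure, x$cycle_period,
              if (x$interval_mode) " (interval mode)" else "",
              x$n_frames, x$duration))
  invisible(x)
}

#' Sample times of one channel
#' @param schedule An `acq_schedule`.
#' @param channel Channel index (1-based).
#' @return Numeric vector of length `n_frames`: exposure start times, with
#'   `time = (frame - 1) * cycle_period + channel_offset`.
#' @export
sample_times <- function(schedule, channel) {
  stopifnot(inherits(schedule, "acq_schedule"),
            channel >= 1, channel <= schedule$n_channels)
  (seq_len(schedule$n_frames) - 1) * schedule$cycle_period +
    schedule$channel_offsets[channel]
}

#' Calibrate a photobleaching hazard from an apparent on-DNA lifetime
#'
#' Bleaching accrues only while the fluorophore's channel is illuminated
#' (one `exposure` per cycle), so a hazard `h` per second of illumination
#' produces an apparent real-time lifetime of `1 / (h * duty)` where
#' `duty = exposure / cycle_period`. Inverting, the mean illuminated time to
#' bleach equals `apparent_lifetime * duty`. The same hazard evaluated on a
#' sparser (interval-mode) schedule yields a proportionally longer apparent
#' lifetime — the reason long-lifetime measurements use stroboscopic imaging.
#'
#' @param apparent_lifetime Measured apparent on-DNA lifetime, s (> 0;
#'   `Inf` gives hazard 0).
#' @param schedule The `acq_schedule` under which it was measured.
#' @return Bleach hazard in 1/s of illumination.
#' @examples
#' sch3 <- make_schedule(3)
#' h <- calibrate_bleach_hazard(93.0, sch3)   # mean illuminated time ~7.05 s
#' apparent_bleach_lifetime(h, make_schedule(1, interval_mode_period = 10))
#' @export
calibrate_bleach_hazard <- function(apparent_lifetime, schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  if (schedule$exposure <= 0) stop("schedule has zero exposure")
  if (is.na(apparent_lifetime) || apparent_lifetime <= 0)
    stop("apparent_lifetime must be positive")
  if (is.infinite(apparent_lifetime)) return(0)
  duty <- schedule$exposure / schedule$cycle_period
  1 / (apparent_lifetime * duty)
}

#' @rdname calibrate_bleach_hazard
#' @param hazard Bleach hazard, 1/s of illumination.
#' @return `apparent_bleach_lifetime`: expected apparent lifetime (s) of the
#'   fluorophore under `schedule` at that hazard.
#' @export
apparent_bleach_lifetime <- function(hazard, schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  if (hazard < 0) stop("hazard must be >= 0")
  if (hazard == 0) return(Inf)
  duty <- schedule$exposure / schedule$cycle_period
  1 / (hazard * duty)
}

#' Label model: which species fluoresce, where, and how brightly
#'
#' @param species Character vector of species names.
#' @param channel Integer channel per species.
#' @param p_label Labelling probability per species (fraction of molecules in
#'   solution carrying an active fluorophore); drawn once per binding
#'   arrival, since each arrival is a fresh molecule from solution.
#' @param brightness Mean fluorophore intensity above background, a.u.
#' @param background Per-channel background level, a.u.
#' @param noise_sd Per-channel Gaussian noise SD, a.u.
#' @return A `label_model`.
#' @export
label_model <- function(species, channel, p_label = 1,
                        brightness = 120, background = 100, noise_sd = 10) {
  n <- length(species)
  tab <- data.frame(species = species,
                    channel = as.integer(rep_len(channel, n)),
                    p_label = rep_len(p_label, n),
                    brightness = rep_len(brightness, n),
                    stringsAsFactors = FALSE)
  if (any(tab$p_label < 0 | tab$p_label > 1))
    stop("label_model: p_label must lie in [0, 1]")
  structure(list(table = tab, background = background, noise_sd = noise_sd),
            class = "label_model")
}

#' Bleach model: per-species fluorophore bleaching hazards
#' @param species Character vector of species names.
#' @param hazard Bleach hazard per second of illumination, per species
#'   (0 = photostable).
#' @return A `bleach_model`.
#' @export
bleach_model <- function(species = character(0), hazard = numeric(0)) {
  h <- stats::setNames(rep_len(as.numeric(hazard), length(species)), species)
  if (any(h < 0)) stop("bleach_model: hazards must be >= 0")
  structure(list(hazard = h), class = "bleach_model")
}

#' Render fluorescence traces from ground-truth trajectories
#'
#' Forward model of the observed per-molecule intensity time series:
#' `intensity = background + sum(bound, labelled, unbleached brightness)
#' + Gaussian noise`, evaluated at each channel's sample times. Each binding
#' arrival draws its label Bernoulli(`p_label`) afresh; a labelled
#' fluorophore bleaches after an exponential amount of *illuminated* time
#' (hazard from `bleach_model`), accrued only during its own channel's
#' exposures while bound.
#'
#' @param trajectories A `trajectory_set`.
#' @param schedule An `acq_schedule`.
#' @param labels A [label_model()]; species absent from it are dark.
#' @param bleach A [bleach_model()] (default: no bleaching).
#' @param seed Optional integer seed.
#' @return A `trace_set`: data.frame `molecule_id, channel, frame, time_s,
#'   intensity` with the schedule attached as attribute `schedule`.
#' @export
render_traces <- function(trajectories, schedule, labels,
                          bleach = bleach_model(), seed = NULL) {
  stopifnot(inherits(schedule, "acq_schedule"),
            inherits(labels, "label_model"),
            inherits(bleach, "bleach_model"))
  if (!is.null(seed)) set.seed(seed)
  occ <- attr(trajectories, "occupancy")
  traj_sp <- unique(unlist(occ, use.names = FALSE))
  lab <- labels$table
  unassigned <- setdiff(traj_sp, lab$species)
  # dark species are fine; a labelled species must map to a valid channel
  if (any(lab$channel < 1 | lab$channel > schedule$n_channels))
    stop("render_traces: label channel outside the schedule's channels")

  mols <- unique(trajectories$molecule_id)
  nm <- length(mols)
  nf <- schedule$n_frames
  nc <- schedule$n_channels
  # intensity array [frame, channel, molecule]
  inten <- array(0, dim = c(nf, nc, nm))
  tms <- vapply(seq_len(nc), function(ch) sample_times(schedule, ch),
                numeric(nf))
  events <- species_intervals(trajectories,
                              intersect(lab$species, traj_sp))
  if (nrow(events)) {
    ch_of <- stats::setNames(lab$channel, lab$species)
    p_of <- stats::setNames(lab$p_label, lab$species)
    br_of <- stats::setNames(lab$brightness, lab$species)
    labelled <- stats::runif(nrow(events)) < p_of[events$species]
    hz <- bleach$hazard[events$species]
    hz[is.na(hz)] <- 0
    # illuminated time to bleach, per labelled fluorophore
    t_bleach <- ifelse(hz > 0, stats::rexp(nrow(events), pmax(hz, 1e-300)),
                       Inf)
    mrow <- match(events$molecule_id, mols)
    for (i in seq_len(nrow(events))) {
      if (!labelled[i]) next
      ch <- ch_of[[events$species[i]]]
      tt <- tms[, ch]
      j <- which(tt >= events$t_start[i] & tt < events$t_end[i])
      if (!length(j)) next
      # bleached once cumulative illumination at exposure start reaches
      # the fluorophore's budget
      n_emit <- min(length(j), floor(t_bleach[i] / schedule$exposure) + 1)
      j <- j[seq_len(n_emit)]
      inten[j, ch, mrow[i]] <- inten[j, ch, mrow[i]] + br_of[[events$species[i]]]
    }
  }
  bg <- rep_len(labels$background, nc)
  sdn <- rep_len(labels$noise_sd, nc)
  for (ch in seq_len(nc)) {
    noise <- if (sdn[ch] > 0) stats::rnorm(nf * nm, 0, sdn[ch]) else 0
    inten[, ch, ] <- inten[, ch, ] + bg[ch] + noise
  }
  out <- data.frame(
    molecule_id = rep(mols, each = nf * nc),
    channel = rep(rep(seq_len(nc), each = nf), times = nm),
    frame = rep.int(seq_len(nf), nc * nm),
    time_s = rep(as.vector(tms), times = nm),
    intensity = as.vector(inten))
  structure(out, schedule = schedule,
            class = c("trace_set", "data.frame"))
}

#' Write / read a trace set as delimited text
#'
#' Long format, tab-separated: `molecule_id, channel, frame, time_s,
#' intensity`. `read_traces()` reattaches a schedule if given.
#' @param traces A `trace_set`.
#' @param path File path.
#' @param schedule Optional `acq_schedule` to attach on read.
#' @export
write_traces <- function(traces, path) {
  utils::write.table(as.data.frame(traces), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, schedule = NULL) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(out, schedule = schedule,
            class = c("trace_set", "data.frame"))
}
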