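# Detection of binding intervals from intensity traces: robust background
# estimation, hysteresis thresholding, gap bridging and censoring flags.

#' Detection parameters
#'
#' Hysteresis thresholding in units of the per-trace background SD: an event
#' is seeded wherever the intensity exceeds `high` SDs above the background
#' median and extended while it stays above `low`. Gaps of at most
#' `max_gap` frames between accepted runs are bridged (a one-frame dropout of
#' a bound fluorophore should not split an event), and runs shorter than
#' `min_length` frames are discarded. These are analysis settings, not
#' published values; all are overridable.
#'
#' @param high,low Entry/exit thresholds in background-SD units
#'   (`high >= low > 0`).
#' @param max_gap Maximum bridgeable gap, frames (>= 0).
#' @param min_length Minimum event length, frames (>= 1).
#' @return A `detection_params`.
#' @export
detection_params <- function(high = 4, low = 2, max_gap = 1, min_length = 1) {
  if (!(high >= low && low > 0)) stop("need high >= low > 0")
  if (max_gap < 0 || min_length < 1) stop("need max_gap >= 0, min_length >= 1")
  structure(list(high = high, low = low, max_gap = as.integer(max_gap),
                 min_length = as.integer(min_length)),
            class = "detection_params")
}

#' Detect binding intervals in one intensity trace
#'
#' The trace background is estimated robustly (median/MAD, which tolerates
#' occupancy well above 50%); maximal runs above threshold become intervals.
#' Hysteresis: a run must reach `high` SDs somewhere but extends over all
#' contiguous frames above `low`. Runs separated by at most `max_gap` frames
#' are joined, then runs shorter than `min_length` are dropped. Intervals
#' touching the first/last frame are flagged left-/right-censored. The dwell
#' of an n-frame run is `n * period`: a sub-frame event appears as a
#' single-frame event with dwell one period.
#'
#' @param intensity Numeric vector of intensities, one per frame (>= 2).
#' @param period Per-channel sampling period, s (one frame = one period).
#' @param params A [detection_params()].
#' @param background Optional `c(center, scale)` overriding the per-trace
#'   median/MAD background estimate — e.g. statistics pooled over a whole
#'   channel, which stay valid when a single molecule is occupied for most
#'   of the movie.
#' @return data.frame `start_frame, end_frame, start_time, end_time, dwell,
#'   left_censored, right_censored` (frames 1-based, inclusive;
#'   `start_time = (start_frame - 1) * period`). A constant or all-saturated
#'   trace yields a single doubly-censored full-length interval with
#'   attribute `degenerate = TRUE`.
#' @export
detect_intervals <- function(intensity, period, params = detection_params(),
                             background = NULL) {
  n <- length(intensity)
  if (n < 2) stop("detect_intervals: need at least 2 samples")
  if (!is.null(background)) {
    med <- background[1]; s <- background[2]
  } else {
    med <- stats::median(intensity)
    s <- stats::mad(intensity)
    if (s > 0) {
      # refine on the background population: frames within 3 SD of the
      # median, so moderate occupancy does not inflate the noise estimate
      bg <- intensity <= med + 3 * s
      med <- stats::median(intensity[bg])
      s2 <- stats::mad(intensity[bg])
      if (s2 > 0) s <- s2
      else if (stats::sd(intensity[bg]) > 0) s <- stats::sd(intensity[bg])
    }
  }
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      dwell = numeric(0), left_censored = logical(0),
                      right_censored = logical(0))
  if (s == 0) {
    if (stats::var(intensity) == 0) {
      # flat at the (known) background level: a genuinely empty trace
      if (!is.null(background) && intensity[1] == med) return(empty)
      warning("constant trace: returning one doubly-censored interval")
      out <- interval_rows(1L, n, n, period)
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    # noiseless background: any deviation from it is signal
    s <- 1e-8 * diff(range(intensity))
  }
  z <- (intensity - med) / s
  above <- z >= params$low
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # hysteresis: keep runs that reach the high threshold
  reach <- vapply(seq_len(nrow(runs)), function(i)
    any(z[runs$start[i]:runs$end[i]] >= params$high), TRUE)
  runs <- runs[reach, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  # bridge short gaps between consecutive accepted runs
  if (nrow(runs) > 1 && params$max_gap > 0) {
    gap <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > params$max_gap)))
    runs <- data.frame(
      start = tapply(runs$start, grp, min),
      end = tapply(runs$end, grp, max))
  }
  len <- runs$end - runs$start + 1L
  runs <- runs[len >= params$min_length, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  interval_rows(as.integer(runs$start), as.integer(runs$end), n, period)
}

interval_rows <- function(start, end, n_frames, period) {
  data.frame(start_frame = start, end_frame = end,
             start_time = (start - 1) * period,
             end_time = (end - 1) * period,
             dwell = (end - start + 1) * period,
             left_censored = start == 1L,
             right_censored = end == n_frames)
}

#' Detect intervals in every trace of a trace set
#'
#' Applies [detect_intervals()] per molecule and channel.
#'
#' @param traces A `trace_set` from [render_traces()] (or [read_traces()]
#'   with a schedule attached).
#' @param params A [detection_params()].
#' @param schedule Optional `acq_schedule`; defaults to the one attached to
#'   `traces`.
#' @param background `"per_trace"` (median/MAD of each trace) or `"global"`
#'   (median/MAD pooled per channel over all molecules — robust when single
#'   molecules can be occupied for most of the movie, e.g. a pre-loaded
#'   clamp channel).
#' @return data.frame `molecule_id, channel, start_frame, end_frame,
#'   start_time, end_time, dwell, left_censored, right_censored`.
#' @export
detect_intervals_set <- function(traces, params = detection_params(),
                                 schedule = attr(traces, "schedule"),
                                 background = c("per_trace", "global")) {
  background <- match.arg(background)
  if (is.null(schedule)) stop("no acquisition schedule available")
  period <- schedule$cycle_period
  df <- as.data.frame(traces)
  df <- df[order(df$molecule_id, df$channel, df$frame), ]
  bg_by_channel <- NULL
  if (background == "global") {
    bg_by_channel <- lapply(split(df$intensity, df$channel), function(x)
      c(stats::median(x), stats::mad(x)))
  }
  key <- interaction(df$molecule_id, df$channel, drop = TRUE)
  pieces <- lapply(split(df, key), function(d) {
    bg <- if (is.null(bg_by_channel)) NULL else
      bg_by_channel[[as.character(d$channel[1])]]
    iv <- detect_intervals(d$intensity, period, params, background = bg)
    if (!nrow(iv)) return(NULL)
    cbind(molecule_id = d$molecule_id[1], channel = d$channel[1], iv)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces))
    return(data.frame(molecule_id = integer(0), channel = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      dwell = numeric(0), left_censored = logical(0),
                      right_censored = logical(0)))
  out <- do.call(rbind, pieces)
  out <- out[order(out$molecule_id, out$channel, out$start_frame), ]
  rownames(out) <- NULL
  out
}

#' Write an interval table as delimited text
#' @param intervals data.frame from [detect_intervals_set()].
#' @param path File path.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Reconstruct a binary occupancy trace from intervals
#'
#' Inverse of detection on a noiseless trace; useful for idempotence checks.
#' @param intervals data.frame with `start_frame`, `end_frame`.
#' @param n_frames Trace length.
#' @param amplitude On-level added above zero baseline.
#' @return Numeric vector of length `n_frames`.
#' @export
reconstruct_trace <- function(intervals, n_frames, amplitude = 1) {
  x <- numeric(n_frames)
  for (i in seq_len(nrow(intervals)))
    x[intervals$start_frame[i]:intervals$end_frame[i]] <- amplitude
  x
}
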