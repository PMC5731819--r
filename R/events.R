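# Interval algebra: co-arrival, loading, unloading, polymerase switching,
# co-localization, lag statistics and the colocalization-based labelling
# efficiency estimator.
#
# Under sequential channel acquisition, "simultaneous" means starting in the
# same or adjacent frames; the same one-frame tolerance is applied to
# co-departure.

.coarrival_tol <- 1L

#' Are two intervals co-arriving?
#'
#' Two binding events on different channels of the same molecule co-arrive
#' when their start frames differ by at most one frame — the operational
#' definition of simultaneity when the laser channels are sampled
#' sequentially.
#'
#' @param interval_a,interval_b Single-row interval data.frames (from
#'   [detect_intervals_set()]) with at least `channel` and `start_frame`.
#' @return Logical. Symmetric in its arguments.
#' @export
classify_coarrival <- function(interval_a, interval_b) {
  if (interval_a$channel[1] == interval_b$channel[1])
    stop("co-arrival is defined between different channels")
  abs(interval_a$start_frame[1] - interval_b$start_frame[1]) <= .coarrival_tol
}

#' Classify clamp-loading events
#'
#' A loading event is a co-arriving loader + clamp pair. Each event records
#' the loader dwell, whether the clamp persists after the loader departs,
#' and whether loader and clamp co-depart (end frames within one frame —
#' the ATPgS-like signature where release requires no hydrolysis).
#'
#' @param loader_intervals,clamp_intervals Interval tables for the two
#'   channels (columns as from [detect_intervals_set()]).
#' @param period Per-channel sampling period, s.
#' @return data.frame of event records: `kind = "loading"`, `molecule_id`,
#'   `loader_dwell`, `co_release`, `clamp_persists`, `censored`.
#' @export
classify_loading <- function(loader_intervals, clamp_intervals, period) {
  out <- list()
  for (m in intersect(unique(loader_intervals$molecule_id),
                      unique(clamp_intervals$molecule_id))) {
    ld <- loader_intervals[loader_intervals$molecule_id == m, , drop = FALSE]
    cl <- clamp_intervals[clamp_intervals$molecule_id == m, , drop = FALSE]
    # one-to-one greedy matching of co-arriving pairs, closest starts first,
    # so abutting events cannot steal each other's partner
    cand <- expand.grid(i = seq_len(nrow(ld)), j = seq_len(nrow(cl)))
    cand$d <- abs(ld$start_frame[cand$i] - cl$start_frame[cand$j])
    cand <- cand[cand$d <= .coarrival_tol, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_i <- logical(nrow(ld)); used_j <- logical(nrow(cl))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      co_rel <- abs(cl$end_frame[j] - ld$end_frame[i]) <= .coarrival_tol &&
        !cl$right_censored[j] && !ld$right_censored[i]
      persists <- cl$right_censored[j] ||
        cl$end_frame[j] > ld$end_frame[i] + .coarrival_tol
      out[[length(out) + 1]] <- data.frame(
        kind = "loading", molecule_id = m,
        loader_dwell = ld$dwell[i],
        co_release = co_rel, clamp_persists = persists,
        censored = ld$right_censored[i])
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), molecule_id = integer(0),
                      loader_dwell = numeric(0), co_release = logical(0),
                      clamp_persists = logical(0), censored = logical(0)))
  do.call(rbind, out)
}

#' Classify clamp-unloading events
#'
#' For each loader arrival at a molecule carrying a pre-loaded clamp
#' (a clamp interval already in progress): the encounter is *productive*
#' if the clamp signal ends during the loader's visit (or within one frame
#' after it), with `lag = (clamp_end_frame - loader_start_frame) * period`
#' (arrival-to-release); otherwise *non-productive* (loader dwell recorded,
#' clamp stays). A loader arrival with no concurrent clamp is classified
#' `"solo"`.
#'
#' @inheritParams classify_loading
#' @return data.frame: `kind` in `unloading_productive` /
#'   `unloading_nonproductive` / `solo`, `molecule_id`, `loader_dwell`,
#'   `lag` (s, productive only, NA otherwise), `censored`.
#' @export
classify_unloading <- function(loader_intervals, clamp_intervals, period) {
  out <- list()
  for (m in unique(loader_intervals$molecule_id)) {
    ld <- loader_intervals[loader_intervals$molecule_id == m, , drop = FALSE]
    cl <- clamp_intervals[clamp_intervals$molecule_id == m, , drop = FALSE]
    for (i in seq_len(nrow(ld))) {
      s <- ld$start_frame[i]; e <- ld$end_frame[i]
      j <- which(cl$start_frame < s - .coarrival_tol & cl$end_frame >= s)
      if (!length(j)) {
        out[[length(out) + 1]] <- data.frame(
          kind = "solo", molecule_id = m, loader_dwell = ld$dwell[i],
          lag = NA_real_, censored = ld$right_censored[i])
        next
      }
      j <- j[1]
      productive <- !cl$right_censored[j] &&
        cl$end_frame[j] >= s && cl$end_frame[j] <= e + .coarrival_tol
      if (productive) {
        out[[length(out) + 1]] <- data.frame(
          kind = "unloading_productive", molecule_id = m,
          loader_dwell = ld$dwell[i],
          lag = (cl$end_frame[j] - s) * period,
          censored = ld$right_censored[i])
      } else {
        out[[length(out) + 1]] <- data.frame(
          kind = "unloading_nonproductive", molecule_id = m,
          loader_dwell = ld$dwell[i], lag = NA_real_,
          censored = ld$right_censored[i])
      }
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), molecule_id = integer(0),
                      loader_dwell = numeric(0), lag = numeric(0),
                      censored = logical(0)))
  do.call(rbind, out)
}

#' Classify polymerase exchange: switches and co-localizations
#'
#' Merges the two species' binding intervals per molecule into time order.
#' Each adjacent pair of non-overlapping intervals from different species is
#' a *switch* in the observed direction with
#' `lag = (start_b - end_a - 1) * period` (the empty frames between them);
#' each overlapping cross-species pair is one *co-localization* with
#' `duration = (overlap frames) * period`, recording which species arrived
#' first and which left first (a tie when the frames coincide). Events whose
#' measured quantity is truncated by the movie end are excluded from means
#' but kept in direction tallies.
#'
#' @param intervals_a,intervals_b Interval tables of the two species.
#' @param period Per-channel sampling period, s.
#' @param species Character length-2: names for the two species (defaults
#'   `"A"`, `"B"`).
#' @param per_molecule If `TRUE`, tally at most one event per molecule (the
#'   earliest classified pair in time) instead of per pair.
#' @param clamp_intervals Optional clamp-channel interval table; when given,
#'   a switch is only counted if one clamp interval spans the gap (the same
#'   clamp stays bound across the exchange). When the clamp is unlabelled,
#'   continuity is assumed.
#' @return list with `events` (one row per classified event) and `summary`
#'   (an `exchange_summary`: counts, percentages over classified pairs, mean
#'   lag per direction, mean co-localization duration, n_pairs).
#' @export
classify_exchange <- function(intervals_a, intervals_b, period,
                              species = c("A", "B"), per_molecule = FALSE,
                              clamp_intervals = NULL) {
  if (nrow(intervals_a) && nrow(intervals_b) &&
      any(intervals_a$channel[1] == intervals_b$channel[1]))
    stop("the two species must come from different channels")
  ev <- list()
  mols <- union(unique(intervals_a$molecule_id),
                unique(intervals_b$molecule_id))
  for (m in mols) {
    a <- intervals_a[intervals_a$molecule_id == m, , drop = FALSE]
    b <- intervals_b[intervals_b$molecule_id == m, , drop = FALSE]
    if (nrow(a)) a$species <- species[1]
    if (nrow(b)) b$species <- species[2]
    iv <- rbind(a, b)
    if (nrow(iv) < 2) next
    iv <- iv[order(iv$start_frame, iv$end_frame), , drop = FALSE]
    cl <- if (is.null(clamp_intervals)) NULL else
      clamp_intervals[clamp_intervals$molecule_id == m, , drop = FALSE]
    # co-localizations: every overlapping cross-species pair
    if (nrow(a) && nrow(b)) {
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        os <- max(a$start_frame[i], b$start_frame[j])
        oe <- min(a$end_frame[i], b$end_frame[j])
        if (oe < os) next
        cens <- (a$end_frame[i] <= b$end_frame[j] && a$right_censored[i]) ||
                (b$end_frame[j] <= a$end_frame[i] && b$right_censored[j])
        first_in <- if (a$start_frame[i] < b$start_frame[j]) species[1]
                    else if (b$start_frame[j] < a$start_frame[i]) species[2]
                    else "tie"
        first_out <- if (a$end_frame[i] < b$end_frame[j]) species[1]
                     else if (b$end_frame[j] < a$end_frame[i]) species[2]
                     else "tie"
        ev[[length(ev) + 1]] <- data.frame(
          kind = "colocalization", molecule_id = m,
          direction = NA_character_, lag = NA_real_,
          duration = (oe - os + 1) * period,
          first_in = first_in, first_out = first_out, censored = cens,
          at_frame = os)
      }
    }
    # switches: adjacent non-overlapping cross-species pairs in time order
    for (i in seq_len(nrow(iv) - 1)) {
      x <- iv[i, ]; y <- iv[i + 1, ]
      if (x$species == y$species) next
      if (y$start_frame <= x$end_frame) next   # overlap -> colocalization
      if (!is.null(cl) && nrow(cl)) {
        spans <- any(cl$start_frame <= x$end_frame &
                     cl$end_frame >= y$start_frame)
        if (!spans) next
      }
      ev[[length(ev) + 1]] <- data.frame(
        kind = "switch", molecule_id = m,
        direction = paste0(x$species, "->", y$species),
        lag = (y$start_frame - x$end_frame - 1) * period,
        duration = NA_real_, first_in = NA_character_,
        first_out = NA_character_, censored = FALSE,
        at_frame = y$start_frame)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(0), molecule_id = integer(0),
               direction = character(0), lag = numeric(0),
               duration = numeric(0), first_in = character(0),
               first_out = character(0), censored = logical(0),
               at_frame = integer(0))
  if (nrow(events)) {
    events <- events[order(events$molecule_id, events$at_frame), ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  if (per_molecule && nrow(events))
    events <- events[!duplicated(events$molecule_id), , drop = FALSE]
  list(events = events,
       summary = exchange_summary(events, species))
}

exchange_summary <- function(events, species = c("A", "B")) {
  d_ab <- paste0(species[1], "->", species[2])
  d_ba <- paste0(species[2], "->", species[1])
  sw <- events[events$kind == "switch", , drop = FALSE]
  co <- events[events$kind == "colocalization", , drop = FALSE]
  n_ab <- sum(sw$direction == d_ab)
  n_ba <- sum(sw$direction == d_ba)
  n_co <- nrow(co)
  n <- n_ab + n_ba + n_co
  pct <- if (n > 0) 100 * c(n_ab, n_ba, n_co) / n else rep(NA_real_, 3)
  mean_sem <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    c(mean(x), stats::sd(x) / sqrt(length(x)))
  }
  lag_ab <- mean_sem(sw$lag[sw$direction == d_ab & !sw$censored])
  lag_ba <- mean_sem(sw$lag[sw$direction == d_ba & !sw$censored])
  dur <- mean_sem(co$duration[!co$censored])
  structure(list(species = species,
                 n_pairs = n, n_switch_ab = n_ab, n_switch_ba = n_ba,
                 n_coloc = n_co,
                 pct_switch_ab = pct[1], pct_switch_ba = pct[2],
                 pct_coloc = pct[3],
                 lag_ab_mean = lag_ab[1], lag_ab_sem = lag_ab[2],
                 lag_ba_mean = lag_ba[1], lag_ba_sem = lag_ba[2],
                 coloc_duration_mean = dur[1], coloc_duration_sem = dur[2]),
            class = "exchange_summary")
}

#' @export
print.exchange_summary <- function(x, ...) {
  cat(sprintf("Exchange summary (%s vs %s), %d classified pairs:\n",
              x$species[1], x$species[2], x$n_pairs))
  cat(sprintf("  %s->%s: %d (%.1f%%), mean lag %.2f +/- %.2f s\n",
              x$species[1], x$species[2], x$n_switch_ab, x$pct_switch_ab,
              x$lag_ab_mean, x$lag_ab_sem))
  cat(sprintf("  %s->%s: %d (%.1f%%), mean lag %.2f +/- %.2f s\n",
              x$species[2], x$species[1], x$n_switch_ba, x$pct_switch_ba,
              x$lag_ba_mean, x$lag_ba_sem))
  cat(sprintf("  co-localization: %d (%.1f%%), mean duration %.2f +/- %.2f s\n",
              x$n_coloc, x$pct_coloc,
              x$coloc_duration_mean, x$coloc_duration_sem))
  invisible(x)
}

#' Colocalization-based labelling efficiency estimator
#'
#' On events where two partner proteins are known to be co-bound, each event
#' shows label A only, label B only, or both. A label's efficiency is
#' estimated from the events certified by the *partner's* label:
#' `p_a = n_both / (n_both + n_b_only)` and symmetrically for B. Doubly-dark
#' events are invisible and drop out of both ratios, which is what makes the
#' estimator consistent.
#'
#' @param n_both,n_a_only,n_b_only Event counts (>= 0).
#' @return list with `p_a`, `p_b` and binomial standard errors `se_a`,
#'   `se_b`.
#' @examples
#' estimate_label_efficiency(100, 50, 50)  # both 2/3
#' @export
estimate_label_efficiency <- function(n_both, n_a_only, n_b_only) {
  if (any(c(n_both, n_a_only, n_b_only) < 0))
    stop("counts must be >= 0")
  na <- n_both + n_b_only   # events with B label -> denominator for p_a
  nb <- n_both + n_a_only
  if (na == 0 || nb == 0)
    stop("labelling efficiency undefined: empty denominator")
  p_a <- n_both / na
  p_b <- n_both / nb
  list(p_a = p_a, p_b = p_b,
       se_a = sqrt(p_a * (1 - p_a) / na),
       se_b = sqrt(p_b * (1 - p_b) / nb))
}

#' Lag statistics over classified events
#'
#' Arithmetic mean and standard error of the lag over uncensored events of
#' one kind (and, for switches, one direction). `bias_correction` is added
#' to each lag before averaging: frame quantization rounds a release down
#' and an arrival up to the sampling grid, so arrival-to-release lags are
#' biased by one cycle period and a `+period` correction restores the mean
#' (the release-to-arrival switch convention is already unbiased).
#'
#' @param events Event data.frame from a `classify_*` function (must have
#'   `kind`, `lag`, `censored`; optionally `direction`).
#' @param kind Event kind to select.
#' @param direction Optional direction filter (e.g. `"A->B"`).
#' @param bias_correction Seconds added to each lag (default 0).
#' @return list `n`, `mean`, `sem`, or an empty result (`n = 0`, `mean` and
#'   `sem` `NA`) when no uncensored event matches.
#' @examples
#' ev <- data.frame(kind = "switch", lag = c(2, 4, 6), censored = FALSE)
#' lag_statistics(ev, "switch")   # mean 4, sem 1.155
#' @export
lag_statistics <- function(events, kind, direction = NULL,
                           bias_correction = 0) {
  sel <- events$kind == kind & !events$censored & !is.na(events$lag)
  if (!is.null(direction) && "direction" %in% names(events))
    sel <- sel & !is.na(events$direction) & events$direction == direction
  x <- events$lag[sel] + bias_correction
  if (!length(x)) return(list(n = 0L, mean = NA_real_, sem = NA_real_))
  list(n = length(x), mean = mean(x),
       sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
}
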