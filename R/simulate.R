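# Gillespie simulation of kinetic schemes and ground-truth interval algebra.

#' Simulate one molecule's state trajectory
#'
#' Exact stochastic (Gillespie) simulation of a [build_scheme()] chain on a
#' single DNA molecule. Dwell times in a state with total exit rate `lambda`
#' are exponential with mean `1/lambda`; the next state is drawn with
#' probability proportional to its transition rate. A state with no outgoing
#' transitions is absorbing and the trajectory stays there until `duration`.
#'
#' @param scheme A `kinetic_scheme`.
#' @param duration Total simulated time, s (> 0).
#' @param seed Optional integer seed (set once before simulation); identical
#'   `(scheme, duration, seed)` gives bit-identical trajectories.
#' @param initial Optional initial state label overriding the scheme default.
#' @return A `data.frame` with columns `t_start`, `t_end`, `state`: contiguous
#'   non-overlapping segments covering `[0, duration]`.
#' @export
simulate_trajectory <- function(scheme, duration, seed = NULL,
                                initial = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(duration) || duration <= 0)
    stop("simulate_trajectory: duration must be a positive finite number")
  if (!is.null(seed)) set.seed(seed)
  eng <- scheme_engine(scheme)
  s0 <- if (is.null(initial)) scheme$initial else initial
  if (!s0 %in% scheme$states) stop("unknown initial state: ", s0)
  sim_one(eng, match(s0, eng$states), duration)
}

# Precompute per-state outgoing transitions for fast repeated simulation.
scheme_engine <- function(scheme) {
  states <- scheme$states
  out <- lapply(states, function(s) {
    t <- scheme$transitions[scheme$transitions$from == s, , drop = FALSE]
    list(to = match(t$to, states), rate = t$rate, total = sum(t$rate))
  })
  list(states = states, out = out)
}

sim_one <- function(eng, state, duration) {
  t_start <- numeric(16); st <- integer(16); n <- 0L
  t <- 0
  repeat {
    n <- n + 1L
    if (n > length(st)) {          # grow
      length(t_start) <- 2L * length(t_start)
      length(st) <- 2L * length(st)
    }
    t_start[n] <- t; st[n] <- state
    o <- eng$out[[state]]
    if (o$total <= 0) break        # absorbing
    t <- t + stats::rexp(1L, o$total)
    if (t >= duration) break
    state <- if (length(o$rate) == 1L) o$to else
      o$to[sample.int(length(o$rate), 1L, prob = o$rate)]
  }
  t_start <- t_start[seq_len(n)]
  data.frame(t_start = t_start,
             t_end = c(t_start[-1L], duration),
             state = eng$states[st[seq_len(n)]],
             stringsAsFactors = FALSE)
}

#' Simulate a set of independent molecules
#'
#' Runs [simulate_trajectory()] for `n_molecules` independent DNA molecules
#' (no shared protein depletion: the solution reservoir is treated as
#' infinite) under one RNG stream seeded once.
#'
#' @inheritParams simulate_trajectory
#' @param n_molecules Number of molecules.
#' @param seed Integer seed for the whole set.
#' @return A `trajectory_set`: data.frame with columns `molecule_id`,
#'   `t_start`, `t_end`, `state`, with attributes `scheme_name`, `occupancy`
#'   (state -> bound species map) and `duration`.
#' @export
simulate_trajectories <- function(scheme, n_molecules, duration, seed = NULL,
                                  initial = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), n_molecules >= 1)
  if (!is.null(seed)) set.seed(seed)
  eng <- scheme_engine(scheme)
  s0 <- if (is.null(initial)) scheme$initial else initial
  i0 <- match(s0, eng$states)
  if (is.na(i0)) stop("unknown initial state: ", s0)
  segs <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    d <- sim_one(eng, i0, duration)
    d$molecule_id <- m
    segs[[m]] <- d
  }
  out <- do.call(rbind, segs)
  out <- out[c("molecule_id", "t_start", "t_end", "state")]
  rownames(out) <- NULL
  structure(out,
            scheme_name = scheme$name,
            occupancy = scheme$occupancy,
            duration = duration,
            class = c("trajectory_set", "data.frame"))
}

#' Ground-truth binding intervals of each species
#'
#' Collapses a trajectory set to per-species bound intervals: maximal runs of
#' contiguous segments in which the species is DNA-bound. These are the true
#' binding events underlying the rendered traces, used as the oracle for
#' detection and classification round-trips.
#'
#' @param trajectories A `trajectory_set` from [simulate_trajectories()].
#' @param species Character vector of species to extract (default: all
#'   species that appear in the scheme's occupancy map).
#' @return data.frame with columns `molecule_id`, `species`, `t_start`,
#'   `t_end`.
#' @export
species_intervals <- function(trajectories, species = NULL) {
  occ <- attr(trajectories, "occupancy")
  if (is.null(occ)) stop("not a trajectory_set (no occupancy attribute)")
  all_sp <- unique(unlist(occ, use.names = FALSE))
  if (is.null(species)) species <- all_sp
  res <- list()
  for (sp in species) {
    bound_states <- names(occ)[vapply(occ, function(s) sp %in% s, TRUE)]
    b <- trajectories$state %in% bound_states
    if (!any(b)) next
    # runs of bound segments within each molecule
    id <- trajectories$molecule_id
    grp <- cumsum(c(TRUE, b[-1] != b[-length(b)] | id[-1] != id[-length(id)]))
    keep <- b
    starts <- tapply(trajectories$t_start[keep], grp[keep], min)
    ends <- tapply(trajectories$t_end[keep], grp[keep], max)
    mol <- tapply(id[keep], grp[keep], function(x) x[1])
    res[[sp]] <- data.frame(molecule_id = as.integer(mol),
                            species = sp,
                            t_start = as.numeric(starts),
                            t_end = as.numeric(ends))
  }
  if (!length(res))
    return(data.frame(molecule_id = integer(0), species = character(0),
                      t_start = numeric(0), t_end = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$molecule_id, out$t_start), ]
  rownames(out) <- NULL
  out
}

#' Write / read a trajectory set as delimited text
#'
#' One row per segment: `molecule_id, t_start, t_end, state`, tab-separated.
#' @param trajectories A `trajectory_set`.
#' @param path Output file path.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.table(as.data.frame(trajectories), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Ground-truth intervals sampled on an acquisition schedule
#'
#' Projects true binding events onto a channel's sampling grid: the interval
#' a perfect detector would report, i.e. the frames whose sample times fall
#' inside each event. Events covering no sample point are dropped (sub-frame
#' events between samples are invisible by construction).
#'
#' @param trajectories A `trajectory_set`.
#' @param schedule An `acq_schedule`.
#' @param species Species to project.
#' @param channel Channel index whose sampling grid to use.
#' @return data.frame in the layout of [detect_intervals_set()]:
#'   `molecule_id, channel, start_frame, end_frame, start_time, end_time,
#'   dwell, left_censored, right_censored`.
#' @export
true_intervals <- function(trajectories, schedule, species, channel = 1) {
  ev <- species_intervals(trajectories, species)
  tms <- sample_times(schedule, channel)
  n <- schedule$n_frames
  period <- schedule$cycle_period
  off <- schedule$channel_offsets[channel]
  # first/last covered frame via the grid arithmetic
  first <- ceiling((ev$t_start - off) / period) + 1
  first <- pmax(first, 1L)
  last <- floor((ev$t_end - off) / period) +
    ifelse((ev$t_end - off) %% period == 0, 0, 1)
  last <- pmin(last, n)
  # a sample at exactly t_end is outside the right-open event interval
  last <- ifelse(tms[pmin(pmax(last, 1), n)] >= ev$t_end, last - 1, last)
  keep <- last >= first
  ev <- ev[keep, , drop = FALSE]
  first <- as.integer(first[keep]); last <- as.integer(last[keep])
  out <- data.frame(molecule_id = ev$molecule_id, channel = channel,
                    start_frame = first, end_frame = last,
                    start_time = (first - 1) * period,
                    end_time = (last - 1) * period,
                    dwell = (last - first + 1) * period,
                    left_censored = first == 1L,
                    right_censored = last == n)
  rownames(out) <- NULL
  out
}
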