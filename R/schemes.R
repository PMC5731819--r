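# Kinetic schemes for clamp / polymerase binding on single DNA molecules.
#
# A scheme is a finite continuous-time Markov chain over occupancy states of
# one DNA molecule.  Each state is labelled, and maps to the set of protein
# species bound in that state; transitions that change two species at once
# (co-arrival / co-departure of a pre-formed complex) are single atomic jumps.

# Default association propensity (per nM per s).  Published switching data tie
# a mean arrival lag of 20.3 s to a 30 nM polymerase concentration, giving
# kon = 1/(20.3 * 30) per nM per s as the field-realistic default.
.default_kon <- 1 / (20.3 * 30)

#' Association/dissociation rate set for one species
#'
#' Bundles the three numbers that define a species' binding kinetics: the
#' association propensity per unit concentration, the dissociation rate, and
#' the solution concentration. The effective arrival rate at a free site is
#' `kon_per_conc * conc`; the mean bound lifetime is `1/koff`.
#'
#' @param kon_per_conc Association propensity, 1/(nM s). Must be >= 0.
#' @param koff Dissociation rate, 1/s. Must be >= 0.
#' @param conc Concentration in solution, nM. Must be >= 0.
#' @return An object of class `rate_set`.
#' @examples
#' rs <- rate_set(kon_per_conc = 0.0016, koff = 1 / 15.7, conc = 30)
#' arrival_rate(rs)
#' @export
rate_set <- function(kon_per_conc, koff, conc) {
  vals <- c(kon_per_conc = kon_per_conc, koff = koff, conc = conc)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rate_set: all of kon_per_conc, koff, conc must be finite and >= 0")
  structure(as.list(vals), class = "rate_set")
}

#' Effective arrival rate of a rate set
#' @param x A [rate_set()].
#' @return Arrival rate in 1/s (`kon_per_conc * conc`).
#' @export
arrival_rate <- function(x) {
  stopifnot(inherits(x, "rate_set"))
  x$kon_per_conc * x$conc
}

new_scheme <- function(name, transitions, occupancy, initial) {
  states <- names(occupancy)
  stopifnot(initial %in% states,
            all(transitions$from %in% states),
            all(transitions$to %in% states))
  if (any(!is.finite(transitions$rate)) || any(transitions$rate < 0))
    stop(sprintf("scheme '%s': all transition rates must be finite and >= 0",
                 name))
  # drop null transitions, then prune states unreachable from the initial one
  transitions <- transitions[transitions$rate > 0, , drop = FALSE]
  reach <- initial
  repeat {
    nxt <- unique(c(reach, transitions$to[transitions$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  keep <- states %in% reach
  occupancy <- occupancy[keep]
  transitions <- transitions[transitions$from %in% reach &
                               transitions$to %in% reach, , drop = FALSE]
  rownames(transitions) <- NULL
  structure(list(name = name,
                 states = names(occupancy),
                 occupancy = occupancy,
                 transitions = transitions,
                 initial = initial),
            class = "kinetic_scheme")
}

tr <- function(from, to, rate) data.frame(from = from, to = to, rate = rate,
                                          stringsAsFactors = FALSE)

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", length(x$states), " states, ",
      nrow(x$transitions), " transitions; initial state '", x$initial,
      "'\n", sep = "")
  occ <- vapply(x$occupancy, function(s)
    if (length(s)) paste(s, collapse = "+") else "(empty)", "")
  cat("States:", paste(sprintf("%s[%s]", names(occ), occ), collapse = ", "),
      "\n")
  invisible(x)
}

#' All species named by a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Character vector of species labels.
#' @export
scheme_species <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  unique(unlist(scheme$occupancy, use.names = FALSE))
}

# ---- preset builders --------------------------------------------------------

scheme_clamp_loading <- function(kon_per_conc = .default_kon, conc = 15,
                                 loader_koff = 1 / 0.41,
                                 clamp_koff = 1 / 1429.7) {
  k_arr <- kon_per_conc * conc
  new_scheme(
    "clamp_loading",
    rbind(tr("empty", "loader.clamp", k_arr),
          tr("loader.clamp", "clamp", loader_koff),
          tr("clamp", "empty", clamp_koff)),
    occupancy = list(empty = character(0),
                     loader.clamp = c("loader", "clamp"),
                     clamp = "clamp"),
    initial = "empty")
}

scheme_clamp_loading_atpgs <- function(kon_per_conc = .default_kon, conc = 15,
                                       complex_koff = 1 / 2.7) {
  k_arr <- kon_per_conc * conc
  new_scheme(
    "clamp_loading_atpgs",
    rbind(tr("empty", "loader.clamp", k_arr),
          tr("loader.clamp", "empty", complex_koff)),
    occupancy = list(empty = character(0),
                     loader.clamp = c("loader", "clamp")),
    initial = "empty")
}

scheme_clamp_unloading <- function(kon_per_conc = .default_kon, conc = 15,
                                   p_productive = 0.47,
                                   release_rate = 1 / 4.1,
                                   loader_total_dwell = 10.8,
                                   nonproductive_koff = 1 / 2.5,
                                   bare_dna_koff = 1 / 1.20) {
  if (p_productive < 0 || p_productive > 1)
    stop("clamp_unloading: p_productive must lie in [0, 1]")
  post_mean <- loader_total_dwell - 1 / release_rate
  if (post_mean <= 0)
    stop("clamp_unloading: loader_total_dwell must exceed the release stage mean")
  k_arr <- kon_per_conc * conc
  new_scheme(
    "clamp_unloading",
    rbind(
      tr("clamp", "clamp.loaderP", p_productive * k_arr),
      tr("clamp", "clamp.loaderN", (1 - p_productive) * k_arr),
      # productive: clamp released first, loader lingers to its total dwell
      tr("clamp.loaderP", "loaderPost", release_rate),
      tr("loaderPost", "unloaded", 1 / post_mean),
      # non-productive encounter: loader leaves, clamp stays
      tr("clamp.loaderN", "clamp", nonproductive_koff),
      # after unloading the loader can still sample the bare DNA
      tr("unloaded", "loaderSolo", k_arr),
      tr("loaderSolo", "unloaded", bare_dna_koff)),
    occupancy = list(clamp = "clamp",
                     clamp.loaderP = c("clamp", "loader"),
                     loaderPost = "loader",
                     unloaded = character(0),
                     clamp.loaderN = c("clamp", "loader"),
                     loaderSolo = "loader"),
    initial = "clamp")
}

scheme_pol_on_clamp <- function(kon_per_conc = .default_kon, conc = 30,
                                koff = 1 / 15.7, species = "pol3") {
  bound <- paste0("clamp.", species)
  occ <- list(clamp = "clamp")
  occ[[bound]] <- c("clamp", species)
  new_scheme(paste0(species, "_on_clamp"),
             rbind(tr("clamp", bound, kon_per_conc * conc),
                   tr(bound, "clamp", koff)),
             occupancy = occ, initial = "clamp")
}

scheme_pol1_dna <- function(kon_per_conc = .default_kon, conc = 30,
                            koff = 1 / 42.2) {
  new_scheme("pol1_dna",
             rbind(tr("empty", "pol1", kon_per_conc * conc),
                   tr("pol1", "empty", koff)),
             occupancy = list(empty = character(0), pol1 = "pol1"),
             initial = "empty")
}

scheme_competition <- function(species_a = "pol3", species_b = "pol4",
                               kon_a = .default_kon, conc_a = 30,
                               koff_a = 1 / 15.7,
                               kon_b = .default_kon, conc_b = 30,
                               koff_b = 1 / 14.2,
                               mutual_exclusion = FALSE,
                               co_rate_multiplier = 1,
                               arrival_rate_a = NULL,
                               initial_bound_a = FALSE) {
  ka <- if (is.null(arrival_rate_a)) kon_a * conc_a else arrival_rate_a
  kb <- kon_b * conc_b
  sa <- paste0("clamp.", species_a)
  sb <- paste0("clamp.", species_b)
  sab <- paste0("clamp.", species_a, ".", species_b)
  occ <- list(clamp = "clamp")
  occ[[sa]] <- c("clamp", species_a)
  occ[[sb]] <- c("clamp", species_b)
  trs <- rbind(tr("clamp", sa, ka), tr(sa, "clamp", koff_a),
               tr("clamp", sb, kb), tr(sb, "clamp", koff_b))
  if (!mutual_exclusion) {
    occ[[sab]] <- c("clamp", species_a, species_b)
    m <- co_rate_multiplier
    trs <- rbind(trs,
                 tr(sa, sab, kb), tr(sb, sab, ka),
                 tr(sab, sb, koff_a * m), tr(sab, sa, koff_b * m))
  }
  new_scheme("competition", trs, occupancy = occ,
             initial = if (initial_bound_a) sa else "clamp")
}

scheme_tau_complex <- function(species_b = "pol4",
                               tether_rate = 1 / 11.3,
                               koff_a = 1 / 14.8,
                               kon_b = .default_kon, conc_b = 30,
                               koff_b = 1 / 14.2,
                               co_rate_multiplier = 1) {
  # Pol IIIcore is tethered to the clamp loader: it co-arrives with the
  # loaded clamp (initial state bound) and is re-delivered after release at
  # a concentration-independent rate set by the tether (default derived from
  # the published replicative-to-translesion switch lag in this regime).
  scheme_competition(species_a = "pol3", species_b = species_b,
                     koff_a = koff_a, kon_b = kon_b, conc_b = conc_b,
                     koff_b = koff_b, mutual_exclusion = FALSE,
                     co_rate_multiplier = co_rate_multiplier,
                     arrival_rate_a = tether_rate, initial_bound_a = TRUE)
}

#' Build a preset kinetic scheme
#'
#' Constructs one of the named binding schemes of the clamp / polymerase
#' system as a continuous-time Markov chain. Available presets:
#'
#' * `"clamp_loading"` — loader and clamp co-arrive on empty DNA as a
#'   pre-formed complex; the loader departs alone (mean 0.41 s) leaving the
#'   clamp loaded (mean lifetime ~1430 s).
#' * `"clamp_loading_atpgs"` — without ATP hydrolysis the loader-clamp
#'   complex co-arrives and co-departs atomically (mean 2.7 s).
#' * `"clamp_unloading"` — loader encounters a pre-loaded clamp; a fraction
#'   `p_productive` of encounters release the clamp after an exponential lag
#'   (mean 4.1 s) with the loader remaining to a total dwell of 10.8 s; the
#'   rest are non-productive (loader dwell mean 2.5 s, clamp stays).
#' * `"pol3_on_clamp"` — a single polymerase exchanging on loaded clamp-DNA
#'   (Pol IIIcore default lifetime 15.7 s).
#' * `"pol1_dna"` — Pol I Klenow fragment binding bare DNA (lifetime 42.2 s).
#' * `"competition"` — two polymerases competing for clamp-DNA with
#'   independent arrivals/departures; optional strict mutual exclusion
#'   (Pol II-like) or independent co-occupancy of the clamp's two grooves
#'   (Pol IV-like), with an optional dissociation-rate multiplier while
#'   co-occupied (default 1 = strict independence).
#' * `"tau_complex"` — as `"competition"` but the replicative polymerase is
#'   tethered to the clamp loader: it starts bound and rebinds at a fast
#'   concentration-independent rate.
#'
#' @param preset Preset name (see above).
#' @param rates Named list overriding the preset's rate/concentration
#'   defaults (arguments of the underlying builder, e.g. `koff_a`, `conc`).
#' @return A `kinetic_scheme`.
#' @examples
#' sch <- build_scheme("pol3_on_clamp", list(koff = 1 / 15.7))
#' sch
#' @export
build_scheme <- function(preset, rates = list()) {
  builders <- list(clamp_loading = scheme_clamp_loading,
                   clamp_loading_atpgs = scheme_clamp_loading_atpgs,
                   clamp_unloading = scheme_clamp_unloading,
                   pol3_on_clamp = scheme_pol_on_clamp,
                   pol1_dna = scheme_pol1_dna,
                   competition = scheme_competition,
                   tau_complex = scheme_tau_complex)
  if (!preset %in% names(builders))
    stop(sprintf("unknown scheme preset '%s'; available: %s", preset,
                 paste(names(builders), collapse = ", ")))
  f <- builders[[preset]]
  bad <- setdiff(names(rates), names(formals(f)))
  if (length(bad))
    stop(sprintf("preset '%s' does not take rate(s): %s", preset,
                 paste(bad, collapse = ", ")))
  if (any(vapply(rates, function(v) is.null(v) || anyNA(v), TRUE)))
    stop(sprintf("preset '%s': missing (NULL/NA) rate value", preset))
  do.call(f, rates)
}

#' Expected co-localization duration under independent dissociation
#'
#' From the instant two species are both bound, with memoryless independent
#' dissociation at rates `1/tau_a` and `1/tau_b`, the time to the first
#' departure is exponential with mean `1/(1/tau_a + 1/tau_b)`.
#'
#' @param tau_a,tau_b Mean bound lifetimes of the two species (s), > 0.
#'   `Inf` is allowed and gives the other species' lifetime in the limit.
#' @return Expected overlap duration in seconds.
#' @examples
#' expected_coloc_duration(15.7, 14.2)   # ~7.46 s
#' @export
expected_coloc_duration <- function(tau_a, tau_b) {
  if (any(is.na(c(tau_a, tau_b))) || tau_a <= 0 || tau_b <= 0)
    stop("expected_coloc_duration: lifetimes must be positive")
  1 / (1 / tau_a + 1 / tau_b)
}
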