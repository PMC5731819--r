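---
title: "Models and methods behind cosmosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cosmosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmosim)
```

# Scope

`cosmosim` reproduces, as a tested pipeline, the single-molecule
co-localization (CoSMoS) analysis of the *E. coli* clamp cycle and
replicative/translesion polymerase exchange. Published lifetimes, lags and
event fractions in this system are measurements on real data; the package
treats each of them as a *generator parameter* and asks whether the full
measurement chain — stochastic binding kinetics, interleaved multi-channel
acquisition, interval detection, event classification, exponential dwell
fitting — returns it. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic data do and do not capture.

# Kinetic schemes

Each DNA molecule is an independent continuous-time Markov chain over
occupancy states (which protein species are bound). Transitions that move
two species at once — a pre-formed loader–clamp complex arriving, or the
ATPγS-arrested complex releasing — are single atomic jumps, so co-arrival
and co-departure are exact at the trajectory level. Simulation is standard
Gillespie: the dwell in a state with total exit rate $\lambda$ is
$\mathrm{Exp}(\lambda)$, and the successor is drawn proportionally to the
individual rates. States without outgoing transitions are absorbing.
Molecules are simulated independently: at nM protein concentrations the
solution reservoir vastly exceeds the surface-tethered molecules, so no
depletion coupling is modelled.

Dissociation rates come directly from published mean lifetimes
($k_\mathrm{off} = 1/\tau_\mathrm{on}$). Association rates are never
printed; the observable tied to concentration is the lag between one
species' release and the next arrival. The default association propensity
is therefore derived from the published 20.3 s switch lag at 30 nM:
$k_\mathrm{on} = 1/(20.3 \times 30)$ per nM per second, used for every
species unless a preset overrides it.

Preset-specific choices:

* **Clamp unloading.** The productive branch is modelled as two sequential
  exponential stages: clamp release after a mean 4.1 s lag, then loader
  departure after a further 6.7 s so the loader's total dwell is 10.8 s.
  Non-productive encounters (probability 0.53, fixed — the data do not
  resolve any concentration dependence of this split) last 2.5 s and leave
  the clamp in place. After unloading the loader still samples the bare
  DNA with its 1.20 s bare-DNA lifetime, which exercises the classifier's
  "solo" category.
* **Competition.** Pol IIIcore and Pol IV occupy the clamp's two
  hydrophobic grooves independently: arrivals and departures of the two
  species are uncoupled, and co-occupancy multiplies neither dissociation
  rate (an optional multiplier exists, default 1, because the measured
  co-localization time is statistically consistent with the strict
  independence prediction $1/(1/\tau_A + 1/\tau_B)$). Pol II is strictly
  mutually exclusive with Pol IIIcore.
* **τ-complex.** Tethering is modelled as a concentration-independent
  re-delivery rate for Pol IIIcore, starting bound. The default, 1/11.3
  per second, is derived from the published replicative-to-translesion
  switch lag in the tethered regime, by the same logic that sets
  $k_\mathrm{on}$ from a lag.
* Trajectories start in the scheme's natural initial state (empty DNA, or
  a pre-loaded clamp) with no burn-in, mirroring the wash/flow-in
  protocol.

# Acquisition model

The camera exposes for 50 ms per frame and alternates between channels, so
each channel is sampled once per cycle: 86 ms for one colour, 440 ms for
two, 660 ms for three. These per-frame periods are configuration constants
rather than quantities derived from exposure plus switching time, because
the published timing numbers are not mutually derivable; taking them as
given reproduces every printed frame rate. Interval (stroboscopic) mode
replaces the cycle period with a long one (e.g. 10 s) to cut cumulative
illumination.

Labelling is Bernoulli per *binding arrival*: a departing and re-arriving
protein is a fresh molecule from solution and re-draws its label. Default
efficiencies are the published per-protein values (e.g. 0.60 for Pol IIIα,
0.85 for the loader complex, 0.68 for the clamp monomer).

Photobleaching is a hazard per second of illumination, accrued only during
the fluorophore's own channel's exposures. Hazards are calibrated from the
published apparent on-DNA lifetimes of the three dyes (274.4 / 145.7 /
93.0 s) assuming those were measured under the standard 3-colour continuous
schedule — the measurement's exact schedule is not stated, and this
assumption is the one the stroboscopic extension factors are computed
against. With duty cycle $d$ = exposure/cycle, hazard $h$ gives apparent
lifetime $1/(hd)$: the same dye lasts ~15× longer under 10 s interval
imaging, which is why the ~1430 s loaded-clamp lifetime is only measurable
stroboscopically. A fluorophore still emits during the frame in which it
bleaches, which lengthens the effective bleach lifetime by about half a
cycle; the forward-model tests account for this.

Intensity is constant brightness per fluorophore plus additive Gaussian
noise (defaults: brightness 120, background 100, noise SD 10 — a
signal-to-noise ratio of 12, typical of good TIRF data). Blinking is not
modelled by default: no blinking correction is applied in the analyses the
package reproduces.

# Detection

Intervals are maximal runs above a hysteresis threshold: an event must
reach `high` (default 4) background SDs somewhere and extends over
contiguous frames above `low` (default 2); gaps up to `max_gap` (default 1)
frames are bridged; runs shorter than `min_length` (default 1) are
dropped. These defaults are the package's own — the GUI used for the
original analyses does not publish its settings — and every scenario can
override them. Two overrides are themselves preset defaults: the
single-channel loading scenario raises `high` to 5 because its dwell
estimate is dominated by genuine single-frame events and 1000-frame traces
would otherwise contribute a comparable rate of single-frame noise spikes;
and interval-mode scenarios set `max_gap = 0` because a one-frame gap at a
10 s cycle is a real absence, not a dropout.

Background statistics are median/MAD, refined once by re-estimating on
frames within 3 SD of the median. Per-trace estimation fails when a single
molecule is occupied for half the movie or more (the median migrates into
the bound level), so `detect_intervals_set()` can pool the statistics per
channel across all molecules (`background = "global"`); the scenario runner
uses pooled statistics, which is also physically sensible — background and
noise are properties of the channel, not the molecule. A constant trace
with no known background is returned as a single doubly-censored interval
with a warning; a trace exactly flat at a known background is empty.
Near-saturating occupancy (the τ-complex regime, ~60% and above) defeats
threshold detection altogether; that regime is analysed from ground-truth
intervals instead, and the limitation is intrinsic to thresholding, not to
the simulator.

A detected run of $k$ frames has dwell $k\Delta$, so a sub-frame event
appears as one frame — matching how sub-frame collisions are reported in
the field.

# Event classification

Under sequential channel acquisition, simultaneity is "same or adjacent
frame" (tolerance 1 frame), applied to co-arrival and co-departure alike.
Loading events pair co-arriving loader and clamp intervals one-to-one,
greedily by start-frame distance, so abutting events cannot steal each
other's partner. Unloading encounters are loader arrivals on a pre-loaded
clamp: productive if the clamp signal ends during (or within one frame
after) the loader's visit, with lag = clamp end − loader start;
non-productive otherwise; arrivals with no concurrent clamp are "solo".

For exchange, intervals of the two polymerases are merged per molecule in
time order. Adjacent cross-species pairs with no overlap are switches with
lag equal to the empty frames between them times the period; overlapping
cross-species pairs are co-localizations with duration equal to the
overlap, recording which species arrived and left first. Percentages are
per classified pair (the published denominators are unstated); a
per-molecule tally — the earliest classified pair per molecule — is
available and is what reproduces the tethered regime's "replicative
polymerase first in ~100% of molecules, translesion-to-replicative
switches absent" structure. Events truncated by the movie end are excluded
from lag and duration means but keep their direction in the tallies.

Frame quantization biases lags in knowable ways: a release is rounded down
to the sampling grid and an arrival rounded up. The release-to-arrival
switch convention (gap of empty frames) is unbiased; the
arrival-to-release unloading lag loses one cycle plus the offset between
the two channels within the cycle, so `lag_statistics()` accepts an
additive correction and the unloading scenario applies
`cycle + (offset_clamp − offset_loader)`. These corrections follow from
the sampling model, not from fitting.

The label-efficiency estimator scores co-bound partner events as A-only,
B-only or both: each label's efficiency is estimated from the events
certified by the *partner's* label, $p_A = n_\mathrm{both}/(n_\mathrm{both}
+ n_{B\,\mathrm{only}})$, which is consistent because doubly-dark events
drop out of both numerator and denominator.

# Dwell-time estimation

The **histogram method** is the field's recipe: bin the complete
(uncensored) dwells with width ≈ τ/2, fit counts by least squares to
$N(t) = (n\Delta/\tau)\,e^{-t/\tau}$ with τ the only free parameter — the
amplitude is pinned by count normalization, which is the one principled
reading of a "one-parameter exponential" (a free-amplitude variant exists
behind a flag for sensitivity analysis). Because the bin width depends on
the answer the fit iterates from the sample mean, with damped updates
(re-binning can otherwise cycle between two widths) until τ changes by
less than 1%, capped at 50 iterations; bin widths are rounded to whole
frame periods when one is supplied, since dwells are frame-quantized.
First-bin exclusion is off by default and used where a fast contaminating
population concentrates in the first bin (the no-ATP unloading analysis);
a mixture test shows it reduces that bias.

The **MLE** is the statistically correct counterpart. Right-censored
events (in progress at the movie end) contribute survival terms —
excluding them would shorten the estimate by the classic length bias, of
order τ²/T. With frame quantization Δ, an event of true duration $t$ and
uniform phase covers $\lfloor (u+t)/\Delta \rfloor$ sample points, and for
exponential $t$ the observed frame count conditioned on detection is
geometric with ratio $q = e^{-\Delta/\tau}$; the MLE
$\hat q = S/(S+n_u)$ (with $S = \sum (k_i - 1)$ over all events and $n_u$
uncensored events) inverts to $\hat\tau = -\Delta/\log\hat q$ and removes
the half-frame-plus bias of naive frame-count means — decisive when τ is
comparable to Δ, as for the 0.41 s loader dwell at 86 ms frames. Standard
errors come from the observed information and the delta method; a
nonparametric bootstrap (`bootstrap_sem()`) cross-checks them.

Observed on-times compose dissociation with bleaching,
$1/\tau_\mathrm{app} = 1/\tau + 1/\tau_\mathrm{bleach}$;
`bleach_corrected_tau()` inverts the composition. Scenario reports carry
raw apparent values — the published numbers are themselves apparent — and
the analysis scripts print both raw and corrected forms without asserting
which convention any published number used.

# Scenarios, problem sizes and reproducibility

A `scenario_config()` bundles scheme, rates, schedule, label/bleach
models, detection parameters, molecule count and seed; a run is
bit-reproducible from config plus seed, and configs serialize to YAML.
The default 2000 molecules keeps each scenario to well under a minute on
one CPU while making recovered standard errors a few percent of the value
— small against the published standard errors the comparisons combine
with. The test suite uses 100–2000 molecules per case and 200 replicates
for coverage and censoring studies; the acceptance script uses 2000
molecules per scenario (5000 for unloading, where labelling losses and
clamp bleaching leave roughly a fifth of encounters classifiable and at
least 1000 productive events are wanted).

# What the synthetic data do not capture

The generator emulates exponential kinetics, interleaved sampling,
incomplete labelling, photobleaching and Gaussian noise. It does not
emulate fluorophore blinking, stage drift, channel registration error,
EMCCD gain statistics, diffusion-limited rebinding microphysics, or DNA
synthesis itself (primer extension changes the substrate over time).
Passing recovery tests therefore shows the analysis chain is unbiased
under the stated physics — including the biases it *shares* with real
measurements, such as bleach-shortened apparent lifetimes and
merge-inflated dwells when two events fall within a frame — but cannot
certify behaviour under artefacts the forward model omits. The Pol
IIIcore/Pol IV co-occupancy question is treated as strict independence by
default; the published co-localization time is consistent with that model
within errors, and a rate multiplier is available to explore departures.
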