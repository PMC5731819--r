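# cosmosim

Simulation and analysis of multi-colour **co-localization single-molecule
spectroscopy (CoSMoS)** experiments on the *E. coli* β-clamp / DNA-polymerase
system: clamp loading and unloading by the clamp loader, and the exchange of
the replicative polymerase (Pol IIIcore) with the translesion polymerases
(Pol IV, Pol II) on clamp-DNA.

## The scientific problem

In CoSMoS, fluorescently labelled proteins bind individual surface-tethered
DNA molecules; binding shows up as a spot appearing at a DNA's position in
one colour channel. The primary observables are *dwell times* — for a
single-step dissociation with rate k<sub>off</sub>, dwell times are
exponential with mean τ<sub>on</sub> = 1/k<sub>off</sub> — and *lag times*
between one species' release and another's arrival, which carry the
concentration dependence of association (arrival rate
k<sub>on</sub>·c). Published values for this system are measurements on real
single-molecule data and cannot be recomputed from raw inputs. This package
therefore closes the loop synthetically: every printed lifetime, lag and
branching fraction is installed as a generator parameter, and the full
measurement chain — stochastic kinetics, interleaved multi-channel TIRF
acquisition with incomplete labelling and photobleaching, threshold
detection, interval-overlap event classification, exponential dwell fitting
— must recover it within combined standard errors.

The chain mirrors the real analyses:

* **Kinetics** — continuous-time Markov chains over occupancy states of one
  DNA molecule (`build_scheme()`, `simulate_trajectories()`). Presets cover
  clamp loading (loader+clamp co-arrival, loader departs alone in 0.41 s),
  the ATPγS-arrested cycle (atomic co-departure, τ = 2.7 s), clamp
  unloading (47% productive encounters, 4.1 s arrival-to-release lag,
  10.8 s loader dwell), polymerase exchange with independent two-groove
  co-occupancy (Pol IIIcore 15.7 s, Pol IV 14.2 s) or strict mutual
  exclusion (Pol II), and the τ-complex (tethered re-delivery of
  Pol IIIcore).
* **Acquisition** — 50 ms exposures interleaved across 1–3 channels
  (86/440/660 ms per-channel periods, 1000 frames), optional 10 s
  stroboscopic interval mode; Bernoulli labelling per binding arrival;
  photobleaching hazards accrued only during a fluorophore's own exposures
  (`make_schedule()`, `render_traces()`, `calibrate_bleach_hazard()`).
* **Detection** — hysteresis thresholding over robust background statistics
  with gap bridging and censoring flags (`detect_intervals()`); an observed
  interval of *k* frames has dwell *k*·Δ.
* **Events** — co-arrival (≤1 frame across channels), loading/unloading
  classification, polymerase switches (lag = empty frames between
  cross-species intervals) vs co-localizations (overlap), and the
  colocalization-based label-efficiency estimator
  (`classify_exchange()`, `estimate_label_efficiency()`).
* **Dwell statistics** — the field's iterative binned one-parameter
  exponential fit (bin ≈ τ/2, amplitude pinned to n·Δ/τ), and a
  censored/frame-quantized maximum-likelihood estimator: conditioned on
  detection, frame counts are geometric with ratio exp(−Δ/τ), whose MLE
  removes the quantization bias (`fit_exponential_histogram()`,
  `fit_exponential_mle()`).

## Worked example

```r
library(cosmosim)

# Pol IIIcore on clamp-DNA: simulate, render 3-colour traces, detect, fit
cfg <- scenario_config("pol3_lifetime", n_molecules = 300, seed = 7)
rep <- run_scenario(cfg)
rep
#> Scenario 'pol3_lifetime' (300 molecules, seed 7, 2.2 s):
#>   quantity truth estimate    sem
#> 1 tau_pol3  15.7     15.3 0.2759
rep$fits$histogram
#> Exponential dwell fit (histogram_1p): tau = 15.25 +/- 0.12 s, n = 3076,
#> bin width 7.92 s

# Independence model for co-localization of two competing polymerases
expected_coloc_duration(15.7, 14.2)
#> [1] 7.456187

# Labelling efficiency from co-bound events scored as A-only/B-only/both
est <- estimate_label_efficiency(n_both = 1520, n_a_only = 640,
                                 n_b_only = 780)
round(c(p_a = est$p_a, p_b = est$p_b), 3)
#>   p_a   p_b
#> 0.661 0.704
```

The recovered 15.3 s sits below the installed 15.7 s by the photobleaching
composition 1/τ<sub>app</sub> = 1/τ + 1/τ<sub>bleach</sub> — exactly the
bias a real measurement with an Atto 488 label carries;
`bleach_corrected_tau()` inverts it.

The numbered scripts under `analysis/` run the full set of reproductions
(clamp cycle, polymerase lifetimes, competition and exchange, labelling /
bleaching / substrate null) and write their tables under `results/`.

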