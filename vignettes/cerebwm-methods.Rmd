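---
title: "Methods: EEG working-memory pipeline and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG working-memory pipeline and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`cerebwm` analyzes pre/post neuromodulation EEG studies of working memory:
five stimulation arms (1, 5, 10, 20 Hz repetitive transcranial magnetic
stimulation of the right cerebellar Crus II, and sham), each subject
recorded at rest and during a 2-back letter task before and after
stimulation. The pipeline quantifies four families of outcomes and their
statistics:

* **Behavior** — d′ sensitivity and mean correct-response reaction time
  per session, the normalized change index, and across-arm comparisons.
* **Event-related potentials (ERPs)** — stimulus-locked trial averages,
  mean amplitudes in the N100 (75–125 ms), P150 (130–190 ms),
  N200 (210–290 ms) and P300 (280–380 ms) windows, and post-minus-pre
  difference waves.
* **Event-related oscillations** — sliding Hanning-window power from
  3–80 Hz, dB-normalized against the −200–0 ms baseline, averaged over
  the theta/alpha/beta1/beta2/gamma bands in the 50–350 ms window.
* **Resting-state networks** — phase-locking value (PLV) matrices per
  band, binarized at the top 30% of connection strengths, and the binary
  graph metrics Cp (clustering coefficient), Lp (characteristic path
  length), Eglob (global efficiency) and Eloc (local efficiency).

Channel-by-time comparisons use cluster-based permutation tests (5000
permutations in the study configuration; positive and negative clusters
each tested at 0.025, i.e. a two-tailed test at 0.05). Scalar outcomes use
ANOVA or Kruskal–Wallis behind a Shapiro–Wilk gate, with Bonferroni or
Benjamini–Hochberg (FDR) correction, and Pearson correlations link
electrophysiological change to behavioral change.

Raw recordings for such studies are typically unavailable, so the package
ships a first-class synthetic-data module that generates EEG and behavior
with the statistical structure the analysis assumes. Every stage is
validated by parameter recovery against the generator's known ground
truth.

# The synthetic generator

## Task epochs

An epoch (−200 to 800 ms around the stimulus, 1000 Hz by default) is the
sum of four components, per channel and trial:

1. **1/f background** — white noise spectrally shaped to `f^(−α/2)`
   amplitude (α = 1 by default) and scaled to 8 µV SD. This reproduces
   the broadband, aperiodic scalp background.
2. **Event-related band bursts** — for each band, a sinusoid at the band
   center with a Gaussian temporal envelope (center 200 ms, SD 80 ms) and
   a random phase per channel and trial, so the power is induced rather
   than stimulus-locked and survives trial averaging only as power, not
   as an evoked deflection. Amplitudes default to
   theta 2.5 / alpha 3 / beta1 1.2 / beta2 0.8 / gamma 0.5 µV.
3. **ERP components** — Gaussian-windowed deflections with fixed latency,
   width, signed amplitude and a Gaussian spatial topography centered on
   a focal electrode (FCz for N100/P150/N200, Cz for P300). The windows
   were chosen so each template's peak sits centrally in its reporting
   window; Gaussian templates make the windowed mean amplitude available
   in closed form for oracle tests.
4. **Phase-coupled carriers** — channels of a configured set share a
   narrowband carrier mixed with channel-private narrowband noise.

## Resting epochs

Resting data are stationary narrowband Gaussian oscillations whose phase
drifts, which matters for connectivity: a pure sinusoid would lock any
channel pair at PLV = 1. Two mechanisms shape the connectivity structure:

* **A local lattice.** Each channel's oscillation mixes the narrowband
  sources of its spatial neighbours with Gaussian distance weights
  (SD 0.35 montage units), emulating volume conduction: nearby
  electrodes phase-lock strongly, distant ones only at the finite-sample
  floor of the PLV estimator.
* **A long-range carrier.** Each channel cedes a variance fraction `v`
  to a carrier component: the shared carrier at full weight on the
  configured fronto-parietal set, and at a weaker spillover weight (0.6)
  elsewhere. `v` is set from the configured target PLV after
  compensating for the in-band share of the 1/f background (which
  dilutes phase locking), so the effective coupled-pair correlation
  approximates the target.

Raising the coupling target therefore does three things at once, matching
what stimulation-induced network integration looks like through a
proportional threshold: coupled long-range pairs strengthen (they enter
the top-30% graph), the local distance gradient flattens, and whole-matrix
mean PLV rises. In group-averaged recovery runs this reproduces the
qualitative signature of interest — mean theta PLV up, theta Eglob up,
Lp down — in ≥ 90% of seeded replicates.

The calibration of the carrier weight against the in-band noise share,
the 0.05 baseline target for long-range coupling, and the 0.6 spillover
weight were fixed empirically while designing the generator, by measuring
PLV matrices of generated data; they are study conditions of the package
and are not revisited by tests.

## Behavior

Letters A–J are drawn uniformly subject to the 2-back constraint; targets
(exactly 30% of 150 trials, rounded to the nearest trial) repeat the
letter from two trials back, non-targets are forced to differ. Responses
follow fixed hit (0.88) and false-alarm (0.06) rates, near-ceiling as
expected for healthy young adults. Reaction times are shifted-lognormal:
a 0.30 s non-decision shift plus a lognormal body with trial-level log-SD
0.25. Subject mean reaction times are drawn per arm from the published
group distributions (e.g. 5 Hz arm: 0.778 ± 0.124 s before stimulation),
and the post-session shift equals the published group change (−0.112 s
for the 5 Hz arm, −0.051 s for sham — all arms improve, reflecting
practice). The 5 Hz arm additionally carries the electrophysiological
effects: P150 + 2 µV, theta + 0.8 dB, alpha + 1 dB, theta-PLV + 0.15.

## What the generator does not emulate

No eye blinks, muscle or stimulation-pulse artifacts, no realistic
forward-model topographies (a Gaussian falloff stands in), no
between-subject variability in ERP latency or band peak frequency, no
speed–accuracy tradeoff, and no crossover session bookkeeping (arms are
simulated as independent groups, matching the between-group statistics).
Passing recovery tests therefore show that the analysis code measures
what it claims to measure under the assumed signal model — not that the
pipeline is robust to every artifact of real recordings.

# Analysis choices

* **Windowed mean, not peak.** Component amplitude is the mean over the
  window and the FC1/FCz/FC2 subset. The mean is linear in the waveform
  (so difference-wave amplitudes commute with subtraction) and far more
  noise-robust than peak picking.
* **Zero-phase filtering.** The preprocessing band-pass (Butterworth
  1–80 Hz, order 4) runs forward and backward so component latencies are
  not displaced. Trials exceeding ±100 µV on any channel are rejected.
* **Hanning window length.** Frequency-adaptive: 4 cycles per frequency,
  floored at 100 ms and capped at 400 ms. Adaptive windows keep the
  cycle count (hence variance) comparable across a 3–80 Hz span; a fixed
  length is available, and is what makes white noise spectrally flat
  across bins. Time bins whose window would leave the epoch are flagged
  invalid, never zero-padded.
* **Total power, averaged before the log.** Power is computed per trial
  and averaged across trials before dB conversion, so induced and evoked
  contributions both count and the baseline estimate is stable.
* **Band edges.** A frequency bin belongs to a band if its center lies
  in `[low, high)`; the 80 Hz top edge is closed. No bin is counted
  twice.
* **PLV estimator.** Zero-phase FIR band-pass (Hamming `fir1`, about
  1.5 cycles of the band's low edge) and the analytic-signal phase,
  fused into one FFT pass per segment with the squared magnitude
  response. The frequency-domain application is circular; 100 ms on each
  segment edge is flagged invalid and excluded. Resting PLV uses
  non-overlapping 2 s segments, PLV computed within segment and averaged.
* **Proportional threshold.** Keep `round(0.30 × n(n−1)/2)` strongest
  upper-triangle weights; ties break by weight, then lexicographic pair
  index, so graphs are platform-independent.
* **Disconnected graphs.** Lp is the mean over reachable pairs and is
  reported with a connectedness flag; Eglob treats unreachable pairs as
  zero efficiency (1/∞). A node with fewer than two neighbours has
  local efficiency 0. This keeps Lp finite without distorting Eglob.
* **Cluster statistics.** Pointwise t maps (paired or pooled-variance
  independent), cluster-forming threshold at the two-sided 0.05 t
  quantile, spatio-temporal connectivity via montage adjacency at equal
  time and temporal contiguity on a channel, clusters with fewer than
  two distinct electrodes discarded, mass = sum of t, and a max-mass
  permutation null (sign flips for paired designs, label reshuffles for
  independent ones) with the add-one Monte Carlo correction. Positive
  and negative clusters are tested separately at 0.025. Between-arm
  comparisons run the independent-design test on subject-level
  post-minus-pre difference maps.
* **Channel adjacency.** Electrodes are neighbours within a radius of
  1.3 × the median nearest-neighbour distance, enlarged when needed to
  just past every channel's second-nearest neighbour so no electrode has
  fewer than two neighbours (a single-neighbour electrode could anchor
  only one cluster pair). On the default montages this yields 2–8
  neighbours per channel.
* **Change index sign.** The index is reported as `(pre − post)/pre`, so
  a reaction-time reduction is positive, matching the sign convention of
  published group tables; a `literal` flag gives `(post − pre)/pre`.
  Group summaries average per-subject indices (mean of ratios), not the
  ratio of group means.
* **d′ extreme-rate correction.** Rates of 0 and 1 are replaced by
  `0.5/n` and `(n − 0.5)/n` before the inverse-normal transform. The
  correction is symmetric, preserving d′ antisymmetry.
* **Normality gating.** If Shapiro–Wilk rejects at 0.05 in any group,
  scalar comparisons route to Kruskal–Wallis / Wilcoxon signed-rank.

# Replication problem sizes

The default configuration reproduces the study conditions (1000 Hz, 150
trials, 30 subjects per arm, 32-channel montage — the montage is kept at
32 of the 61 available 10-10 positions so a full study fits comfortably
in memory; the channel count is configurable up to 61). Validation
simulations in the test suite and the reproduction script use reduced
sizes chosen to give stable Monte Carlo estimates at desk scale: 250 Hz
sampling, 8–16 channels, 12–60 trials, 8–10 subjects per group, 500
permutations for calibration (scaled down from the study's 5000) and 200
for recovery runs. The vignette-level claims (null calibration within the
binomial confidence band, ≥ 90% recovery of the injected P150, alpha and
theta-PLV effects) are exactly what `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R` compute at those sizes.

# Known limitations

* The cluster test controls family-wise error for one map at a time; the
  report does not correct across the many maps it contains (bands ×
  arms), mirroring common practice.
* Lp on disconnected graphs is not monotone under edge addition (a new
  edge can make distant pairs reachable and lengthen the average); the
  connectedness flag should be consulted before interpreting Lp.
* The PLV floor at 2 s segments is substantial (≈ 0.3 in theta); PLV
  values are comparable within a configuration, not across segment
  lengths.
* The generator's "target PLV" is the asymptotic carrier correlation
  after noise compensation, not the finite-sample PLV estimate, which
  sits above it by the estimator floor.
* EDF import/export is not provided; epochs enter either from the
  generator or from the package's documented RDS + JSON container.
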