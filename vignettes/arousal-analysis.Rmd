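---
title: "Methods: arousal-dependent thalamic activity from pupil, LFP and spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arousal-dependent thalamic activity from pupil, LFP and spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilstate)
```

`pupilstate` quantifies how lateral geniculate nucleus (LGN) neurons follow
spontaneous arousal fluctuations within wakefulness. Two observable proxies
define the brain state: the pupil (dilated in active wakefulness, AW;
constricted in quiet wakefulness, QW) and the visual-cortical LFP
(desynchronized in AW; large 3–6 Hz oscillations in QW). This vignette
explains the models and conventions behind each stage, the parameters that
matter, and the choices made where the methods left the design open.

## The synthetic-session generator

All tests and examples run on sessions from `generate_session()`, which
produces coupled components with full ground truth. What it emulates, and
the conditions its defaults encode:

* **States.** A semi-Markov alternation of QW and AW with uniform dwell
  draws (default 4–8 s each; QW never below the 3 s detector minimum). No
  empirical dwell distribution is asserted by the methods this package
  implements, so uniform draws are the least-structured choice; ranges are
  configurable. Each QW epoch carries one oscillation frequency drawn from
  3–6 Hz, shared by the LFP and the burst generator so rhythm and bursts
  stay phase-consistent.
* **LFP.** QW epochs contain an amplitude-modulated sinusoid calibrated so
  the per-cycle peak-to-peak amplitude is 0.77 mV; AW epochs contain
  broadband (1–30 Hz) noise rescaled, using the same windowed peak-to-peak
  measurement the analysis applies, to 0.27 mV. These are the group-mean
  amplitudes the analysis is expected to reproduce.
* **Pupil.** First-order relaxation (τ = 1 s) toward state plateaus
  (QW 10 px, AW 16 px on the default 64 px frame), plus a slow sinusoidal
  drift (0.5 px) and white measurement noise (0.1 px). The underlying
  methods report no pupil dynamics, so range and time constant are free,
  realistic parameters chosen once.
* **Spike trains.** TC cells: tonic Poisson firing at 20.1 Hz in AW; in QW,
  bursts (2–4 spikes, first ISI ~3.4 ms, all intra-burst ISIs ≤ 10 ms)
  locked to the oscillation peaks with a probability set so the mean QW
  rate is 6.2 Hz. Interneurons: tonic Poisson with the opposite modulation
  (defaults 15 Hz QW / 6 Hz AW; the methods report the inversion but not
  numeric rates). Waveform templates are a negative Gaussian trough plus a
  positive after-peak: broad for TC (0.44 ms trough-to-peak, height ratio
  0.41) and narrow/biphasic for interneurons (0.23 ms, 0.73).
* **Membrane potential.** The subthreshold baseline is an affine map of the
  pupil delayed by 5 s, spanning −63.0 mV (QW) to −59.1 mV (AW); Poisson
  EPSPs (18 Hz, fixed 2 mV double-exponential kernel) are added
  independently of state; action potentials are superimposed at the TC
  spike times; colored noise (0.1 mV, ≤ 500 Hz) completes the trace. The
  pure-delay-plus-affine coupling is deliberately minimal: only a lag and
  two state means are specified by the methods.
* **Eye video.** A dark pupil disc (intensity 0.15) on a brighter iris disc
  over a mid-gray background, with slow centroid jitter, pixel noise, and
  all-black synchronization frames at a configurable interval. The iris is
  rendered with a radial shading (0.85 at the pupillary margin falling to
  0.55 at the outer edge). This gradient is not cosmetic: with an exactly
  uniform iris, the equal-area ring/disc construction makes the contour
  energy *flat* in the radius between the pupil edge and the iris edge, so
  the radius would be unidentifiable on idealized frames. A graded
  surround — which real infrared iris images possess in the form of
  texture and shading — is the minimal realism that gives the energy a
  unique optimum.

What the generator does **not** emulate: blinks, eye movements, corneal
reflections, NREM/REM sleep epochs, biophysical membrane dynamics, multiple
simultaneous units per channel, or electrode drift. Passing tests therefore
demonstrate correctness of the algorithms under clean, known-truth
conditions, not robustness to every artifact of real recordings.

## Pupil tracking

The contour ("snake") is an inner disc of radius $r$ at $(c_x, c_y)$ with a
concentric ring of outer radius $\sqrt{2}\,r$, so ring and disc always have
equal area. Its energy on the inverted frame is

$$E = \sum_{\text{ring}} I \;-\; \sum_{\text{disc}} I,$$

zero in expectation on uniform images and minimal when the disc covers the
(bright, inverted) pupil with the ring on the darker iris.

Numerical conventions:

* **Pixel membership** is fractional at the boundaries: a pixel at distance
  $d$ contributes to the disc with weight $\mathrm{clip}(r - d + 1/2, 0, 1)$
  (and analogously at the outer radius). Hard membership by center distance
  was tried first and leaves a systematic ~0.7 px radius bias against
  soft-edged pupils; the fractional weights are the proper sub-pixel
  discretization of the continuous region integrals and bring the maximum
  radius error on rendered frames below 1 px.
* **Inversion** is a linear, monotone-decreasing map anchored so the mean of
  a user-chosen iris reference rectangle goes to 0 and the darkest frame
  pixel to 1, clipped at the bright end only. Clipping the dark end as well
  would flatten all structure brighter than the reference to a single
  level, and a flat surround re-creates the radius-degeneracy described
  above whenever the reference sits in the outer iris.
* **Optimization** is greedy coordinate descent over $(c_x, c_y, r)$ with an
  annealed step schedule (4, 2, 1, 0.5, 0.25 px; move budget 200). Moves
  are accepted only on strict energy decrease, so the energy trace is
  non-increasing and the result never exceeds the initial energy. On
  64×64 frames the final energy matches an exhaustive integer grid search
  within 1%, which the test suite asserts on 50 frames.
* **Tracking** seeds frame 1 from a user-supplied contour (the manual
  initialization of interactive workflows) and each later frame from the
  previous non-black frame. Black synchronization frames are detected by
  mean intensity ≤ 2% of full scale (inclusive at the threshold), flagged,
  and skipped. A black first frame is an error, since nothing can seed it.

## State segmentation

QW is any period of at least `min_qw_s = 3` s during which the 3–6 Hz
envelope exceeds `thresh_factor = 2` times a baseline level; everything
else is AW. Implementation choices:

* **Envelope**: magnitude of the FFT analytic signal of the zero-phase
  band-passed trace (order-2 Butterworth, forward–backward, so transition
  times carry no group delay).
* **Smoothing**: the instantaneous envelope of band-limited noise has heavy
  (Rayleigh) tails whose brief excursions chatter across any threshold. A
  0.3 s running *median* removes them without spreading epoch edges the
  way a linear smoother does (a 2 Hz low-pass was tried and widened epochs
  by ~0.8 s per side).
* **Baseline**: the 0.40 quantile of the smoothed envelope over the whole
  recording. This was calibrated once over quantiles {0.25, 0.40, 0.50} ×
  bridging {0.2, 0.5 s} against two requirements: no false QW on
  pure-noise sessions and high label recovery on generated sessions. The
  0.40 quantile satisfies both (0 false QW, 98% median agreement); the
  median is unstable when QW occupies about half the recording (the
  envelope distribution is bimodal and the median can land in the QW mode,
  collapsing recovery), and 0.25 is low enough that noise excursions chain
  across the threshold on quiescent recordings.
* **Bridging**: sub-threshold gaps shorter than 0.5 s between
  supra-threshold runs are bridged before the 3 s test, emulating
  semi-automated threshold cleanup; configurable.
* **Transition refinement** moves each AW→QW time to the first positive
  band-passed-signal peak inside the QW epoch and each QW→AW time to the
  last one. Peaks must exceed half the epoch's median band envelope, so
  filter onset smear is not mistaken for the first cycle; epochs with no
  qualifying peak keep their coarse time and are flagged.
* **Degenerate input**: a constant trace yields a single AW epoch with a
  warning.

A 2 s supra-threshold burst is rejected by the minimum-duration rule. Note
that at extreme contrast (envelope hundreds of times the threshold) the
band-pass ring-down itself can hold the envelope above a very low threshold
for a few hundred milliseconds on each side — a property of any band-pass
detector, which is why the edge-case tests use moderate-contrast bursts, the
regime the 2× rule describes.

## Spike analysis

* **Waveform features**: duration is trough-to-subsequent-peak of the mean
  waveform; the height ratio is after-peak amplitude over trough amplitude,
  both from baseline (mean of the first waveform quarter). A waveform
  without a negative trough followed by a positive peak (e.g. reversed
  polarity) is an error. Classification: interneuron below
  `duration_thresh_ms = 0.35` (0.3 is the alternative convention and is
  configurable), TC at or above it — ties go to TC.
* **Bursts**: maximal clusters of ≥ 2 spikes with all ISIs ≤ 10 ms,
  mutually separated by > 100 ms measured edge-to-edge; clusters violating
  the separation are both rejected, and single spikes are never bursts.
  The detector is asserted to agree exactly with an independent brute-force
  enumerator on 1000 random trains.
* **Burst subtype**: LTS below `isi_cut_ms = 5` (midway between the
  reported LTS ≈ 3.4 ms and HT ≈ 8.2 ms class means), HT above it; when a
  pre-burst membrane potential is available it must agree
  (below/above `vm_cut_mV = -60`), otherwise the burst is unclassified. A
  first ISI exactly at the cut is unclassified — the cut is a heuristic
  midpoint, and claiming either class at the boundary would overstate it.
* **Modulation index**: $\mathrm{MI} = (F_{AW} - F_{QW})/(F_{AW}+F_{QW})$,
  +1 when the cell is silent in QW, −1 when silent in AW, an error when
  both rates are zero.
* **PETH** bins are half-open $[t, t+\Delta)$ and reported in Hz
  (counts / events / bin width); the autocorrelogram excludes zero-lag
  self-pairs and is symmetric by construction.
* **EPSP detection**: slope threshold (default 1.5 mV/ms) on the smoothed
  trace plus a minimum 3 ms rise of 1 mV, a 3 ms refractory merge, and a
  ±2 ms exclusion mask around action potentials (samples above −40 mV)
  plus a 50 ms filter-settle margin at the trace ends. Per-state rates are
  dead-time corrected: masked time is removed from each state's
  denominator. Without this correction the higher AW spike rate masks more
  AW time and biases the QW/AW rate ratio upward by ~15%, which would
  spuriously break the planted state-independence.

## Correlation statistics

* **Alignment**: firing rates are binned at 1 s (pupil dynamics are
  multi-second) and the pupil is interpolated to bin centers; black-frame
  gaps are interpolated when shorter than 2 s, otherwise the bins are
  dropped from both series. At least 10 overlapping bins are required.
* **Permutation test**: the null is built from `n_perm = 1000` random
  re-pairings of the two series, each yielding a Pearson r. The original
  wording of this procedure ("two data points were randomly selected and
  paired up … repeated 1000 times") is ambiguous between re-pairing and a
  bootstrap of single pairs; re-pairing is the reading that makes
  "compare the observed r to the random distribution" well defined, and
  the literal bootstrap-of-pairs variant ships behind
  `method = "pair_bootstrap"`. Significance: the observed r outside the
  central 95% band of the null; the two-tailed p uses the add-one
  permutation estimator so p is never exactly 0. Calibration is asserted
  by test: the empirical type-I rate at the 95% band over 1000 null
  sessions of 200 bins lies in [0.03, 0.07], and power at a planted
  r = 0.4 exceeds 0.95. Serial dependence in real binned series inflates
  permutation significance; a conservative block-permutation mode
  (`block_s`) is provided.
* **Modulation classes**: positive/negative only when significant,
  otherwise uncorrelated. Tercile masks are rank-based lower/upper thirds;
  a constant pupil distribution is an error.
* **Vm–pupil lag**: both series are zero-phase low-passed at 0.5 Hz,
  z-scored, and cross-correlated; the lag at the maximum is reported,
  positive when the membrane potential follows the pupil. The
  cross-correlogram is averaged over 60 s half-overlapping segments
  (Welch style): on a single whole-session correlogram the quasi-periodic
  state alternation produces an echo at (lag − alternation period) that
  occasionally exceeds the true peak (3 of 50 test sessions locked onto
  ≈ −7.7 s); segment averaging dephases the echo while the true peak adds
  coherently, recovering 5.0 ± 0.2 s on all 50. A maximum at the search
  window edge is flagged unreliable. Lag recovery is tested on 180 s
  sessions — roughly 15 state cycles, the size at which the averaged
  correlogram is stable; on 60 s sessions single-session estimates scatter
  by ±1 s.
* **Condition comparison** pairs per-neuron correlation values across two
  conditions and delegates the significance test to the standard paired
  Wilcoxon signed-rank routine; mismatched neuron sets are an error.

## Pipeline and reproducibility

`run_pipeline()` composes the stages (simulate/load → track → segment →
spikes → Vm → figures → summary), logs every stage and parameter, and
writes a JSON summary that is a pure function of `(config, seed)` — reruns
are bit-identical. Every random draw in the package goes through a seed
derived deterministically from the master seed, and seeded helpers restore
the caller's RNG state. Defaults in `validate_config()` equal the stated
analysis conventions (3 s, 2×, 3–6 Hz, 10 ms/100 ms, 0.35 ms, terciles,
1000 permutations, 95% band).

Problem sizes used by the test suite, chosen as the smallest at which each
estimate is stable: 60 s sessions for segmentation recovery (20 seeds),
a 30 s / 50 fps video for end-to-end tracking, 200-bin series for
permutation calibration (1000 null sessions), and 180 s sessions for lag
recovery (50 seeds).

## Known limitations

* The tracker assumes a single dark, roughly circular pupil without
  occlusion; blinks and corneal reflections are out of scope.
* The segmentation threshold is a global statistic of the recording; slow
  nonstationarity of the noise floor would require an adaptive baseline.
* The radius estimate carries a small (< 1 px) positive bias from the
  interaction of the contour energy with the graded iris; it is constant
  within a session and does not affect correlation-based statistics.
* Permutation significance assumes exchangeable bins; with strongly
  autocorrelated firing the default test is anticonservative (use
  `block_s`).
* Burst subtyping thresholds (5 ms, −60 mV) are documented heuristics at
  class midpoints, not fitted boundaries.
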