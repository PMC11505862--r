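---
title: "Phase-amplitude coupling diagnostics for HD-sEMG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-amplitude coupling diagnostics for HD-sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pacemg)
```

## The problem

Lateral epicondylitis ("tennis elbow") is a degenerative tendinopathy of the
forearm extensor origin. High-density surface EMG (HD-sEMG) records the
electrical activity of the affected muscles noninvasively — here, seven
single-differential channels for each of four forearm muscles (ECR, EDC, ECU,
FCR) at 2048 Hz. The hypothesis this package operationalises is that the
disorder leaves a signature in *cross-frequency coupling*: the phase of a
low-frequency rhythm modulates the amplitude envelope of higher-frequency
muscle activity (phase-amplitude coupling, PAC), and this dependence separates
patients from controls where conventional amplitude and spectral features do
not.

The package implements the full analysis chain — preprocessing, three feature
families, class-separability screening, a feedforward classifier under
leave-one-subject-out (LOSO) validation with subject-level probability
aggregation, and a diagnostic-statistics stack — together with a seeded
synthetic cohort generator that stands in for the clinical recordings, which
are not public.

## Preprocessing

Signals are band-pass filtered to 20–450 Hz with a second-order Butterworth
design. Filtering is zero-phase by default (forward–backward, so the
effective order doubles and group delay cancels); analysis is offline, so
causality is irrelevant, and zero phase matters because the Morlet *phase* is
the object of study. A single causal pass is available via
`filter_spec(zero_phase = FALSE)`.

Channels flagged as bad are removed (`drop_bad_channels()`); a subject is
rejected only if *every* channel is flagged. Retained channels are cut into
non-overlapping 500 ms epochs (1024 samples at 2048 Hz); the trailing
remainder is discarded. The unit of analysis is the (channel, epoch) row:
per-channel rows keep variable bad-channel counts harmless and match the
row-count bookkeeping a per-subject test set of several thousand rows
implies. An overlap fraction is exposed for sensitivity studies but defaults
to zero.

## Phase-amplitude coupling

A complex Morlet wavelet `exp(i 2 pi f t) exp(-t^2 / (2 sigma_t^2))`,
truncated at four envelope s.d. and normalised to unit L2 energy, supplies at
each frequency an amplitude envelope (modulus) and an instantaneous phase
(argument). The width parameter 7 is interpreted as *cycles*:
`sigma_t = 7 / (2 pi f)`, i.e. a spectral s.d. of `f / 7`. A literal
7-second (or 7-sample) Gaussian would be physically meaningless across a
1–350 Hz axis at 2048 Hz; the cycles reading is the standard one, and an
absolute-seconds mode is kept for completeness
(`morlet_params(sigma_mode = "seconds")`).

Coupling between a phase frequency `f_p` and an amplitude frequency `f_a` is
the magnitude-squared Welch coherence between the real phase carrier
`cos(arg W(f_p, t))` and the envelope `|W(f_a, t)|` — the cosine makes the
coherence a well-defined statistic between two real series — estimated with
256-sample Hann segments at 50% overlap and read off at the Welch bin nearest
`f_p`. Evaluating a grid of `(f_p, f_a)` pairs (default phase 2–30 Hz step
2, amplitude 30–350 Hz step 10, cells with `f_a <= f_p` masked) yields the
comodulogram; row-major flattening with stable `PAC_<fp>_<fa>` names turns it
into a feature vector.

A 500 ms epoch can neither resolve a 10 Hz phase rhythm nor give more than
one Welch segment, so PAC is estimated on longer per-channel windows:
consecutive epochs are concatenated into 4 s blocks and each epoch inherits
its block's comodulogram. This windowing is the largest interpretive gap in
the chain — computing PAC "per segment" from 1 Hz with a 7-cycle wavelet on
500 ms segments is not simultaneously satisfiable, so both the windowed mode
and a short-window fallback (Welch segments shrunk when fewer than two fit)
are implemented, and neither is claimed to be the original computation.
Frequencies whose truncated wavelet support exceeds the analysis window are
dropped with a warning (at 4 s this removes the 2 Hz phase row).

## Classic and wavelet features

The sixteen classic features (RMS, v-order, log detector, MAV, MYOP, ZC, SSC,
WAMP, temporal moments 3–5, waveform length, DASDV, square integral, mean and
median frequency) are computed per epoch, vectorised across rows. Choices the
formulas leave open:

* v-order and the log detector use `|x|`; fractional powers and logarithms of
  negative samples are undefined, and the source literature rectifies first.
* The log detector's default is the classical geometric mean
  `exp(mean(ln |x|))`; the literal mixed-base form `e^(mean(log10 |x|))` is
  kept as an option because the defining text states both.
* TM3 and TM5 take absolute values (their defining section is titled
  "absolute value of the ... temporal moment" even though the formulas print
  none).
* The zero-crossing gate combines a negative adjacent product with an
  adjacent difference of at least the threshold — the standard reading of the
  mixed condition.
* The spectrum estimator is the full-epoch periodogram with the DC bin
  excluded; MDF is the first bin where cumulative power reaches half the
  total.
* Thresholds (default 0.01) are applied in raw amplitude units with no
  normalisation, as stated.

Wavelet features use the orthogonal 8-tap Daubechies wavelet with four
vanishing moments (db4) to level 4 with *periodized* boundaries, which makes
energy conservation and perfect reconstruction exact and testable
(symmetric-ish alternatives trade that away). At 2048 Hz the subbands are A4
0–64, D4 64–128, D3 128–256, D2 256–512, D1 512–1024 Hz. The scalar taken
per subband is deliberately configurable — the source never states its
wavelet feature set's dimensionality — with RMS and MAV of the coefficients
as the documented default (10 columns, order A4, D4, D3, D2, D1).

## Separability and the classifier

Class separability is screened per feature with the univariate Gaussian
Bhattacharyya distance and its bounded Jeffries–Matusita transform
`JM = 2(1 - exp(-D_B))` in [0, 2). One scalar per feature *set* is needed for
set-level comparisons; the reduction is unstated in the source, so the mean
over features is the default and max/median are reported alongside. JM is
computed on the training rows of each LOSO dataset, matching per-dataset
reporting.

The classifier is a feedforward network: four hidden layers of 128 ReLU
units, 0.2 dropout after each, sigmoid output, binary cross-entropy, batch
32, exactly 20 epochs. Unstated pieces chosen here: Adam at learning rate
1e-3 (the field-default adaptive method), per-feature z-scoring fitted on
training rows only (networks of this depth need standardised inputs; raw
mode available), He/Xavier initialisation, no early stopping (fixed epochs as
printed). Training runs in single precision in compiled code, single-threaded
and fully determined by the seed.

LOSO construction: one dataset per subject; the held-out subject's rows form
the test set and never touch training or validation; the remaining rows are
split 80/20 *at the row level* (the source splits rows, not subjects, for
validation). A subject's diagnosis is the mean of its epoch probabilities
against a 0.5 cutoff; an exact tie is called a case (favouring sensitivity)
and flagged. The random-label control permutes the subject-to-group map
before the whole LOSO loop, so no true signal can survive.

## Evaluation statistics

Sensitivity, specificity and accuracy come with Wald (normal-approximation)
binomial intervals on the percent scale, clipped to [0, 100] — this is the
interval that reproduces the published bracketed bounds digit for digit;
Clopper–Pearson is available. The diagnostic odds ratio and the
prevalence-adjusted ("unbiased") positive predictive value summarise clinical
usefulness at population prevalences (1–3% for this condition). McNemar's
test defaults to the exact binomial form (28 subjects is small) with Cohen's
g on the discordant pairs; Friedman (average ranks, tie-corrected; constant
inputs give statistic 0 and p 1) and one-sided Wilcoxon signed-rank tests
(exact for n ≤ 30 without ties, else tie-corrected normal approximation)
with rank-biserial effect sizes compare feature sets, with Bonferroni
multipliers applied by the caller for the three pairwise comparisons.
Mean-probability intervals use normal theory at 99.9%; the Bayesian interval
treats thresholded epoch predictions as Bernoulli draws under a Beta prior
(uniform by default, configurable) and reports the *equal-tailed* posterior
interval — the published lower bound at k = n matches the equal-tailed form.
The AUC-based sample size uses the Hanley–McNeil variance with
`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; only the software used was named in the
source, and this formula reproduces the published n = 13 per group
(n = 12 fails the power condition, n = 13 meets it).

## The synthetic world

`simulate_cohort()` emulates what the pipeline assumes about the real
recordings: 2048 Hz, 20–450 Hz band-limited Gaussian background, four
muscles × seven channels, per-subject exercise durations drawn uniformly
from 9.1–95.9 s, two groups of 14, a ~12% bad-channel rate, and — in cases —
phase-amplitude coupling injected into ECR and EDC at strength m (default
0.8) with 2% relative per-subject jitter on (f_p, f_a, m).

Three generator choices deserve explanation:

* **The pacing rhythm is part of the signal.** A purely multiplicative
  coupled component `(1 + cos(2 pi f_p t))/2 * cos(2 pi f_a t)` has spectral
  energy only at `f_a` and its sidebands — nothing at `f_p` — so the Morlet
  phase at `f_p` would be noise-driven and no phase-amplitude estimator could
  recover the coupling, even in principle. Real PAC consists of a
  low-frequency rhythm *plus* high-frequency activity locked to its phase,
  and simulation practice in the coupling literature follows that form. The
  injected component is therefore
  `m * rms * [0.5 cos(2 pi f_p t + phi) + (1 + cos(2 pi f_p t + phi))/2 * carrier]`,
  which makes the deterministic coherence at the true pair ≈ 1 and
  parameter recovery testable. The composite channel is band-limited before
  the final rescale, so the 10 Hz rhythm enters attenuated through the 20 Hz
  band edge — exactly as sub-band content survives a hardware front end —
  and >95% of every channel's power stays inside 20–450 Hz.
* **Controls are spectrum- and amplitude-matched.** Every channel is
  rescaled to the target RMS after injection, which removes whole-epoch
  amplitude information; but an injected carrier also *redistributes* band
  power, and that alone lets spectral features classify subjects perfectly
  after averaging hundreds of epochs. Because the stated purpose of the
  stand-in world is that classic features are matched across groups while
  the coupling separates them, control subjects receive the same pacing
  rhythm plus an *unmodulated* carrier of equal average power
  (`sqrt(3/8)` of the modulated carrier's peak factor). Only the
  phase-amplitude dependence then distinguishes the groups: measured on the
  scaled cohort, PAC features reach subject accuracy 1.00 while classic
  features reach ≈ 0.43 — the direction and rough magnitude of the published
  contrast. `control_carrier = "none"` restores plain-noise controls; under
  that variant the band-power residue is real, and it is there that the
  published three-way separability ordering JM(PAC) > JM(wavelet) >
  JM(classic) is reproduced (under matched controls the wavelet RMS/MAV
  summaries lose their signal *by construction*, which the tests state
  honestly rather than paper over).
* **Scale and units.** The target RMS defaults to 0.2 (mV scale): large
  enough that the fixed 0.01 amplitude threshold of MYOP/ZC/SSC/WAMP sits in
  its sensitive range (at much smaller scales the SSC slope-product gate
  saturates at zero and the feature degenerates), and typical of
  surface-EMG amplitudes during moderate contraction.

What a green test on this world establishes: that the estimator recovers
injected coupling through the full pipeline, that no subject-level leakage
occurs, and that the feature-family ordering has the published direction. It
does **not** establish anything about real electrophysiology — the synthetic
spectrum is an assumption (the source characterises its hardware band, not
its spectral shape), there are no motor-unit action potentials, no fatigue
dynamics, no within-recording nonstationarity, and the published headline
numbers (100%/100% sensitivity/specificity on clinical data) are not
reproducible from a simulator and are not claimed.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses odd-reflection padding with matched initial
  conditions (step-response steady state), so constant inputs map to
  constants and edge transients are suppressed.
* Coherence is clipped to [0, 1]; a zero-power bin yields 0 rather than NaN.
  At least two Welch segments are required — a single segment's coherence is
  identically 1.
* Zero samples are floored at machine epsilon inside the log detector; an
  all-zero epoch is rejected by the spectral features (undefined ratio).
* A feature with zero class variance raises an error naming the feature
  rather than silently producing an infinite separability.
* Exact-tie diagnoses (mean probability exactly 0.5) are called cases and
  flagged.
* Seeds: every stochastic step (cohort, per-subject streams, splits,
  initialisation, dropout, permutations) derives from explicit integer seeds
  kept below 2^31; per-subject seeds are a documented hash of the cohort
  seed and subject index so any subject is regenerable in isolation.

## Scaled-down testing

The test suite runs the full pipeline on a reduced cohort — 14 + 14 subjects
at a fixed 20 s, two channels per muscle, no bad channels, and a PAC grid
restricted to the coupling neighbourhood (phase 8/10/12 Hz × amplitude
130/150/170 Hz) — purely to fit a CI budget; generator physics, coupling
strength and all thresholds are the defaults of the stated world. Coupling
recovery is tested on 8 s analysis windows (the estimator's accuracy
improves with window length; 4 s sits at the edge of the 90% recovery bar at
the weakest stated coupling).

## Known limitations

* The PAC windowing is one defensible reading of an under-specified
  computation; absolute comodulogram values depend on it (relative structure
  is robust).
* The wavelet feature set's dimensionality in the source is unknown; the
  RMS/MAV default is a choice, applied consistently across JM and the
  classifier.
* The published McNemar adjusted p = 0.147 and Cohen's g = 0.9 are not
  recoverable from standard McNemar definitions on the published per-subject
  tables; the package implements the standard definitions.
* EDF output round-trips through 12-bit quantization; CSV is the bit-exact
  interchange format.
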