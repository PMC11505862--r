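# pacemg

Phase-amplitude coupling (PAC) features and subject-level diagnostics for
high-density surface electromyography (HD-sEMG).

Surface EMG records muscle electrical activity noninvasively; with many
closely spaced electrodes (here, 7 single-differential channels on each of
four forearm muscles at 2048 Hz) it becomes a candidate screening signal for
neuromuscular disorders such as lateral epicondylitis ("tennis elbow"). This
package implements an analysis chain built around the idea that the disorder
shows up as *cross-frequency coupling* — the phase of a low-frequency rhythm
modulating the amplitude envelope of higher-frequency activity — rather than
in conventional amplitude or spectral features:

* **Preprocessing** — 20–450 Hz second-order Butterworth band-pass
  (zero-phase by default), bad-channel removal, 500 ms epoching.
* **PAC features** — complex Morlet transform (7-cycle wavelets, unit
  energy); coupling of a pair (f_p, f_a) is the Welch magnitude-squared
  coherence between `cos(arg W(f_p, t))` and `|W(f_a, t)|`, evaluated at the
  bin nearest f_p; a grid of pairs gives the comodulogram, flattened into
  named `PAC_<fp>_<fa>` columns.
* **Classic features** — the sixteen standard time/frequency-domain EMG
  features (RMS, v-order, log detector, MAV, MYOP, ZC, SSC, WAMP, temporal
  moments 3–5, waveform length, DASDV, square integral, MNF, MDF).
* **Wavelet features** — orthogonal periodized db4 decomposition to level 4
  with per-subband RMS/MAV summaries.
* **Separability** — per-feature Bhattacharyya distance
  `D_B = 1/4 ln[1/4 (s_p/s_q + s_q/s_p + 2)] + 1/4 (mu_p-mu_q)^2/(s_p+s_q)`
  and Jeffries–Matusita distance `JM = 2(1 - e^-D_B)` in [0, 2).
* **Classifier** — feedforward network (4 × 128 ReLU, 0.2 dropout, sigmoid,
  binary cross-entropy, Adam, batch 32, 20 epochs) under leave-one-subject-out
  validation; a subject's diagnosis is its mean epoch probability against a
  0.5 cutoff.
* **Evaluation** — Se/Sp/Acc with Wald intervals, diagnostic odds ratio
  `DOR = Se·Sp / ((1-Se)(1-Sp))`, prevalence-adjusted PPV
  `Se·prev / (Se·prev + (1-prev)(1-Sp))`, McNemar/Cohen's g,
  Friedman and one-sided Wilcoxon tests with rank-biserial effect sizes,
  99.9% mean-probability and Beta-posterior credible intervals, and
  Hanley–McNeil AUC-based sample size.
* **Synthetic cohorts** — a seeded generator of two-group HD-sEMG cohorts
  with injectable coupling of known (f_p, f_a, m), standing in for the
  non-public clinical data; amplitude and band-power structure are matched
  across groups so that only the phase-amplitude dependence separates them.

## Worked example

A small spectrum-matched cohort (4 cases + 4 controls, 10 s each, two
muscles, coupling injected into ECR only), with both PAC and classic
features through the full LOSO pipeline:

```r
library(pacemg)
cfg <- run_config(
  sim = sim_config(n_cases = 4, n_controls = 4, duration_s = 10,
                   muscles = c("ECR", "FCR"), channels_per_muscle = 2,
                   coupled_muscles = "ECR", bad_channel_rate = 0, seed = 7),
  feature_sets = c("classic", "pac"),
  pac_phase_freqs = c(8, 10, 12), pac_amp_freqs = c(130, 150, 170),
  seed = 7, out_dir = tempfile())
res <- run_pipeline(cfg)
res$runs$pac$subject_accuracy      # 1
res$runs$classic$subject_accuracy  # 0
round(mean(res$jm$pac), 3)         # 1.244
round(mean(res$jm$classic), 3)     # 0.004
res$runs$pac$summary
#   subject_id true_label predicted_label mean_prob
# 1        p01       case            case     0.692
# 2        p02       case            case     0.594
# 3        p03       case            case     0.619
# 4        p04       case            case     0.652
# 5        s01    control         control     0.130
# 6        s02    control         control     0.205
# 7        s03    control         control     0.171
# 8        s04    control         control     0.429
```

Every held-out subject is diagnosed from its mean epoch probability: PAC
features separate all eight subjects (JM ≈ 1.24 of a possible 2), while the
sixteen classic features — amplitude- and spectrum-matched by construction
in this simulator — carry almost no class signal (JM ≈ 0.004) and mislabel
every subject. The corresponding cohort metrics for the PAC run print as
`Se 100%  Sp 100%  Acc 100%  DOR Inf  PPV(3%) 100%`.

`run_pipeline()` writes the resolved config, cohort manifest, feature
tables, per-dataset JM report, per-subject diagnoses and the metrics report
(Wald CIs, DOR, unbiased PPV at the configured prevalences, 99.9% intervals)
into the run directory.

## Acceptance script

`scripts/acceptance.R` recomputes, with the installed package, the
evaluation-arithmetic quantities that are checkable from published numbers —
diagnostic odds ratios and prevalence-adjusted PPVs of the published
operating points at 1% and 3% prevalence, and the AUC-based per-group sample
size (one-sided alpha 0.05, power 0.95, AUC 0.7 vs 0.95) — and writes them
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/pac-emg-methods.Rmd`) documents the models
and their assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, the
numerical choices, and known limitations.
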