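# tcdqeeg

Multimodal bedside prognostics for **large hemispheric infarction (LHI)** —
ischemic stroke covering at least two-thirds of one middle-cerebral-artery
territory. Patients with LHI die within 90 days in roughly a third to two-thirds
of cases, and serial imaging is often impractical in a neuro-ICU. Two
non-invasive bedside modalities carry prognostic signal instead:

* **Quantitative EEG (QEEG)** — as cerebral blood flow falls, fast (alpha/beta)
  activity is lost and slow (delta/theta) activity grows;
* **Transcranial Doppler (TCD)** — ultrasound measurement of cerebral
  blood-flow velocity identifies the *offending vessel* (proximal internal
  carotid artery, terminal ICA, or MCA) and grades residual flow.

`tcdqeeg` implements the full analysis chain that combines these with the
Glasgow Coma Scale (GCS) into a 90-day survival model, plus synthetic-data
generators with known ground truth so that every stage is testable without
patient data. It is aimed at methods researchers in clinical neurophysiology
and biostatistics who want a reproducible, end-to-end testable version of this
kind of multimodal prognosis analysis.

## What it computes

**QEEG branch** (`select_segments`, `welch_psd`, `relative_band_powers`,
`spectral_ratios`, `compute_bsi`, `compute_qeeg_indices`): Welch power
spectral density per channel (2-s Hamming windows, 50% overlap, 0.5 Hz
resolution, 1–30 Hz), relative band powers over delta (1–3 Hz), theta
(4–7 Hz), alpha (8–13 Hz) and beta (14–30 Hz),

- RDP, RTP, RAP, RBP — band power as a fraction of total 1–30 Hz power,
- DAR = P(δ)/P(α), DTABR = (P(δ)+P(θ)) / (P(α)+P(β)) — slowing indices,
- BSI = mean over homologous channel pairs *m* and frequency bins *f* of
  |(R<sub>mf</sub> − L<sub>mf</sub>)/(R<sub>mf</sub> + L<sub>mf</sub>)| —
  the pairwise-derived brain symmetry index in [0, 1].

**TCD branch** (`extract_envelope_measures`, `classify_tibi`,
`classify_offending_vessel`): systolic/diastolic/mean velocities
(Vm = (Vs + 2 Vd)/3), Gosling pulsatility index PI = (Vs − Vd)/Vm,
Thrombolysis-in-Brain-Ischemia (TIBI) flow grading 0–5, and a rule-based
classifier for the offending vessel from TIBI-by-depth patterns and
collateral findings (ACoA cross-filling, PCoA collateral flow, reversed
ophthalmic artery flow).

**Statistics and modelling** (`pearson_chi2`, `compare_groups`,
`dichotomize`, `cox_fit`, `backward_select`, `km_fit`, `logrank_test`,
`fit_logistic`, `roc_auc`, `delong_compare`, `youden_operating_point`):
baseline group comparisons (Student's t / Mann–Whitney with a Shapiro–Wilk
gate, uncorrected Pearson chi-squared), clinical dichotomization (GCS ≤ 8,
NIHSS > 25, DAR ≥ 4, DTABR ≥ 3), Cox proportional hazards with Efron ties
and backward stepwise elimination at α = 0.05, Kaplan–Meier curves with
log-rank tests, and per-model ROC curves with AUROC, DeLong comparisons and
the Youden operating point.

**Synthetic data** (`simulate_eeg`, `simulate_tcd_waveform`,
`simulate_cohort`, `simulate_vascular_exam`, `run_pipeline`): band-structured
EEG with analytically calibrated band-power targets, TIBI-morphology Doppler
envelopes with exact round-trip velocities, and exponential
proportional-hazards cohorts calibrated to ~37% 90-day mortality, composed
into a full simulate → extract → model pipeline by `run_pipeline()`.

## Worked example

```r
library(tcdqeeg)

# A 5-minute EEG with the band profile of a poor-prognosis patient
rec <- simulate_eeg(eeg_sim_spec(duration = 300,
  band_targets = c(delta = 0.6846, theta = 0.1003,
                   alpha = 0.1315, beta = 0.0836),
  seed = 42))
compute_qeeg_indices(rec)
#> <qeeg_indices> RDP 0.675 RTP 0.110 RAP 0.131 RBP 0.084 | DAR 5.14 DTABR 3.65 BSI 0.034
```

The recovered relative powers match the generator targets to ~0.01 and the
DTABR of 3.65 sits in the marked-slowing regime (≥ 3); the BSI is near 0
because both hemispheres received the same targets.

```r
# A blunted affected-side MCA envelope, graded against the other side
aff <- extract_envelope_measures(simulate_tcd_waveform(
  tcd_sim_spec(vs = 40, vd = 15, morphology = 2, noise_sd = 1, seed = 42)))
una <- extract_envelope_measures(simulate_tcd_waveform(
  tcd_sim_spec(vs = 115, vd = 48, morphology = 5, noise_sd = 1, seed = 43)))
aff
#> <tcd_measures> Vs 39.8 Vd 14.8 Vm 23.1 PI 1.08 AT 0.247 s
classify_tibi(aff, una)
#> [1] 2
classify_offending_vessel(vascular_exam(
  data.frame(depth = 62, grade = 2), acoa_crossfill = TRUE))
#> [1] "tica"
```

The delayed upstroke (acceleration time 0.247 s > 0.20 s) with preserved
diastolic flow grades as TIBI 2 (blunted); an abnormal spectrum at 62 mm with
anterior-communicating cross-filling locates the lesion at the terminal ICA.

```r
# Survival modelling on a simulated cohort with known hazard ratios
co <- simulate_cohort(cohort_sim_spec(n = 2000, seed = 42))
sel <- backward_select(co$time, co$event,
  data.frame(gcs_low = co$gcs_low, vessel = co$vessel,
             dar_high = co$dar_high, dtabr_high = co$dtabr_high))
sel$dropped
#> [1] "dar_high"
sel$fit
#> <cox_fit> n = 2000, events = 729, efron ties, 4 iteration(s)
#>            term    hr    lo    hi        p
#>     gcs_lowTRUE 3.247 2.800 3.766 9.44e-55
#>      vesseltica 4.237 3.494 5.139 9.26e-49
#>       vesselmca 1.638 1.385 1.937 8.50e-09
#>  dtabr_highTRUE 3.998 3.420 4.673 7.63e-68
```

Backward elimination drops the redundant DAR ≥ 4 indicator (it carries no
hazard beyond DTABR ≥ 3 in the generator) and the fitted hazard ratios
recover the generator's truth (3.228, 3.830, 1.64, 3.647) within sampling
error. The full pipeline — per-patient signals in, baseline table, Cox model,
Kaplan–Meier curves and the four-model ROC comparison out — runs as
`run_pipeline(default_config())`.

## Layout

* `R/` — implementation (QEEG spectral analysis, TCD hemodynamics, cohort
  statistics, survival models, ROC evaluation, synthetic generators, pipeline
  and EDF/CSV/YAML I/O)
* `tests/testthat/` — unit, property and acceptance tests, with brute-force
  oracles (naive Welch, double-loop BSI, hand-written Efron partial
  likelihood, pair-counting AUROC, bootstrap DeLong)
* `vignettes/multimodal-prognosis.Rmd` — methods vignette: models,
  assumptions, parameter choices, limitations
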