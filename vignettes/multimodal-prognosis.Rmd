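---
title: "Multimodal TCD-QEEG prognostic modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal TCD-QEEG prognostic modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdqeeg)
```

## The problem

Large hemispheric infarction — ischemic stroke of at least two-thirds of one
MCA territory — carries very high early mortality, and bedside, non-invasive
markers of 90-day prognosis are clinically valuable because serial imaging is
often infeasible in these patients. Three markers carry complementary
information: the Glasgow Coma Scale (consciousness), quantitative EEG
(neuronal dysfunction downstream of hypoperfusion), and transcranial Doppler
(the vascular lesion itself). This package implements the complete analysis
chain that turns raw multichannel EEG, Doppler velocity envelopes and a
clinical cohort table into a combined prognostic model, together with
synthetic-data generators that make every stage testable against known
ground truth.

## QEEG branch

### Spectral estimation

`welch_psd()` computes an averaged modified periodogram per channel: 2-s
Hamming-windowed segments with 50% overlap, constant detrending per segment,
one-sided spectra with window-power normalization (U = Σw²), yielding a
0.5 Hz grid restricted to 1–30 Hz (the recording band after 0.3 Hz high-pass
and 30 Hz low-pass filtering). The normalization is fixed so that the summed
PSD times the bin width equals in-band signal variance; the test suite pins
this with a sinusoid Parseval identity (1% tolerance) and checks every bin
against a naive segmented-FFT reference implementation at 10⁻⁹ relative
error.

### Band partition

The clinical band labels (delta 1–3 Hz, theta 4–7 Hz, alpha 8–13 Hz, beta
14–30 Hz, "inclusive") leave the 3.5, 7.5 and 13.5 Hz bins unassigned on a
0.5 Hz grid. `default_bands()` therefore assigns bins by half-open intervals
— delta [1, 4), theta [4, 8), alpha [8, 14), beta [14, 30.5) — so the four
bands exactly partition the grid and relative powers sum to 1 (enforced at
10⁻⁹ in every analysis). Band edges are arguments, so sensitivity analyses
with other conventions are one call away.

### Indices

Band powers are averaged across all 16 channels before ratios are formed
(the analysis reports one value per patient; whether averaging preceded or
followed ratio formation is not observable from per-patient indices, and
global averaging is the variance-minimizing choice). DAR = P(δ)/P(α) and
DTABR = (P(δ)+P(θ))/(P(α)+P(β)); a zero fast-band denominator is flagged
("silent fast-band") and reported as `Inf` rather than an error, since a
near-isoelectric fast band is a real clinical situation.

The brain symmetry index uses the pairwise-derived formulation: the mean of
|(R−L)/(R+L)| over the 8 homologous 10–20 pairs and all retained bins. Two
published variants differ in frequency range (1–25 vs full band); we
evaluate over the recording band 1–30 Hz for internal consistency, and the
spectral estimate passed in controls the range, so the 1–25 Hz variant is
available by restriction. Averaging jointly over pairs and bins equals
per-pair-then-mean aggregation here because all pairs retain the same bins.

### Artifact handling

Clinical practice selects artifact-free 5-minute segments manually;
`select_segments()` automates this with epoch-level rules: reject any 2-s
epoch exceeding ±100 µV on any channel (gross movement/electrode artifact)
or flat below 1 µV peak-to-peak on *all* channels (disconnection). Both
thresholds are configurable; the defaults are conventional clinical review
values. Selection keeps the earliest clean epochs, so a clean recording
passes through verbatim. No ICA or regression artifact removal is attempted.

## TCD branch

`extract_envelope_measures()` segments the velocity envelope into cardiac
cycles by systolic peak detection and reports across-cycle medians of Vs
(cycle maximum), Vd (end-diastolic minimum), Vm = (Vs + 2 Vd)/3 (the
standard time-weighted clinical approximation), PI = (Vs − Vd)/Vm (Gosling),
and the systolic acceleration time. The estimator adapts to measured noise
(median-filter residual): a noiseless envelope is measured exactly at its
samples, a noisy one via a lightly smoothed diastole and a plateau-averaged
systole, which keeps the round-trip against the generator within ~1% at
realistic noise.

TIBI grading follows the six-level scale with explicit numeric rules: 0
absent flow; 1 minimal (Vd ≤ 0 or Vd < 0.1 Vs); 2 blunted (acceleration
time > 0.20 s with positive diastolic flow and PI < 1.2); 3 dampened (normal
upstroke, Vm more than 30% below contralateral); 4 stenotic (Vm ≥ 80 cm/s
and ≥ 30% above contralateral); 5 normal. The 0.20 s threshold quantifies
"delayed systolic flow acceleration", which is named qualitatively in
clinical criteria; it is exposed in the configuration. Downstream rules
treat grade ≤ 4 as "abnormal spectrum". The classifier is pinned to an
exhaustive truth-table oracle over a grid crossing every rule boundary.

`classify_offending_vessel()` applies the diagnostic criteria in precedence
order TICA → MCA → proximal ICA. TICA precedes MCA because its criterion
(abnormal spectrum at 60–70 mm *plus* communicating-artery collaterals) is
strictly more specific over the overlapping 60–65 mm range. Carotid
compression results are carried as a supporting flag and never required,
keeping the default examination non-invasive; carotid-duplex findings enter
the same way. The ambiguous conjunction in the proximal-ICA criterion
("blunted ipsilateral MCA, and mean flow velocity > 20 cm/s") is read as a
conjunction within one alternative: collaterals AND (reversed OA flow OR
(blunted MCA AND Vm > 20 cm/s)). An examination satisfying no rule returns
`indeterminate` — with a warning when collateral findings are present but
unexplained — rather than an error, so cohort processing never aborts on a
single odd exam.

## Statistics, survival and ROC

Baseline comparisons mirror clinical "Table 1" practice: Student's t-test
(equal variances) for variables passing Shapiro–Wilk at α = 0.05 in both
groups, otherwise Mann–Whitney U (normal approximation, tie-corrected,
uncorrected); categorical variables use uncorrected Pearson chi-squared —
the variant that reproduces the printed baseline p-values of this study
design — with expected counts reported and a Fisher-exact option for sparse
tables. Dichotomization follows the printed inequalities exactly: GCS ≤ 8
and DTABR ≥ 3 inclusive, NIHSS > 25 strict. No multiplicity adjustment is
applied across the baseline panel, matching practice for descriptive
tables.

The Cox model uses Efron tie handling (day-resolution survival times make
ties likely and Efron is less biased than Breslow; the option is exposed),
Wald confidence intervals exp(β ± 1.96 SE) and Wald p-values, matching the
HR/CI/p reporting convention. The offending vessel enters as two indicators
against the proximal-ICA reference, the category with the lowest observed
mortality. `backward_select()` removes the worst covariate by Wald p while
it exceeds α = 0.05, factors as whole blocks judged by their minimum-p
contrast, ties broken by column order for determinism. Monotone likelihood
is flagged (diverging-coefficient warning), not silently reported.
Kaplan–Meier medians use the smallest time with S(t) ≤ 0.5 and report "not
reached" otherwise. The Cox score test at β = 0 for a binary covariate
equals the log-rank statistic, which the suite checks at 10⁻⁸.

The combined prognostic score is the fitted probability from a logistic
regression of 90-day death on the three predictors (GCS ≤ 8 indicator,
risk-ordered vessel category, DTABR ≥ 3 indicator). A patient-level score
is the only construction consistent with reporting a single
sensitivity/specificity pair for the combination; logistic combination is
the standard such construction, and it is labelled as a modelling choice in
the report. Single-predictor models use the raw predictor as score. AUROC
uses the Mann–Whitney identity (ties 0.5); its variance and curve
comparisons use DeLong's method with confidence intervals formed on the
logit scale and back-transformed (clipped to [0, 1]); operating points
maximize Youden's J with ties resolved toward higher specificity. Perfect
separation in the logistic fit falls back to a positive-predictor count
with a warning. No cross-validation is attempted: the reported AUROC is the
apparent (in-sample) value, as is standard for cohorts of this size.

## Synthetic data: what it emulates, and what it does not

`simulate_eeg()` builds each channel as a sum of four band-limited Gaussian
noise components (white noise through zero-phase order-4 Butterworth
band-passes at the band edges, chosen because the flat in-band spectrum
makes band fractions analytic). Component variances are not set naively to
the targets: filter roll-off leaks several percent of each component's
power across band edges, so the variances solve a 4×4 linear system built
from the analytic zero-phase power response |H(f)|⁴, making the *expected*
relative band powers equal the targets (negative solutions for degenerate
targets, e.g. a single active band, are clipped and renormalized). Measured
recovery error is below 0.02 absolute for 5-minute recordings. Hemispheres
take independent targets (left channels Fp1, F3, F7, C3, T3, T5, P3, O1 and
right homologues), giving controlled BSI ground truth. The default RMS
amplitude is 15 µV, placing physiologic peaks comfortably inside the
±100 µV rejection limit while injected artifacts (300 µV half-second
bursts at a configurable rate per minute) deliberately exceed it.

`simulate_tcd_waveform()` generates one envelope cycle shape per TIBI
morphology (normal sharp upstroke with exponential diastolic decay; blunted
delayed upstroke; minimal-flow systolic spikes with zero diastole; absent
flow) scaled between Vd and Vs. Each cycle carries a 3%-of-cycle systolic
plateau and a 5% end-diastolic plateau so sampled waveforms attain Vs and
Vd exactly at any heart-rate/sampling-rate combination — the noiseless
round-trip through `extract_envelope_measures()` is exact, which pins the
extraction conventions.

`simulate_cohort()` draws the three predictors independently at the study's
prevalences — GCS ≤ 8 in 19/59, vessels (proximal ICA, TICA, MCA) at
(29, 8, 22)/59, DTABR ≥ 3 at 0.45 (no prevalence is printed for this
indicator; 0.45 is chosen once from the group DTABR medians of 3.57 and
2.70 straddling the cutoff of 3) — and survival times from an exponential
proportional-hazards model with true hazard ratios 3.228 (GCS ≤ 8), 3.830
(TICA vs proximal ICA) and 3.647 (DTABR ≥ 3). No hazard ratio is reported
for the MCA indicator; its generator default of 1.64 is derived from the
vessel-specific 90-day mortalities (36.4% vs 24.1%) under the exponential
hazard, log(−log(1−0.364)/−log(1−0.241)). The baseline hazard is calibrated
by root-finding so expected 90-day mortality equals 22/59 ≈ 37%, and
administrative censoring is applied at day 90. The exponential baseline is
a deliberate simplification: it provides closed-form checks (Kaplan–Meier
convergence to exp(−λt), exact null mortality), and the Cox fit is
baseline-agnostic, so hazard-ratio recovery tests remain valid for any true
baseline.

Predictors are simulated independently because no per-patient joint
distribution linking QEEG, TCD and GCS is available; a correlated auxiliary
DAR ≥ 4 indicator (85% agreement with DTABR ≥ 3) is included so that
backward elimination has a realistic redundant covariate to remove. When
`run_pipeline()` operates at signal level, each patient's EEG band targets
are drawn from slowing-regime profiles (renormalized group-mean band powers
for marked slowing, moderate slowing and healthy controls, with the
affected hemisphere more slowed than the unaffected one and mild
multiplicative jitter), and each patient's vascular exam expresses their
true offending vessel; the analysis branches then re-extract everything
from the signals. Index recovery is deliberately imperfect near the
DTABR = 3 boundary — the moderate-slowing regime mean (≈2.8) sits close to
the cutoff, as the real survivor group's median (2.70) does — so
study-scale (n = 59) results vary realistically across seeds and
dichotomized predictors are attenuated relative to their generator truth.

The generators do **not** emulate: real artifact morphology (eye blinks,
EMG), EEG nonstationarity, volume conduction or reference effects; Doppler
spectral broadening, emboli or probe-angle error; correlated clinical
covariates beyond the DAR/DTABR pair; non-exponential baseline hazards or
informative censoring. Passing tests therefore demonstrate correctness of
the analysis chain and calibration of the generators, not clinical validity
on real recordings.

## Numerical conventions and degenerate inputs

* Welch preconditions: fs × window length must be a whole number of
  samples; recordings shorter than one window are errors.
* A zero recording yields an identically zero spectrum; band powers then
  error (zero total power) rather than return 0/0.
* All-zero Doppler envelopes return zero measures flagged `no_flow` (TIBI
  0); a constant positive envelope returns PI = 0; fewer than three
  detectable cycles is an "unreadable waveform" error.
* Cox fits drop constant covariates with a warning, require at least one
  event, and converge at a 10⁻⁹ relative tolerance; scale equivariance
  (doubling a covariate halves β) holds at 10⁻⁸.
* ROC ties use the 0.5 convention in the AUROC and inclusive thresholds
  (score ≥ t ⇒ positive) in the curve; `delong_compare()` of a curve with
  itself returns p = 1 by convention instead of 0/0.
* Seeds: every generator takes an explicit seed and is byte-reproducible
  given it; `run_pipeline()` derives all per-patient randomness from the
  single configured seed.

## Problem sizes used by the tests

The suite exercises hazard-ratio recovery at n = 2000 (±10% on each log
hazard ratio), Wald coverage at the study's own scale via 500 replicates of
n = 59, band-power recovery on ten 5-minute 16-channel recordings, DeLong
agreement against a 10,000-replicate stratified bootstrap on a 40-patient
fixture, and full signal-level pipeline runs at n = 14 with 24-second
recordings — sizes chosen to make the statistical assertions sharp while
keeping the default test run fast on a single CPU. The acceptance script
runs the signal-level pipeline at the full study scale (n = 59, 5-minute
recordings).

## Known limitations

* The offending-vessel classifier encodes the published depth/collateral
  criteria as deterministic rules; real sonographer judgment integrates
  more context, and borderline exams that satisfy no rule are labelled
  `indeterminate` rather than adjudicated.
* Apparent (in-sample) AUROC overstates out-of-sample discrimination at
  n = 59; the package intentionally reproduces that design rather than
  "fixing" it with cross-validation.
* The BSI variant and its frequency range differ across the literature;
  results are reported for the pairwise-derived 1–30 Hz version.
* EDF support covers continuous 16-bit recordings with uniform sampling
  rates and ignores annotations.
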