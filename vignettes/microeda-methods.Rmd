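---
title: "Methods: from wristband voltage to microclimate-stress models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wristband voltage to microclimate-stress models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the measurement
model, the decomposition and the spectral indices, the synthetic-data
generator that stands in for participant data, and the numerical and
design choices a maintainer should know about. Code chunks are small and
self-contained; nothing here asserts an empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. Measurement model

Exosomatic EDA measurement passes a small current through the skin and
watches its conductance. The wristband modeled here is a symmetric
voltage divider: supply 3.3 V, reference resistor 826 kΩ, a 16-bit ADC
(±2.048 V full scale) sampling at 10 Hz, dry Ag/AgCl electrodes of
0.80 cm diameter (≈0.50 cm² area, ≈3 µA/cm² current density — well under
the 10 µA/cm² safety recommendation). Conversion is

$$R_\text{skin} = \left(1 - \frac{2 V_\text{out}}{V_{dd}}\right) R_\text{ref},
\qquad G_\text{skin}\,[\mu S] = \frac{10^6}{R_\text{skin}}.$$

Readings at or above $V_{dd}/2$ would imply non-positive resistance;
`ingest_wristband()` masks them as invalid rather than clipping and
bridges gaps up to 1 s by linear interpolation (longer dropouts abort
ingestion, because the downstream filters need a complete uniform
series). Typical dry-electrode skin conductance sits between ~1.5 and
~10 µS, comfortably inside the divider's measurable range
(1.21 µS–∞ for this `Rref`).

## 2. Preprocessing

* **Filtering.** The artifact-removal low-pass is a 1.5 Hz, 32nd-order
  Butterworth; the detrending high-pass before spectral analysis is
  0.01 Hz, 8th order. At order 32 a direct transfer function overflows
  double precision, so the filters are designed analytically — Butterworth
  prototype poles, bilinear transform, conjugate pairs grouped into
  second-order sections with the gain distributed across sections — and
  applied forward–backward (zero phase, so the two devices being compared
  in validation never acquire relative lag from filtering). Because the
  double pass squares the magnitude response, the design cutoff is
  pre-compensated on the bilinear (tan) axis so the *two-pass* half-power
  point lands exactly at the nominal cutoff; tests verify −3 dB at 1.5 Hz
  and > 60 dB stopband attenuation at 3 Hz. Each biquad is seeded with its
  steady-state response to the edge value, so constants pass with zero
  transient.
* **Resampling** (10 → 4 Hz for decomposition, → 2 Hz for spectral
  indices) uses a Blackman-windowed sinc kernel band-limited to 90% of
  the narrower Nyquist interval, with per-sample weight renormalization
  (a constant resamples exactly) and reflected edges. A 10 → 4 → 10 Hz
  round trip of a 0.5 Hz tone stays within 0.1% RMS. The `signal`
  package's own `resample()` was tried first and produced order-of-100%
  errors on band-limited tones in this version, so the kernel
  interpolator is authored here.
* **Normalization** defaults to per-session min–max into [0, 1] (z-score
  by flag); both are monotone, so Spearman-based screens are unaffected.
  The processing order is filter-then-normalize by default and
  configurable, since the upstream description leaves the order open.
* **Outliers** are masked per 15-min protocol window at |z| > 3 and
  interpolated.

## 3. Tonic/phasic decomposition

Skin conductance is modeled as a smooth tonic trajectory plus a train of
skin conductance responses (SCRs): sparse sudomotor impulses convolved
with the biexponential $h(t) = e^{-t/\tau_0} - e^{-t/\tau_1}$,
$\tau_0 = 2$ s, $\tau_1 = 0.7$ s, peak-normalized so driver amplitudes
read in µS. With $M$ the convolution operator (realized implicitly as a
2nd-order ARMA filter — no dense matrix), $B$ a cubic B-spline basis with
knots every 10 s and $C$ an affine drift,

$$\min_{p \ge 0,\ \ell,\ d}\ \tfrac12\|y - Mp - B\ell - Cd\|^2
  + \alpha\|p\|_1 + \gamma\|\ell\|^2,$$

defaults $\alpha = 8\times10^{-4}$, $\gamma = 10^{-2}$.

The solver exploits two structural facts. First, for any driver the
tonic coefficients have a closed-form ridge solution, so they are
eliminated (variable projection), leaving a problem in $p$ alone. Second,
on the feasible set $p \ge 0$ the $\ell_1$ term is linear, so the
projected problem is a smooth box-constrained convex quadratic: L-BFGS-B
solves it quickly, and an active-set polish — an exact `quadprog` solve
restricted to the (augmented) support — drives the KKT residual to the
1e−6 relative tolerance, typically in two or three rounds. The polish
cost grows cubically with the support, so `pipeline_config()` relaxes the
tolerance to 1e−4 for whole-session batches; the derived indices are
insensitive to driver perturbations below that level (the fixtures in
`tests/testthat/test-decompose.R` pass at either setting).

Properties maintained by construction and covered by tests: exact
reconstruction (`tonic + phasic + residual = input`), non-negative
driver, monotone regularization path in $\alpha$, homogeneous scaling
when $\alpha$ is scaled with the data, and < 5% residual energy on the
SCR fixtures. Recordings longer than ~15 min are solved in 900-s chunks
with 30-s overlap and stitched at chunk midpoints; the chunked and
monolithic solutions agree on the fixtures away from seams.

**Working rate.** Decomposition defaults to 4 Hz. One caveat is
resolution: at NS-SCR rates near 18/min, Poisson event pairs closer than
0.5 s occur about 2.8 times per minute and collapse into single driver
bins at 4 Hz, biasing counts low by more than the ±2/min recovery target.
Event-rate studies should therefore decompose at 8 Hz
(`decompose_rate = 8`) and count events with 0.25 s minimum separation,
which is what the recovery tests and the acceptance script do; component
shapes and all other indices are unaffected by the working rate.

## 4. EDA indices

* **SCL** — mean of the tonic component over 2-min windows.
* **NSSCR** — SCR events per minute. Events are taken from the sparse
  driver, not from phasic local maxima: deconvolution separates responses
  that overlap into a single phasic peak. An event is a driver local
  maximum with prominence ≥ 0.1 µS (noise and drift absorbed by the
  driver spread thinly and stay well below this; true impulses
  concentrate their mass in one or two samples). The per-sample event
  indicator travels with the feature stream so coarser windowings recount
  exactly.
* **dphEDA** — central-difference derivative of the phasic component,
  one-sided at the edges.
* **EDASymp** — mean Blackman-windowed (128-point, 50% overlap)
  periodogram power in 0.045–0.25 Hz, reported both absolute (µS²) and
  normalized by total above-DC power. The upstream description of the
  segment overlap ("0.5 s") is read as 50% — a one-sample overlap of 64-s
  segments would be spectrally meaningless — with the literal variant
  available by configuration.
* **TVSymp** — variable-frequency complex demodulation: the 2 Hz signal
  is demodulated on a 0.03 Hz grid of center frequencies, each component
  extracted with a 6th-order low-pass of half-bandwidth 0.015 Hz and
  refined by re-centering *the component itself* at its smoothed
  instantaneous frequency (re-demodulating the raw signal instead lets
  neighboring components double-count a tone — a ~2× amplitude error the
  tests would catch). In-band (0.08–0.24 Hz) components are summed and
  the analytic-signal magnitude gives the instantaneous amplitude; the
  summary statistic is the mean of the unit-variance-normalized series,
  following the index's literature convention, with the raw amplitude
  also returned.
* **MTVSymp** — current TVSymp minus the mean of the preceding 5 s,
  clipped at zero; the first seconds use the available partial history.

Features are synchronized to the 2 Hz grid against the ~1 Hz environment
log by carrying each environmental variable forward from its most recent
observation, at most 2 s stale; no EDA row inside the overlap is dropped
or duplicated.

## 5. Labeling and screening statistics

A window is **high** stress when difficulty ≥ 7 (of 10) and stress ≥ 5
(of 7); **low** when both ≤ 2 or the window is a designated baseline;
otherwise unlabeled. The strict-inequality variant (> 6 / > 4 / < 3) is
available as `rule = "strict"`; the two rules differ only at the
boundary scores, and the closed-threshold form is the operational
default. Raw SAM and questionnaire items are carried through unscored.

The screen is deliberately simple: a one-sample Kolmogorov–Smirnov check
against a fitted normal (parameters estimated, no Lilliefors correction —
the statistic only gates the choice of rank-based association measures,
so its p-value is reported as approximate and never used for inference),
Fisher's ratio $(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$ with unbiased
variances for class separability (computed per subject, then averaged,
with a pooled fallback), and Spearman's rank correlation implemented
explicitly as Pearson on average ranks so that tie handling is auditable
against a brute-force oracle (they agree to 1e−12 on small tied vectors).

## 6. Models and attribution

Three regression families — random forest (`ranger`, 500 trees), radial
ε-SVR (`e1071`, standardized inputs, C = 1, ε = 0.1), and ordinary least
squares — are evaluated by held-out R² under two schemes:
leave-one-subject-out (one fold per subject; the fold structure makes
training on the held-out subject impossible, and a leakage test with
per-subject offset targets confirms it) and repeated seeded 70/30 splits
(5 repeats; a single split has no "mean cross-validation" score, so the
mean over seeded repeats is reported). Negative R² values are reported
as-is. The same machinery runs forward (12 environmental inputs → each
EDA index) and reverse (6 EDA indices → temperature, CO₂, humidity,
infrared), which is the design's two-way consistency check: on
deterministic synthetic links both directions exceed R² 0.9, and on
shuffled targets both collapse to ≤ 0.1.

Attributions are Shapley values by permutation sampling over a fixed
background: for each sampled (permutation, background row) pair the
marginal contributions telescope, so per-instance attributions sum
*exactly* to prediction minus baseline for every model family — local
accuracy to machine precision, without tree-specific algorithms. The
trade-off is sampling variance in individual attribution values
(64 permutations by default; the global ordering by mean |attribution| is
stable on the fixtures).

## 7. The synthetic-data generator

The generator emulates the study protocol — eight 15-min windows with
randomized microclimate setpoints, hard mathematical tasks in most
windows and easy/baseline tasks in a few — with a known ground-truth
chain from environment to physiology:

* **Environment:** per-window setpoints drawn from realistic indoor
  ranges (e.g. 20–32 °C, 400–1800 ppm CO₂), with stationary AR(1)
  fluctuation (φ = 0.95, SD 5% of the setpoint range) at 1 Hz across all
  twelve logged variables.
* **Latent stress** per window: logistic in standardized temperature,
  CO₂ and task difficulty, default weights (0.5, 0.5, 4). Difficulty
  dominates deliberately — hard tasks are the protocol's stressor, the
  microclimate modulates — and the weights are set so hard windows earn
  the high-stress label with probability ≥ 0.9 while the environmental
  effects remain detectable in the screen.
* **EDA:** tonic = per-window level (2–4 µS, increasing in latent
  stress) + 0.3 µS/h drift + a 0.01 Hz, 0.1 µS thermoregulatory wave;
  SCRs at Poisson times with per-window rate 4–20/min (increasing in
  latent stress), biexponential shape (τ₀ = 2 s, τ₁ = 0.7 s), LogNormal
  peak amplitudes (meanlog −1.2, sdlog 0.4 — median ≈ 0.30 µS); Gaussian
  noise SD 0.01 µS. The conductance is pushed back through the divider
  equations to produce wristband voltage in the valid range, so the whole
  ingest path is exercised. A shape-mismatch mode (different τ) exists to
  probe decomposition robustness.
* **Self-reports:** stress = clip(1 + 7·latent + logistic(0.4)),
  arousal/valence/dominance monotone in latent stress on the SAM scale.
* **Device pair:** a second stream at 4 Hz as an affine, lagged,
  independently noised copy — the two-wrists validation setup; setting
  the noise from the attenuation formula $\rho = 1/\sqrt{1+\sigma^2/\mathrm{var}}$
  targets a chosen correlation. The formula is a Pearson statement, so
  `validate_devices()` reports both correlations: the measured Pearson
  tracks the target closely (slightly above it, because the 1.5 Hz
  low-pass removes part of the added noise), while the Spearman headline
  sits a few hundredths lower on spiky conductance, where ranks compress
  the large excursions that carry the linear correlation.

What the generator does **not** emulate: motion artifacts and electrode
detachment, skin-temperature dependence of conductance, circadian drift,
inter-subject variability beyond seed-level randomness, sensor
quantization beyond the ADC model, and any real coupling between the
twelve environmental channels (they fluctuate independently around their
setpoints). Passing tests therefore demonstrate correctness of the
*computational chain* under the stated generative assumptions — not that
the paper-level scientific findings would replicate on new participants.

## 8. Problem sizes and runtimes

The test fixtures are sized for desk-scale runs: decomposition fixtures
are 5–10 min of 4 Hz signal, recovery studies use 5-min windows at
2/8/18 events per minute, the null-association check uses one full
two-hour session (7200 2-Hz rows), model fixtures use a few hundred
rows, and the device study uses twenty 5-min pairs. The full default
pipeline (five subjects, eight 15-min windows each, models included) is
the largest single computation; the decomposition stage dominates its
cost. These sizes are the package's own validation choices; all scale up
by argument.

## 9. Known limitations

* The 4 Hz decomposition default undercounts NS-SCRs above ~12/min (see
  §3); use 8 Hz for event-rate work.
* EDASymp's normalized value for broadband signals reflects the
  discrete band fraction of the 128-point grid (14/64 ≈ 0.219 at 2 Hz)
  rather than the continuous fraction 0.205.
* KS p-values are approximate (estimated parameters); they are never
  used for inference here.
* Permutation-Shapley individual values carry sampling noise; only the
  summary ordering should be interpreted at default settings.
* The correlation tables pool subjects by default (subject id is
  retained, so per-subject sensitivity analyses are one `group_by` away).
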