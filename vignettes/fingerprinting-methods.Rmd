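---
title: "Methods: neurophysiological fingerprinting from ROI timeseries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neurophysiological fingerprinting from ROI timeseries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

brainprint implements *connectome* and *spectral fingerprinting* of
individuals from multichannel electrophysiological recordings that have
already been source-imaged and summarized as one timeseries per cortical
region of interest (ROI). This vignette is the package's account of the
model, its tunable parameters, the synthetic cohort generator that makes
the pipeline testable without access-controlled MEG archives, and the
numerical and design choices behind the implementation.

## The fingerprinting model

Given two datasets per participant (two halves of a session, two sessions
days apart, or short 30 s segments), each participant is summarized by a
feature vector in each dataset:

* **Connectome features.** Each ROI timeseries is band-pass filtered,
  Hilbert envelopes are extracted, and every ROI pair's amplitude envelope
  correlation (AEC) is the Pearson correlation of the two envelopes. The
  symmetric $R \times R$ matrix is vectorized to its
  $R(R-1)/2$ upper-triangle edges (2278 edges for the 68-ROI
  Desikan-Killiany parcellation).
* **Spectral features.** Welch power spectral densities per ROI (2 s Hann
  windows, 50% overlap, 0–150 Hz at 0.5 Hz resolution), concatenated over
  ROIs (optionally restricted to one band's bins).

With feature matrices $F^{(1)}, F^{(2)}$ (subjects × features), the cohort
similarity matrix is $A_{ij} = \mathrm{corr}(F^{(1)}_{i\cdot},
F^{(2)}_{j\cdot})$ — square and generally asymmetric. A probe row $i$ is
*identified* as the column with the largest correlation; accuracy is the
proportion of correct matches, and swapping rows for columns swaps which
dataset serves as probe. Both directions are always computed.

Per-participant *differentiability* is the z-score
$$D_{\mathrm{self}}(i) = \frac{A_{ii} - \mu_i}{\sigma_i},$$
where $\mu_i$ and $\sigma_i$ are the mean and sample (n−1) standard
deviation of participant $i$'s correlations to the *other* cohort members
(row $i$, diagonal excluded).

Feature-level contributions are quantified by three edgewise metrics
across the two datasets: one-way random-effects intraclass correlation
(ICC(1,1), two datasets as repeated measurements), group consistency
$\Phi(e) = \mathrm{mean}_i\, \phi^{(1)}_i(e)\phi^{(2)}_i(e)$ on unit-norm
feature vectors, and differential power
$\mathrm{DP}(e) = \sum_i -\ln P_i(e)$ with $P_i(e)$ the empirical
probability that a cross-subject envelope product beats the within-subject
product.

The PLS stage relates a demographics block $X$ to a neural-feature block
$Y$ by SVD of the cross-block correlation matrix
$R = X_z^\top Y_z/(n-1) = USV^\top$: latent variables pair demographic
saliences (columns of $U$) with neural saliences (columns of $V$).
Significance per LV comes from permuting the rows of $X$ (10,000
permutations is a common choice); stability from bootstrapping
subjects (bootstrap ratio = salience / bootstrap SE; 95% percentile CIs
for demographic saliences, which need not be symmetric).

## The synthetic cohort generator

No public generative model exists for the source data, so all generator
parameters are this package's own and are documented here. The generator
plants exactly the structure the analysis exploits:

* **Band-power topographies.** Per subject $i$, ROI $r$, band $b$ the band
  log-amplitude is $a_{irb} = \mu_b + u_{irb}$,
  $u \sim N(0, \sigma_{\mathrm{between},b})$, with an independent
  $N(0, \sigma_{\mathrm{within},b})$ perturbation per session. Carriers
  are white noise filtered by the *same* band-pass bank the analysis uses
  and normalized to unit variance, so $e^{a}$ is interpretable as band
  RMS amplitude.
* **Inter-ROI coupling.** `n_latents` shared band-limited latent carriers
  per session; ROI $r$ loads latent $k$ with weight
  $w_{irk} \sim N(0, \texttt{coupling\_sd})$, scaled by the latent band's
  mean amplitude so the coupled share of band power is comparable across
  bands. Weights persist across sessions up to a drift proportional to
  the mean within-session amplitude SD — session drift affects amplitudes
  and couplings jointly, which lets tests separate connectome from
  spectral robustness over time.
* **Individual alpha peak.** The alpha carrier is a narrow ±1 Hz band
  around a subject-specific peak frequency ($N(10, 1)$ Hz by default),
  the simplest controllable analog of inter-individual peak-frequency
  variability.
* **Demographics.** All four variables (age, sex, handedness, clinical
  status) load one shared latent — a linear combination of `n_planted`
  randomly chosen (ROI, band) log-amplitude features — scaled by
  `demographic_effect`, plus unit noise; binary variables are quantile
  cuts (50% sex, 15% left-handed, 30% clinical). With
  `demographic_effect = 0` demographics are pure noise, which is the null
  used to calibrate PLS permutation p-values.
* **Artifacts.** Cardiac/ocular/motion RMS values and scan durations are
  drawn independently of identity, so differentiability must not
  correlate with them.
* **Empty room.** One pseudo-recording per subject-session with a single
  deterministic amplitude per band, chosen so expected band power equals
  the cohort mean (log-normal amplitude mean plus the latent power
  contribution folded in). No subject-specific quantity enters, so any
  downstream identification can only succeed at chance level.

Default parameter choices, made once as realistic for resting-state MEG
source data: `sigma_between = 0.5` and `sigma_within = 0.1` (between-subject
band-power spreads of ~ a factor 2–3, session drift far smaller),
`coupling_sd = 0.5` (coupled share of band power around 20%, giving AEC
values in the 0.05–0.3 range typical of envelope connectivity),
`noise_sd = 0.5`, `band_log_mean` following a 1/f-like power profile
centred on alpha, `fs = 600` Hz and 300 s sessions (the analysis ceiling
is 150 Hz; resting-state recordings of this kind are typically ~5 min). `n_subjects`
and `n_sessions` have no defaults — cohort size is a property of the study
being emulated (on the order of 150 within-session and ~50 between-session in open MEG
archives).

What the generator does **not** emulate: 1/f-exact spectra (band-wise
constant densities instead), sensor geometry and field spread (no leakage
between ROIs beyond the planted coupling; the `orthogonalize` flag is
therefore exercised on constructed leakage in tests), non-stationarity,
and artifact waveforms. Passing tests therefore demonstrate correctness of
the *pipeline* under the planted statistical structure, not performance on
real MEG data.

## Numerical choices

* **Filter.** Zero-phase band-pass applied in the frequency domain with an
  order-24 Butterworth magnitude response after odd (point-symmetric)
  signal extension. Pass-band gain is within 1 dB, attenuation one octave
  outside the band exceeds 40 dB, and a 10 Hz tone leaks < 1% RMS into the
  neighbouring beta band. Forward-backward IIR filtering of the narrow
  1–4 Hz band at 600 Hz is numerically fragile at the orders needed for
  that stop-band contract, which is why the filter is applied spectrally;
  the magnitude contract — not the realization — is the specification, and
  the test suite checks the contract with FFT oracles.
* **Welch PSD.** Periodic Hann window, one-sided density scaling
  (power/Hz), no detrending; 2 s windows with 50% overlap give the 0.5 Hz
  grid. A white-noise Parseval check and a tone-localization check pin the
  scaling.
* **Envelope.** Analytic-signal magnitude via the FFT weighting
  (1, 2, …, 2, 1); no installed package provides this primitive.
* **Matching.** Argmax ties break deterministically toward the lowest
  subject index and are counted; they are measure-zero on real data but
  must be reproducible on synthetic edge cases. Subjects with undefined
  similarity rows (zero feature variance) are reported unidentifiable and
  leave the accuracy denominator.
* **Degenerate inputs.** Constant envelopes, zero-norm feature vectors and
  zero-variance features propagate as explicit `NA` (with warnings), never
  as silent zeros.
* **PLS.** Add-one permutation p-values, $(\#\{S^{perm}_k \ge S_k\}+1)/
  (n_{perm}+1)$, so p is never exactly zero. Bootstrap LVs are aligned to
  the original by orthogonal Procrustes rotation of the demographic
  saliences before SEs are computed — without alignment, sign and order
  indeterminacy of the SVD would inflate SEs arbitrarily. Bootstrap ratios
  whose SE underflows are capped and flagged. Categorical demographics are
  encoded as centered binary codes before z-scoring.
* **Seeds.** One user-facing seed per entry point, fanned out to
  independent per-stage child streams via an affine counter scheme, so
  adding draws to one stage cannot perturb another; identical
  (config, seed) is bit-reproducible.

## Open design decisions, and how they were resolved

* **Diagonal in the differentiability null.** "All other individuals" is
  read exclusively: $\mu_i, \sigma_i$ omit $A_{ii}$. The inclusive variant
  is available as `include_self_in_null = TRUE`.
* **Sample vs population SD.** Sample (n−1) SD, pinned; the worked
  example (self 0.9 vs others {0.5, 0.6, 0.4} → $D_{\mathrm{self}} = 4$)
  fixes the convention.
* **AEC leakage correction.** Plain AEC by default; the method family
  includes pairwise-orthogonalized variants, so the `orthogonalize` flag
  implements symmetric pairwise orthogonalization for users whose source
  data needs it.
* **PSD scale for matching.** Raw (not log) PSD values by default, with a
  `log_psd` switch; correlation-based matching is scale-free per subject,
  and both conventions appear in the literature.
* **Band-restricted spectral features** keep per-bin values rather than a
  single band mean — per-ROI averaging happens over Welch windows, not
  over frequency.
* **Edge order.** Lexicographic (row-major, $i < j$) upper-triangle
  order, pinned for reproducibility of serialized feature matrices.
* **30 s segments** are taken from the start of each recording; placement
  is otherwise arbitrary and unstated in the source methodology.
* **ICC variant.** One-way random effects, single rater (ICC(1,1)) — each
  participant acts as their own rater across the two datasets.
* **Differential power aggregation.** Sum (not mean) of $-\ln P_i$ over
  subjects, with $P$ clipped below at $1/(2(N-1))$; the exact formula is
  part of the package contract and is verified against brute-force
  enumeration in tests.
* **Headline accuracy.** Every dataset-pair combination and both probe
  directions are always computed; the scalar summary is the sample mean
  across pair-directions, with the first pair's row-direction value also
  reported as the headline.

## Problem sizes used by the test suite

Tests and the acceptance script run small cohorts chosen so that the full
generative model stays exercised end to end:
typically 6–20 subjects, 4–12 ROIs, 20–90 s sessions at 300 Hz over five
bands (the high-gamma band needs `fs >= 600` and is exercised separately),
with a 100-cohort Monte-Carlo loop for null calibration and 10-seed loops
for monotonicity checks. These sizes are the package's own validation
choices; the statistical structure, not the scale, is what the checks
depend on. The high-reliability regime used where perfect identification
is expected (`sigma_between = 1`, `sigma_within = 0.02`,
`coupling_sd = 1.5`, 12 latents, theta–gamma bands) avoids the delta band
because slow delta envelopes contribute few effective samples to AEC
estimates at short test durations.

A note on PLS parameter recovery: the LV1 neural salience is estimated
from a $q \times p$ matrix of sample correlations whose entries carry
$1/\sqrt{n}$ sampling noise, so at $n = 100$ the cosine between the true
and estimated salience saturates well below 1 once $p$ grows — around
0.85 at $p = 30$ features irrespective of coupling strength. Recovery
checks therefore use compact band-power feature sets ($p = 15$) and
average the cosine over several cohorts; the binary demographic codes
also attenuate the planted coupling (point-biserial ceilings between
~0.55 and ~0.8), which is why the recovery regime sits at
`demographic_effect = 2` on this generator's scale.

## Known limitations

* Connectome fingerprinting accuracy on *broadband* features is sensitive
  to the envelope correlation estimation noise of the slowest band in the
  mix; narrowband connectomes are the more reliable feature set at short
  durations, in the generator as in practice.
* The generator's demographics are linear in log band-power features by
  construction; PLS recovery results say nothing about nonlinear
  brain-demographics relationships.
* The empty-room analog matches the cohort's *band-power profile*, not its
  full spectral shape within bands.
* Sensor-level preprocessing (line-noise removal, artifact projection),
  source modelling and parcellation are out of scope: the pipeline starts
  at ROI timeseries.
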