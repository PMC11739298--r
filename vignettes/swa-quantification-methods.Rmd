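---
title: "Methods: slow-wave activity quantification and intervention statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow-wave activity quantification and intervention statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaquant)
```

# Scope and model

swaquant quantifies slow-wave activity (SWA) — EEG power in the delta band
during non-rapid-eye-movement sleep (NREMS) — and the change in SWA induced
by a pharmacological intervention, together with the group statistics such a
preclinical study reports. The unit of analysis is a pair of 24-h recording
days per animal (baseline and under treatment), scored in 4-s epochs as
WAKE / NREM / REM / ARTIFACT by an external scorer; scoring itself is out of
scope and hypnograms are inputs.

The quantity of interest is *relative* delta power: per 4-s epoch, each
0.25 Hz bin is expressed as a percentage of the total 0.5–30 Hz power of
that epoch, delta power is the 0.5–4 Hz sum, and hourly NREM means are
compared across days at matched Zeitgeber (ZT) hours. Working with relative
power removes between-animal and between-day differences in absolute EEG
amplitude (electrode impedance, amplifier gain), at the cost of making band
estimates compositional: a genuine delta increase necessarily depresses the
remaining bands' shares. The delta-activity gain at hour *h* is the
treatment-minus-baseline difference in mean NREM relative delta power, in
percentage points (p.p.); the per-animal summary is the mean over ZT hours
9 and 10, the hours following the second of the two daily administrations
(ZT1, ZT9).

# Signal path

The post-processing stack runs in a fixed order; each stage records its
parameters in the recording's provenance.

1. **Clipping detection.** Maximal runs of at least 2 consecutive samples
   with |x| ≥ 0.999 × input range are flagged. Saturation at the digitiser
   rails is the physical definition of clipping; the fraction and run length
   are configurable because acquisition chains differ in how they encode
   saturation. Epochs containing clipping are excluded from spectra.
2. **Three-point moving average and Fermi taper.** Flagged samples are
   zeroed; each sample is replaced by the mean of itself and its neighbours
   (shrinking window at the ends, to avoid edge transients); each contiguous
   artifact-free segment is multiplied by a Fermi–Dirac-shaped taper that is
   ~0.5 at the segment boundary and rises to 1 over 1% of the segment
   length. The taper bounds the spectral footprint of excision edges before
   the FIR stage, whose long kernel would otherwise ring across several
   seconds of signal.
3. **Resampling to exactly 200 Hz.** Fourier-domain (trigonometric)
   interpolation: the length-`round(n·200/fs)` output preserves the
   amplitude and frequency of every component below the output Nyquist
   exactly for band-limited signals, at O(n log n). Polyphase resampling
   would behave equivalently here; the FFT route has no rational-ratio
   restriction. Input rates are restricted to [150, 250] Hz.
4. **Zero-phase equiripple band-pass, 0.5–30 Hz.** High-pass (transition
   0.25–0.5 Hz, 1600 taps) and low-pass (30–33 Hz, 260 taps) filters are
   designed with the Parks–McClellan algorithm and applied forward and
   backward. Requirements are stated for the filter *as applied* — the
   zero-phase cascade, whose magnitude is the square of the single-pass
   response: ≥ 40 dB stop-band attenuation and ≤ 0.5 dB pass-band ripple
   are required and verified at design time (the defaults achieve ~56 dB
   and ~0.06 dB, i.e. pass-band amplitudes correct to < 1%). The cascade is
   computed as one linear convolution with the autocorrelation kernel
   conv(b, rev(b)), which is identical to bidirectional filtering away from
   the (already tapered) edges and several times faster on day-long
   signals. Designs the exchange algorithm cannot meet raise an error
   rather than degrading silently.
5. **NREM outlier reconstruction.** One interquartile range (IQR) is
   computed over all NREM samples of the recording — a single scope, since
   NREM EEG is approximately stationary across the light period. Runs of
   fewer than 7 samples exceeding ±8 × IQR are replaced by cubic-spline
   interpolation through 8 flanking unflagged samples per side; runs of 7
   or more are regional artifacts: left untouched and their epochs
   excluded. A degenerate recording in which every NREM sample exceeds the
   threshold is an error, not a silent repair.

# Spectral estimation

Each scored epoch's spectrum averages the Hamming-windowed 4-s FFT segments
(0.25 Hz resolution) advanced by 2 s whose centres fall inside the epoch —
interior epochs average two half-overlapping segments, the first epoch one.
Segments containing any flagged sample (clipping or regional) are dropped;
an epoch with no clean segment is marked artifact and never contributes to
a mean. Bins from 0.5 to 30 Hz inclusive (119 bins) are kept and normalised
to sum to 100% per epoch (normalisation is per epoch, not per day, matching
the per-bin-percentage definition). Band power sums bins with both edges
inclusive; band edges must lie on the 0.25 Hz grid, and off-grid requests
are errors rather than silently snapped.

Hour *h* covers [h, h+1) anchored at ZT0 (lights-on, which the simulator
places at recording start). An hourly value requires at least 15 qualifying
NREM epochs (one minute) on both days to enter the gain series; the 9+10
summary defaults to the mean of the two hourly gains, with a `sum` option.

# Statistical battery

* **Independent t**: Student (pooled) or Welch, two-sided, computable from
  raw data or from `(n, M, SD)` summaries. The automatic variant selection
  uses Levene's test (centre = mean) at α = 0.05 and therefore needs raw
  data; both variants can be forced.
* **Cohen's d** uses the unweighted-variance denominator
  √((s₁²+s₂²)/2). This variant — not the n-weighted pooled SD — is the one
  consistent with the published effect sizes the acceptance checks
  reproduce (1.64, 0.91, 1.80).
* **Hourly gain series**: one independent t per ZT hour, Benjamini–Hochberg
  adjustment across the 24 hourly p-values, flags at q = 0.05. BH is the
  standard "false discovery method" of common graphing software; the
  adjustment is monotone and never lowers a p-value.
* **Two-way ANOVA** (genotype × treatment): Type-III sums of squares with
  sum-to-zero contrasts (via `car::Anova`), partial
  η² = F·df₁/(F·df₁+df₂) per effect, and the four simple pairwise cell
  comparisons with standard errors from the residual mean square,
  unadjusted p-values and 95% CIs — matching the reporting style of raw
  pairwise comparisons after separate main-effect analyses.
* **Correlations**: Pearson with the t-transform p-value; point-biserial as
  Pearson against a 0/1 dichotomy; biserial as
  r_b = r_pb·√(pq)/y with y the standard-normal ordinate at the success
  proportion's quantile. The p-value of the underlying point-biserial test
  is carried through unchanged. Degenerate splits (0 or n successes) are
  errors because the ordinate transformation is undefined there. Note that
  √(pq)/y is symmetric in p ↔ q, so a split and its mirror yield the same
  |r_b|; when locating an unknown split by brute force both must be
  entertained.
* **T-maze**: percent correct over four test trials; *success* requires
  strictly more than 50% — a 2-of-4 session is a fail.
* **Assumption screen**: 1.5×IQR boxplot fences, bias-corrected sample
  skewness/kurtosis (the convention of mainstream statistical software),
  Levene with centre = mean.

# Tissue quantification

The area-fraction fractionator tiles the ROI bounding box with a square
sampling grid from a seeded random origin and counts plaque and ROI pixels
inside each counting frame. Defaults follow stereological practice for
these regions: 150 µm frames (hippocampus) and 200 µm (cortex), grid pitch
equal to the frame so the probe scans the entire ROI — in that
configuration the estimate *equals* exhaustive pixel counting, which the
tests assert exactly. With a sparser grid the estimator is unbiased over
random origins. Frames clipped by the ROI boundary contribute their
ROI-intersected pixels; no exclusion lines are used because the probe
estimates area fraction, not particle number. Subject-level burden is the
ratio of summed plaque area to summed ROI area across the five sections
(total area over total area), not the mean of per-section ratios — the two
differ whenever section ROI areas differ. Raw summed areas are reported
alongside the dimensionless burden.

ELISA readouts are normalised to pg per mg of tissue; the Aβ-42/Aβ-40
ratio is computed within each extraction fraction (soluble / insoluble) per
subject, and incomplete analyte pairs yield flagged missing ratios.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known ground truth; its defaults are the study conditions the pipeline
assumes.

* **Hypnogram**: a semi-Markov bout process with geometric dwell times
  (mean 120 s WAKE, 240 s NREM, 60 s REM — light-period values typical of
  laboratory mice, giving ~63% NREM time). REM is entered only from NREM
  and exits to wake; NREM bouts end in brief awakenings (65%) or REM
  transitions (35%).
* **EEG**: per-epoch frequency-domain synthesis — complex-Gaussian Fourier
  coefficients shaped to a per-state target density amp²·(f^−α + Gaussian
  band bumps). NREM has α = 0.5 with a delta bump at 1.5 Hz; REM and WAKE
  have theta bumps at 7 Hz. The absolute scale is a convention (no
  published absolute power exists to reproduce); the shapes are tuned once
  so NREM relative delta sits near 50%, inside the plausible 40–60% range
  for rodent NREM, and clearly above WAKE and REM.
* **Treatment effect**: the target is a *gain in measured relative delta
  power*. For an epoch at time t after an administration the injected gain
  is e·exp(−Δt/τ) (defaults e = 8 p.p., τ = 2 h), converted to a
  delta-band amplitude factor by the closed-form renormalisation
  g² = d₁(1−d₀)/(d₀(1−d₁)) with d₁ = d₀ + e. The baseline share d₀ is
  computed in the *measurement* domain — the target density weighted by the
  squared response of the three-point moving average on the 0.25 Hz
  analysis grid — so that the injected gain is what the pipeline should
  read back. Residual smearing (Hamming leakage, epoch-boundary
  discontinuities, filter edges) attenuates recovered gains by a few
  percent of the effect; the recovery tests bound the error at 1 p.p. for
  effects of 5 p.p. and larger.
* **Artifacts**: clipping events saturate the trace at the input range for
  0.1–1 s (default 1/h); transient spikes of 1–3 samples at 25× the NREM
  IQR (default 3/h) survive the smoothing stage with enough margin to
  exceed the 8×IQR reconstruction threshold. Every injected event is
  logged sample-exactly, which is what makes detector counts testable as
  equalities.
* **Cohort draws**: behavioural percent-correct and ELISA pg/mg values are
  drawn as unbounded Gaussians at configurable group means/SDs (defaults:
  the published baseline group summaries). Draws are group-level
  emulations: no trial-level structure, no truncation at 0/100 — truncation
  would shift the generating moments the recovery checks are calibrated
  against.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: EMG and scorer behaviour, within-state spectral
nonstationarity, spindle/slow-oscillation morphology, pharmacokinetic
nonlinearity (the exponential decay is a convenience), movement and
electrode artifacts other than clipping/spikes, and bounded, quantised
behavioural scores.

# Numerical choices and degenerate inputs

Seeds propagate through a single integer: cohort members and modalities
derive child seeds by a fixed affine map mod 2³¹−1, so any subset of the
bundle is reproducible in isolation. RNG state is restored after every
seeded call. Identical inputs give byte-identical outputs at every level.

Ties and boundaries: an epoch belongs to hour ⌊ZT⌋; a segment belongs to an
epoch if its centre lies in the epoch's half-open interval; band edges are
inclusive on both sides; success requires percent > 50 exactly. Zero
variance in both groups, empty ROIs, empty designs, misaligned hypnograms
and all-flagged NREM raise errors instead of returning NaN.

Problem sizes in the test-suite: property and recovery tests run on 1–6 h
recordings (the 6-h recovery windows cover ZT6–12, bracketing the ZT9
administration that defines the 9+10 summary), 20 seeds for effect
recovery, 200–1000 replicates for calibration checks, and 500 seeds for
the FDR family-wise rate — sizes chosen so the suite exercises every code
path at meaningful statistical resolution while staying fast enough to run
routinely.

# Known limitations

* The biserial transformation assumes a latent normal continuum; with n of
  8–9 its sampling error is large, and the carried-through p-value refers
  to the point-biserial test, not r_b itself.
* Pairwise comparisons after the ANOVA are deliberately unadjusted
  (LSD-style), mirroring the analysis they implement; users wanting
  familywise control should adjust externally.
* The EDF carrier for recordings is not implemented; recordings and
  hypnograms travel as TSV (see `write_recording_tsv()`), masks as ASCII
  PGM with a sidecar scale file.
* Relative power is compositional; gains in delta mechanically imply losses
  elsewhere, so band-by-band inference beyond delta should be interpreted
  accordingly.
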