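---
title: "Piecewise linear 12-lead ECG synthesis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise linear 12-lead ECG synthesis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arspl)
```

## The model and its assumptions

The voltage of an ECG lead is the projection of the heart vector onto that
lead's lead vector. Treating the torso as a linear, quasi-static volume
conductor justifies reconstructing missing leads from a reduced subset by a
linear map; treating the heart vector as a *moving* dipole — its effective
location shifts between atrial systole, ventricular systole and ventricular
diastole — implies that one global map is a compromise across electrically
different stages. The piecewise model therefore fits a separate affine
transform from `[1, I, II, V2]` to each target precordial lead per cardiac
region:

* `b_STT` on the juxtaposed ST-T regions (ventricular diastole),
* `b_RP` on the resting-phase/P-wave regions (atrial systole),
* `b_QRS` on the QRS regions (ventricular systole),
* `b_HT` for the head–tail region. The head (before the first cycle's S-wave
  end) and tail (after the last cycle's Q-wave start) are mutually unrelated
  fragments that can contain any sub-wave, so this matrix is fitted on the
  *complete* sequence rather than on the H-T samples themselves.

Lead III and the augmented limb leads need no regression. Sign conventions
for the Einthoven identity vary in the literature; we use the one consistent
with the Goldberger formulas `aVL = I − II/2` and `aVF = II − I/2`, namely
`III = II − I`, so `I − II + III = 0` and `aVR + aVL + aVF = 0` hold exactly
on every synthesized record.

Key assumptions: the model is *personalized* (trained and applied on the same
subject — no cross-subject state); the inter-lead relation is stable over the
recording; segmentation needs only R-peak anchors, not true P/Q/S/T
delineation. Regions are approximations by design — the boundaries are
experienced time windows, not fiducial points.

## Segmentation

For `M` detected R peaks at `peak_x(n)` (we require `M ≥ 3`), boundaries in
samples are

* `B_SE(n) = peak_x(n) + round(T_RS · fs)`, cycles `1…M−1`,
* `B_TE(n) = peak_x(n) + round(a_RT · rr(n) · fs)`, cycles `1…M−1`,
* `B_QS(n) = peak_x(n) − round(T_QR · fs)`, cycles `2…M`.

Only the R-T window adapts to the RR interval: the Q-R and R-S spans are
nearly rate-independent, while the distance to the T-wave end shrinks with
the cycle. Internally all indices are 0-based with half-open `[start, end)`
ranges, which removes the off-by-one ambiguity of inclusive ranges; segment
lengths obey `SegL_STT(n) = B_TE(n) − B_SE(n)`, `SegL_RP(n) = B_QS(n) −
B_TE(n−1)`, `SegL_QRS(n) = B_SE(n) − B_QS(n)`, `head_len = B_SE(1)`,
`tail_len = N − B_QS(M)`, and their sum is exactly `N`. The segmentation
pattern is fixed: `M−1` ST-T fragments, `M−1` R-P, `M−2` QRS and one H-T
region regardless of where the recording starts or ends.

Degenerate cycles are resolved by clamping, never by overlap: if `B_TE(n) ≥
B_QS(n+1)` then `B_TE(n) = B_QS(n+1) − 1` (every R-P fragment keeps at least
one sample), and if `B_SE(n)` then exceeds `B_TE(n)` it is pulled down so the
ST-T fragment becomes empty. Empty fragments are legal throughout and
round-trip through restoration. Restoration consumes fragments strictly in
cycle order and is the exact inverse of segmentation — a property the test
suite checks on randomized records including clamped degenerate cycles.

## Wavelet preprocessing

Detrending and denoising use a maximal-overlap (undecimated) discrete wavelet
transform with the symlet-5 basis, 8 levels at 1000 Hz, and symmetric
reflection extension at the record edges (minimizing artifacts in the H-T
region). The undecimated pyramid was chosen over the decimated transform
because every detail level retains the signal length, the transform is
shift-invariant (peak positions do not depend on sampling phase) and the
inverse is exact; the per-level frequency bands are identical, so the usual
dyadic level arithmetic carries over.

Zeroing the level-8 approximation removes everything below about
`fs/2⁹ ≈ 2 Hz` — baseline wander and drift. Wideband noise is removed by
soft-thresholding each detail level with a universal threshold
`T_j = σ_j √(2 ln n_j)`. The noise scale is estimated *at the finest level*,
`σ₁ = median(|d₁|)/0.6745`, and propagated as `σ_j = σ₁ / 2^{(j−1)/2}` (the
white-noise level scaling of the undecimated transform). Estimating the
scale per level from that level's own coefficients was evaluated and
rejected: on clean or low-noise ECG the deep levels are dominated by T- and
P-wave energy, so a per-level estimate reads the waves themselves as noise
and soft shrinkage visibly erodes the T wave and with it the ST level — the
very quantity the evaluation metrics protect. With the finest-level anchor,
clean signals pass essentially untouched apart from detrending.

Detrending itself has an intrinsic cost worth stating: at 60 bpm the cardiac
fundamental lies at 1 Hz, inside the removed band, and with realistic
morphology roughly 10% of the AC signal energy (mostly the T wave's slow
component) lives below 2 Hz. The correlation between a detrended clean ECG
and its raw self is therefore bounded near 0.94. Comparisons of synthesized
against reference signals are consequently most informative in the detrended
domain, and the ST-level report requires both inputs detrended identically.

## R-peak detection

The detection sequence is the band-passed component carried by detail levels
3–5 (≈15–125 Hz at 1000 Hz, covering the QRS energy band), squared and
smoothed by a centered moving average. Detection parameters, with rationale:

| parameter | default | meaning |
|---|---|---|
| `smooth_window_s` | 0.15 s | envelope smoothing, ≈ one QRS duration |
| `init_threshold_frac` | 0.30 | initial threshold as a fraction of the first-window maximum |
| `init_threshold_window_s` | 2 s | initial-threshold window |
| `adapt_threshold_frac` | 0.50 | adaptive threshold as a fraction of the recent-peak mean |
| `adapt_peak_count` | 3 | peaks averaged; adaptation starts once this many exist |
| `max_hr_bpm` | 220 | heart-rate gate: minimum RR of 60/220 ≈ 273 ms |
| `candidate_window_s` | 0.10 s | search span for the detection-sequence maximum |
| `correction_window_s` | 0.05 s | search span for the final signal-maximum snap |
| `detection_lead` | II | lead with typically the largest R amplitude |

Candidates fire where `sign(d(i)) > sign(d(i+1))` (with `sign(0) = 0`, so
plateaus fire at their right edge) and the envelope exceeds the threshold.
When a candidate violates the heart-rate gate against the most recent
registration, the one with the larger envelope value survives — a symmetric
tie-break that also merges duplicate firings within one QRS. Because the
smoothing can shift envelope maxima slightly, every registered peak is
finally snapped to the maximum of the (preprocessed) signal within the
correction window and its amplitude re-read there. All thresholds are
relative, so detection is invariant to positive rescaling of the input. At
sampling rates other than 1000 Hz the detail levels are shifted by
`round(log2(fs/1000))`, which preserves the selected band in Hz for
power-of-two rate changes.

Detection-quality scoring matches detected to reference beats one-to-one,
closest pairs first, within a 50 ms tolerance (a conventional beat-matching
window; the tolerance is a parameter of `evaluate_detection`).

## ST-level measurement

The ST level is measured 60 ms after the J-point relative to the PR segment.
Within this framework the J-point is proxied by `B_SE(n)` (the end-of-S
boundary) and the PR reference by `B_QS(n) − round(0.02 · fs)`, both
available for inner cycles `2…M−1`. The denivelation ratios count cycles
with `|STSE| > 0.1 mV` (CDR), split exactly into elevation (ER) and
depression (DR), so `CDR = ER + DR` holds by construction.

## The synthetic generator

`generate_ecg()` emulates what the method needs from real data, with ground
truth for every stage: quasi-periodic 12-lead ECG with P/QRS/T morphology
(sums of per-beat Gaussians; default amplitudes and widths chosen as typical
adult values, e.g. R = 1100 μV and T = 320 μV in lead II at widths 11 ms and
55 ms), known R-peak sample indices (wave centers snapped onto the sample
grid), region-dependent linear relations between {I, II, V2} and V1, V3–V6,
and additive baseline / powerline / white noise. Defaults: 1000 Hz, 10 s,
60 bpm, no jitter, no noise; tests and the acceptance script state their own
durations, rates, jitter and noise explicitly.

Two design points deserve explanation:

* **Truth boundaries come from wave supports, not from the segmentation
  algorithm** (`±2.5` standard deviations around each wave, with the T-wave
  offset shortened in fast cycles), so segmentation accuracy can be scored
  against independent truth rather than against itself.
* **The head–tail mixing matrix defaults to the self-consistent blend.** The
  trainer defines `b_HT` as the complete-sequence fit, so a generator using
  an arbitrary fourth matrix for head/tail samples would create data that no
  piecewise model of this form can represent exactly. Solving
  `(Σ_ρ Xᵀ_ρX_ρ) b = Σ_ρ Xᵀ_ρX_ρ b_ρ` over the three cycle regions yields
  the unique matrix that the complete-sequence fit recovers exactly when
  head/tail samples follow it; with this default, noiseless generator output
  is exactly representable and parameter recovery is a sharp test (observed
  recovery error ≈ 1e-10, synthesis residual ≈ 1e-12 μV given ground-truth
  segmentation).

What the generator does **not** emulate: pathological morphology (ectopy,
bundle-branch blocks, ST deviation), respiration-modulated amplitudes,
electrode motion artifacts, or a physical dipole-trajectory forward model.
Passing tests therefore demonstrate correctness of the algorithmic pipeline
and its self-consistency — not clinical synthesis fidelity on real
pathology, which requires recorded data.

## Numerical choices

* Canonical amplitude unit is the microvolt (native PTB-style resolution);
  the 0.1 mV denivelation threshold is 100 μV internally and ST levels are
  reported in mV. Time windows are converted to samples by `round()`.
* The least-squares solver is QR-based (`qr.coef`), numerically preferable
  to the literal normal-equations inverse; the normal-equations and
  SVD pseudo-inverse forms are kept as independent test oracles (agreement
  to 1e-10 relative on well-conditioned inputs). Fits require `N > 3`
  samples and a full-rank design; collinear source leads are an error.
* Wavelet depth is reduced with a warning when a record is shorter than
  `2^levels` samples.
* Determinism: segmentation and synthesis contain no randomness; the
  generator is fully seeded; identical inputs give byte-identical outputs.

## Problem sizes

The test suite uses 8–20 s records at 1000 Hz (plus 250–1000 Hz randomized
round-trip cases) and one 205 s record for the 200-beat detection-robustness
check at 10 dB SNR; the acceptance script uses the same 205 s detection run
and a personalized two-record protocol with 65 s per record and 50 s of
training, mirroring a realistic training length for a wearable workflow.

## Known limitations

* Region boundaries are experienced time windows; on atypical conduction
  (e.g. very wide QRS) regions will mislabel samples near boundaries and the
  regional models blend accordingly.
* Inter-region amplitude gaps are measured but deliberately untreated — no
  cross-fade or spline smoothing is applied at fragment junctions.
* No back-search for missed beats or ectopic-beat handling in detection.
* Detrending removes genuine sub-2 Hz cardiac energy (see above); ST-level
  comparisons are only meaningful with identically detrended inputs.
* WFDB support covers format 16 (header + one interleaved 16-bit signal
  file), the layout of PTB-style records; other formats are out of scope.
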