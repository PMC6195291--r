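# arspl — piecewise linear 12-lead ECG synthesis from leads I, II and V2

Wearable and mobile ECG monitors record only a few leads, while clinicians
interpret the standard 12-lead ECG. Because the torso is close to a linear,
quasi-static volume conductor, the missing leads can be reconstructed from a
reduced subset by personalized linear regression. A single global transform,
however, ignores that the equivalent cardiac dipole moves between the stages
of the cardiac cycle — atrial systole (P wave), ventricular systole (QRS) and
ventricular diastole (ST segment and T wave) — so the linear relation between
leads is itself stage-dependent.

`arspl` implements *adaptive region segmentation based piecewise linear*
synthesis: every cardiac cycle is segmented, using only R-peak positions and
experienced time windows, into four regions

- **ST-T** — from the end of the S wave `B_SE(n)` to the end of the T wave
  `B_TE(n)`,
- **R-P** — from `B_TE(n-1)` to the start of the Q wave `B_QS(n)` (resting
  phase plus P wave),
- **QRS** — from `B_QS(n)` to `B_SE(n)`,
- **H-T** — the head of the record before `B_SE(1)` spliced to the tail
  after `B_QS(M)`, which makes the segmentation pattern independent of where
  the recording starts and ends,

with `B_SE(n) = peak_x(n) + T_RS·fs`, `B_QS(n) = peak_x(n) − T_QR·fs` and
`B_TE(n) = peak_x(n) + a_RT·rr(n)·fs` (defaults `T_QR` = 0.03 s, `T_RS` =
0.04 s, `a_RT` = 0.37). Same-type regions are juxtaposed and a least-squares
model

```
L = a_L + b_L·I + c_L·II + d_L·V2        i.e.   b = (XᵀX)⁻¹ Xᵀ R,  X = [1 | I | II | V2]
```

is fitted per region (`b_STT`, `b_RP`, `b_QRS`; `b_HT` is fitted on the
complete sequence), giving the five synthesized precordial leads V1, V3–V6.
Lead III and the augmented limb leads follow arithmetically: `III = II − I`,
`aVR = −(I+II)/2`, `aVL = I − II/2`, `aVF = II − I/2`. Synthesized regions
are reassembled into full-length signals by the exact inverse of the
segmentation.

R peaks are found by Pan–Tompkins-style wavelet detection: a detection
sequence is rebuilt from sym5 detail levels 3–5 (QRS energy band), squared
and smoothed; inflection points above an adaptive amplitude threshold (30% of
the first-2-s maximum, then 50% of the mean of the three most recent peaks)
are registered, gated at 220 bpm, and snapped to the signal maximum. The
package also provides wavelet detrending/denoising, the plain
linear-regression baseline, a full metric suite (CC, RMSE, ST-level
denivelation ratios CDR/ER/DR measured 60 ms after the J-point against the PR
segment, detection Se/+P/Acc, inter-region amplitude gaps), a synthetic
12-lead generator with ground truth, and WFDB/CSV readers and writers.

## Worked example

```r
library(arspl)

# a synthetic "patient": 20 s of 12-lead ECG at 1000 Hz with mild noise
spec <- synth_spec(duration_s = 20, hr_bpm = 63, hr_jitter_frac = 0.04,
                   noise = list(white_sd_uV = 25), seed = 42)
g <- generate_ecg(spec)

peaks <- detect_rpeaks(g$record)
evaluate_detection(peaks, g$peaks$peak_x, fs = 1000)
#> Detection: TP = 20, FN = 0, FP = 0 | Se = 100.00%, +P = 100.00%, Acc = 100.00%

# train the four regional models, then reconstruct from I, II, V2 only
models <- arspl_fit(g$record, train_seconds = 20)
rec3 <- ecg_record(g$record$leads[c("I", "II", "V2")], 1000)
syn <- synthesize_arspl(rec3, models)

# agreement with the clean reference in the detrended domain (synthesis
# operates on detrended signals, so the sub-2 Hz band is removed first)
evaluate_leads(syn, denoise_record(g$clean), c("V1", "V3", "V4", "V5", "V6"))
#>   lead        cc  rmse_uv
#> 1   V1 0.9987409 11.95018
#> 2   V3 0.9989963 13.96449
#> 3   V4 0.9989129 13.76957
#> 4   V5 0.9988038 13.64093
#> 5   V6 0.9986893 13.50979
```

The detection line shows every beat found with no false alarms; the table
shows the five synthesized precordial leads agreeing with the reference at
correlations above 0.998 with residuals of 12–14 μV — noise-floor level for
the 25 μV measurement noise in this record.

A command-line wrapper (`inst/cli/arspl.R`) exposes the same pipeline as
`simulate`, `detect`, `train`, `synth` and `eval` subcommands; see
`Rscript inst/cli/arspl.R help`.

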