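---
title: "Camera-based vital signs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based vital signs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppgvitals)
```

## The measurement problem

Cardiac activity modulates the blood volume in skin capillaries, which
modulates how much light the skin absorbs: skin flashes minutely darker
and brighter at the pulse rate. A camera watching a face therefore
carries a photoplethysmographic signal in the spatially averaged pixel
intensities of skin patches, and the contrast between a red band and a
near-infrared band additionally carries arterial oxygen saturation,
because oxy- and deoxy-haemoglobin absorb those bands very differently.
`rppgvitals` turns such per-frame, per-region pooled intensities — five
face regions in R, G, B, grey and IR — into per-window heart rate and
SpO2.

The processing model makes three assumptions worth stating explicitly.
First, the pulse appears as a narrowband component between 0.66 and
3.33 Hz (39–200 BPM), so the dominant in-band spectral peak of a
suitably cleaned signal is the heart rate. Second, pixel pooling and
channel mixing are linear, so linear source-separation methods (ICA,
PCA, JADE) can unmix pulse from noise. Third, any region or channel may
be the cleanest on a given subject at a given moment (motion, makeup,
beard, illumination), so the pipeline scores *every* region × component
candidate by a spectral signal-to-noise ratio and lets the best one win
per window, rather than committing to one region or one channel.

## The processing chain

Per window the chain is: align channels onto the colour stream's even
grid → pre-process → separate sources → FFT magnitude spectrum →
cardiac bandpass → dominant peak + SNR per candidate → best-SNR
candidate gives HR; the grey channel's bandpassed waveform, sampled at
its pulse peaks against raw red, raw IR and distance, gives SpO2; a
reliability gate compares both against the previous window.

### Pre-processing registry

Seven techniques compose six primitives in fixed orders; the two that
matter in practice are technique 6 (detrend → interpolate onto an even
grid → Hamming taper → L2 normalise) and technique 7, which inserts an
FFT upsampling step (factor 2) after detrending. Technique 1 is the raw
signal and technique 2 normalisation only; techniques 3–5 (which add
median filtering and a moving average) are retained so that the full
registry is testable, including the negative result that they tend to
flatten the cardiac peak. The "smooth" step is a centred moving average
with window 5 — the registry needs *a* definition, a moving average is
the conventional one, and its effect is assessed empirically rather
than assumed.

The fps-adaptive rule selects technique 7 below 15 fps and technique 6
at 15 fps and above; exactly 15 fps maps to technique 6 (the boundary
must fall somewhere, and upsampling buys nothing once the Nyquist rate
comfortably exceeds the passband). A window's frame rate is the
*minimum* per-second frame count across all streams in the window — a
conservative choice, since the weakest stream limits the usable joint
sample grid.

### Source separation

FastICA is implemented with symmetric (parallel) estimation, the
logcosh contrast, whitening on, tolerance 1e-4 and at most 500
iterations; the unmixing matrix is initialised from a configurable seed
so runs are reproducible. "Applying ICA three times" means feeding the
components of one pass back in as the next pass's input; passes beyond
three are clamped with a warning because further repetitions do not
change the extracted subspace. JADE joint-diagonalises the fourth-order
cumulant matrices of the whitened data with Jacobi rotations. Spectral
embedding treats the T time samples as points in channel space, builds
an RBF affinity (γ = 1/n_channels, the common default) and uses the
bottom non-constant eigenvectors of the symmetric normalised Laplacian
as candidate series, sign-fixed deterministically; its component count
equals the channel count so it plugs into the same candidate machinery
as ICA. Non-convergence is flagged on the candidate, never silent.

### Spectral scoring

The SNR of a candidate is its dominant peak magnitude divided by the
*mean in-band magnitude after the bandpass, peak bin included*. The
denominator could plausibly include out-of-band bins or the DC term;
we restrict it to the band because the score is meant to compare
candidates on cardiac-band content only, and magnitudes keep it real
and positive. A flat in-band spectrum scores exactly 1. The bandpass is
a frequency-domain mask (filtering happens after the FFT), which makes
it exactly idempotent. Peak detection takes strict local maxima with no
prominence threshold — the SNR threshold downstream is the quality
gate — and ties break toward the lower frequency.

### SpO2 pathway

The ratio-of-ratios uses raw values: at each pulse peak of the
bandpassed grey waveform, the nearest-timestamp raw red, raw IR and
distance samples enter

\[ q = \frac{\varepsilon^{red}_{HbO_2}}{\varepsilon^{ir}_{HbO_2}}
      \cdot \frac{I \cdot d}{R} / 52, \qquad
   SpO_2 = 100\,\frac{\varepsilon^{red}_{Hb} - q\,\varepsilon^{ir}_{Hb}}
                     {\varepsilon^{ir}_{HbO_2} + \varepsilon^{red}_{Hb}
                      - \varepsilon^{ir}_{Hb} - \varepsilon^{red}_{HbO_2}}
            - C . \]

The trailing 52 is a divisor (it is a *scaling factor* for the ratio),
and the constant offset C = 6 is subtracted after the 100× ratio. The
per-peak values are averaged (mean, not median — with a handful of
peaks per window the mean uses all of them and the gate already rejects
outlier windows), the result is clipped to [0, 100] %, and the
grey-channel HR SNR serves as the quality proxy in the gate since the
ratio itself has no natural SNR. Nearest-timestamp lookup handles the
IR stream's separate clock; at camera frame spacing the worst-case
mismatch is half a frame interval, negligible against the pulse period.

The extinction coefficients ship as a small CSV
(`inst/extdata/hb_molar_extinction_synthetic.csv`): the 860 nm row for
the IR band and a 10 nm-resolution red band averaged over 600–700 nm.
The file is a clearly labelled synthetic reconstruction of the standard
public compilation — coarse, but preserving the orderings the method
rests on (ε_ir_HbO2 > ε_ir_Hb above the isosbestic point,
ε_red_Hb ≫ ε_red_HbO2) — and can be swapped for exact rows via the
`path` argument of `load_extinction_table()`. Because the synthetic
generator encodes SpO2 by inverting the same relation with the same
table, every closed-loop property of the pipeline is independent of the
table's absolute values; only absolute calibration against a real
oximeter would require the exact rows.

### Reliability gate

A new window estimate is held — previous values returned, flagged
`accepted = FALSE` — when its SNR is below 5.0 or when HR or SpO2
deviates from the previously held value by more than 18 % relative.
Vitals change gradually; a stable 60 BPM does not leap to 144 BPM for
one second. The first window is accepted unconditionally (there is
nothing to compare against), and a window with no usable candidate
always inherits the previous estimate.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_s` / `step_s` | 15 / 1 | s | 15 s gives 1/15 Hz = 4 BPM resolution; 1 s steps track change |
| `band` | 0.66–3.33 | Hz | plausible HR range, 39–200 BPM |
| `snr_threshold` | 5.0 | — | below it, in-band content is too close to the noise floor |
| `deviation_factor` | 0.18 | relative | physiological rate-of-change bound between 1 s steps |
| `preprocess` | auto | — | technique 6, or 7 below 15 fps |
| separation | FastICA ×1, joint | — | best general performer; PCA→ICA is the preset for active subjects |
| SpO2 `scaling` / `offset_c` | 52 / 6 | — / % | IR/red scaling factor; constant device offset |

## The synthetic generator

Each channel is `baseline + amplitude · sin(2π φ(t)) + trend·t + ε`,
with φ(t) the integral of the instantaneous cardiac frequency HR(t)/60
(computed on a 4 ms grid, so HR ramps and random walks produce a
continuous phase), ε Gaussian sensor noise, timestamps at the
configured per-second frame counts with Gaussian jitter, and the grey
channel derived from the noisy R, G, B exactly as the reader would
derive it. Defaults — 60 s, 30 fps both streams, 1 ms jitter, 72 BPM,
97 % SpO2, baselines R 120 / G 90 / B 70, amplitudes R 1.5 / G 2.0 /
B 1.0 / IR 1.5 (green strongest, as in skin reflectance), noise sd 0.2
(10 % of the green amplitude), 0.5 m distance — are the package's
reference study conditions.

SpO2 is encoded in the IR DC level: the target ratio is obtained by
algebraically inverting the saturation relation, and the IR baseline is
set so that the *systolic-peak* IR/red pair (baseline plus amplitude,
scaled by distance) reproduces it exactly — because the forward path
samples raw values at pulse peaks. The per-frame target is interpolated
smoothly between seconds; a per-second stepped DC level would inject a
spurious 1 Hz comb into the IR spectrum that a source separator happily
isolates (we observed exactly that before making the interpolation
smooth). The waveform is a pure sinusoid: the pipeline only uses the
fundamental peak, so harmonics would add realism without changing what
the tests can show.

What the generator does *not* emulate: facial motion geometry, specular
illumination changes, skin-tone-dependent amplitude (no quantitative
melanin model exists in this framework — amplitude is a free knob),
beards or makeup. Their effects enter only as extra noise via
`noise_sd`, so a passing test suite demonstrates correctness of the
processing chain under its stated signal model, not field accuracy on
real faces.

## Numerical choices and degenerate inputs

Median filtering uses zero-padded edges (the convention of the usual
1-D routine); the Hamming taper rejects length-1 signals (the window
formula is degenerate); L2 normalisation rejects all-zero signals;
FFT upsampling splits the Nyquist bin for even lengths; box-coordinate
mapping floors to integer pixels and clips inside the IR frame;
candidate ties break by region-then-channel order, and spectral-peak
ties toward the lower frequency, keeping every run deterministic.
Distance used at a pulse peak is the nearest-timestamp sample (the
sensible choice when only a timestamped trace is available). All
randomness — generator noise, jitter, ICA initialisation — flows from
explicit seeds through a local RNG that never disturbs the caller's
stream, which is what makes `simulate`/`process` bitwise reproducible.

## Problem sizes used in the checks

The shipped checks run 60 s recordings at 30 fps (46 windows) across an
HR grid of 48/72/120/180 BPM with five seeds, a 12 fps low-frame-rate
variant, and an SpO2 grid of 90/93/96/99 % in noise-free and noisy
conditions — sizes chosen so the full suite exercises every path in
about a minute on one CPU. Under these conditions HR is recovered to
within the 4 BPM frequency-bin bound (median), SpO2 to ≤ 0.5 %
noise-free and ≤ 2 % noisy, and `scripts/acceptance.R` reports the
corresponding RMSE/MAE/correlation numbers recomputed from scratch.

## Known limitations

Windowed spectral estimation lags a moving reference by roughly half a
window, which dominates the HR error on ramps. The gate can lock onto a
wrong value if a spurious candidate wins many consecutive windows (the
deviation factor then rejects the correct one); the SNR threshold makes
this rare but not impossible. JADE's cumulant matrices grow as n², so
it is the slowest method. The extinction table is synthetic (see
above); absolute SpO2 calibration on real data requires exact
coefficients and a device-specific offset C.
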