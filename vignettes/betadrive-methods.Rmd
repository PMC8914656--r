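---
title: "From analog front end to beta-band statistics: the betadrive methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From analog front end to beta-band statistics: the betadrive methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadrive)
```

`betadrive` is a software counterpart of a six-channel dry-electrode EEG
headband (Fp1, Fp2, C3, C4, O1, O2; common mastoid reference) and of the
analysis that uses it to compare driver stress between manual and autonomous
driving.  It has three layers: a *digital twin* of the acquisition hardware
with its metrological characterization, a *synthetic cohort generator* with
known ground truth, and the *signal-processing and statistics chain* (clean,
estimate band powers, compare conditions).  This vignette explains the
models, the defaults and the numerical choices.

## The acquisition chain

### Analog front end

Each channel is a band-pass amplifier.  A passive high-pass input filter and
a DC-compensation loop contribute a double zero/pole pair at
$1/\tau_{HP}$, and a third-order anti-alias filter contributes three
coincident poles at $1/\tau_{LP}$:

$$H(s) \;=\; G_1 G_2 \,
\frac{(\tau_{HP}\,s)^2}{(1+\tau_{HP}\,s)^2\,(1+\tau_{LP}\,s)^3},$$

with defaults $G_1 = 680$, $G_2 = 6.6$ (overall gain $4488$),
$\tau_{HP} = 0.33$ s, $\tau_{LP} = 2.7$ ms.  The magnitude rises at
+40 dB/decade below the band and falls at −60 dB/decade above it
(`analog_transfer()`).  Two conventions exist for the −3 dB cutoffs: relative
to the *peak* of the response or to the *nominal* gain $G_1G_2$.  They
differ because the response has no flat top: the lower cutoff is 0.725 Hz
peak-referenced and 0.750 Hz nominal-referenced.  `estimate_bandwidth()`
supports both and defaults to the peak; the design figures quoted for this
front end (0.75/0.8 Hz) correspond to the nominal reference.  The upper
cutoff from these constants is near 30 Hz; the design documentation quotes
44 Hz, which is not reproducible from the stated time constants, so only
the slopes and the lower cutoff are treated as checkable figures.

For time-domain simulation (`simulate_front_end()`) the transfer function is
discretized by the bilinear transform at the oversampled rate of 3200 Sa/s,
with the gain matched to the continuous response at 5 Hz; at the frequencies
of interest (≪ Nyquist) warping is negligible.  Amplifier noise is injected
at the input as white Gaussian noise with the datasheet density
(35 nV/√Hz) and shaped by the same response.  Consequently the realized
input-referred noise equals the density times the square root of the chain's
*equivalent noise bandwidth* (≈ 33.6 Hz, hence ≈ 203 nV), a little below the
rectangular-band budget figure $\sigma_A = 35\,\mathrm{nV}/\sqrt{\mathrm{Hz}}
\cdot \sqrt{44-0.8\,\mathrm{Hz}} = 230$ nV used in `noise_budget()`; the
budget is the conventional, slightly conservative bookkeeping.

### Oversampling converter and noise budget

The 12-bit converter samples at 3200 Sa/s and the firmware sums blocks of
16 codes into one 200 Sa/s datum (`quantize_and_oversample()`).  Summing
$k$ independent noisy samples multiplies the signal by $k$ and the noise by
$\sqrt k$, an SNR gain of $\sqrt{16} = 4$, i.e. two effective bits
(`snr_improvement_experiment()` verifies the closed form by Monte Carlo).
The wire datum is kept as the raw sum (0–65520); "14 bit" is the effective
resolution, and `counts_to_input_microvolts()` divides by 16 before mapping
codes back through the reference offset and gain.

`noise_budget()` reproduces the design arithmetic: quantization noise
$\sigma_Q = V_{supply}/(G\,2^{12}\sqrt{12}) \approx 52$ nV by formula; the
design documents round this to 60 nV, and `sigma_q_override` lets the
budget carry that printed value so the published chain
(230 ⊕ 60 → 240 nV, /4 → 60 nV, $\mathrm{ENOB} = \log_2(700\,\mu V/60\,nV)
= 13.51$ bit, 14-bit step 43 nV) is reproduced exactly.

### GUM characterization

The bench protocol steps a 5 Hz sinusoid through 47 amplitudes
(0.1–2.4 V peak-to-peak) behind a 0.303·10⁻³ attenuator and takes 20 RMS
readings per amplitude.  The package implements the uncertainty calculus as
first-order GUM propagation: `input_uncertainty()` for the attenuated
stimulus, `output_uncertainty()` (type A of the mean ⊕ type B) for the
readings, `fit_gain()` as the moment-form least-squares slope
$\mathrm{cov}(V_{IN}, \bar V_{AD})/\mathrm{var}(V_{IN})$ (the only reading
of the overbar notation that is dimensionally a gain, offset-invariant by
construction), and `gain_uncertainty()` propagating every per-point
uncertainty through the slope — analytically for the outputs, by central
differences for the inputs, both validated against Monte-Carlo oracles in
the tests.  `linearity_error()` reports residuals from the fitted line in
volts and as %FS; the %FS normalization uses a 750 µV span so that 0.8% FS
corresponds to 6 µV.

`synth_characterization_run()` simulates the whole protocol against the
twin.  Two modelling choices matter.  First, the recovered slope is the
chain's gain *at the stimulus frequency*, $|H(5\,\mathrm{Hz})| \approx
4399$, not the asymptotic product 4488 — the stimulus sits on the gently
curved top of the band-pass.  Second, the simulated instrument is ideal
(reading scatter 1 mV) while the propagated budget carries the conservative
type-B allowances a bench protocol would quote (2 mV instrument, 1 mV
stimulus, 3·10⁻⁶ attenuator).  Budgets built from manual specifications
bound rather than estimate the realized error, so coverage of the true gain
within the expanded uncertainty $2u(G)$ is comfortably above the nominal
95%; the acceptance suite checks exactly that.

### Power-line notch

`design_notch()` builds the second-order IIR notch used on the receiving
side: zeros just inside the unit circle at 50 Hz (radius sets the designed
depth, default 40 dB), poles at the same angle with radius set by a 3 Hz
bandwidth, gain normalized at DC.  The returned object carries its own
evaluated response; the design errors out unless the attenuation at $f_0$
reaches the requirement (30 dB) and the response deviates less than 1 dB
outside $f_0 \pm 5$ Hz.

## Synthetic cohorts

`generate_band_signal()` produces stationary Gaussian processes confined
exactly to a band: white noise is shaped in the frequency domain (bins
outside $[f_{lo}, f_{hi})$ zeroed) and rescaled so the realized variance
equals the requested power.  We chose brick-wall shaping over re-using the
cleaning filter because it guarantees zero out-of-band power and exact
power control, which makes ground truth unambiguous.  No explicit 1/f
background is added: the analysis consumes band integrals only, so the
band powers are the complete description.  Within-session variability is
whatever the stationary process produces (the 4 s Welch windows see the
natural $\chi^2$ scatter); no extra slow modulation is modelled.

A cohort (`cohort_spec()`, `generate_cohort()`) mirrors the driving study:
10 subjects × three conditions (Manual, gentle autonomous "ADAS1",
aggressive autonomous "ADAS2"), sessions 420–600 s at 200 Sa/s.  True
per-channel beta powers are drawn log-normally with medians equal to the
per-channel medians of the bundled reference cohort and $\sigma_{\log} =
0.35$, chosen once from the spread of the reference columns (per-channel
log-SDs 0.26–0.51).  Background band powers default to δ 10, θ 6, α 8,
γ 1.5 µV².  Artifacts (`inject_artifacts()`): blinks (12/min, 400 ms
biphasic, ~100 µV, fixed frontal-dominant loading), motion bursts (2/min,
1–2 s, broadband, 8× channel RMS on all channels), and a 5 µV 50 Hz line.
Every session is regenerable in isolation (`generate_session()`) from the
master seed, so study-scale cohorts can be processed one session at a time
in constant memory.

What the generator does *not* emulate: volume conduction (channels are
independent, so ICA has no cross-channel brain topography to find),
non-stationary band power, ECG and electrode-impedance drift.  Passing
recovery tests therefore demonstrate the pipeline's bookkeeping and artifact
arithmetic, not its behaviour on physiological source mixtures.

## Cleaning pipeline

`preprocess_recording()` chains three steps.

1. **Band-pass** (`fir_bandpass()`): windowed-sinc (Hamming) linear-phase
   FIR with passband edges [1, 45] Hz, applied forward-backward (zero
   phase).  The −6 dB points sit at 0.675 and 47 Hz so the passband proper
   starts at 1 Hz and the stopbands are reached one octave below the lower
   edge and before 50 Hz; the transition widths (0.35 Hz / 4 Hz) set the
   filter length (≈ 1900 taps at 200 Sa/s), and filtering is done by FFT
   convolution with odd-reflection padding.
2. **Simplified ASR** (`asr_clean()`): 0.5 s windows, 50% overlap, von Hann
   overlap-add.  Windows are whitened against calibration statistics
   (MAD-based channel scales + calibration correlation; calibration
   defaults to the lowest-RMS 60 s of the recording).  Per window,
   principal directions whose variance exceeds the calibration spread —
   mean window variance plus `cutoff_k` (default 20) standard deviations of
   the calibration window-variance distribution — are projected out and the
   window is rebuilt from the retained subspace.  Expressing the cutoff in
   SDs of the calibration variability follows the reference implementations
   of the method; a multiple of the calibration variance itself would leave
   burst edges untouched.  `cutoff_k = Inf` is an exact identity.
3. **ICA removal** (`ica_unmix()`, `classify_components()`,
   `remove_components()`): square symmetric fixed-point ICA with the tanh
   contrast on whitened data, deterministic for a fixed seed, components
   ordered by explained variance.  Components are labelled ocular (frontal
   loading share > 0.6 *and* sub-4 Hz power fraction > 0.6), line (50 Hz
   density > 10× spectral median), else brain; non-brain components are
   zeroed and the data re-projected.  The thresholds are module defaults,
   overridable — the underlying study reports no values for them.

The ordering (filter → ASR → ICA) means blinks are usually absorbed by ASR
before ICA sees them; the ICA stage matters when ocular activity is too
frequent or too small to trip the subspace threshold.

## Spectral estimation

`welch_psd()` is the classic averaged periodogram: 4 s von Hann windows,
50% overlap, per-segment mean removal, one-sided density scaled so its
integral equals the signal variance.  An 8 min session at 200 Sa/s yields
239 averaged segments.  `band_power()` integrates the density by the
trapezoidal rule with edge interpolation over the half-open clinical bands
(δ [0.5, 4), θ [4, 8), α [8, 12), β [12, 30), γ [30, 45), the last capped
at the filter's upper passband edge).  "Session mean beta power" is the
whole-session Welch band power; `eeg_spectrogram()` returns the per-window
densities, whose time average equals the Welch estimate by construction.
Band powers are computed *after* cleaning.

## Group statistics

`ranksum_test()` implements the two-sample Wilcoxon rank-sum test with
mid-ranks: a normal approximation with tie-corrected variance and *no*
continuity correction, and a tie-aware exact method that enumerates the
permutation null by dynamic programming over doubled ranks (feasible to
$n+m = 24$).  `signed_rank_test()` is the paired analogue (zero differences
dropped and counted; exact sign-flip enumeration to $n = 20$).  Two-sided
exact probabilities are `min(1, 2·min(lower, upper))`.

A deliberate identity choice: the published comparison table for this study
is reproduced by the *two-sample rank-sum* test under the uncorrected
normal approximation — all five of its significant cells match at printed
rounding — whereas the paired signed-rank test (which the study's text
names) contradicts them, e.g. a condition pair whose differences are all
one-signed would force p ≈ 0.002 where 0.05 is printed.
`build_comparison_table()` therefore uses the rank-sum/normal variant, with
display rounding of two decimals (three below 0.005).  On these data the
exact and normal methods differ by at most ≈ 0.034 (largest near p ≈ 0.7,
where the approximation is loosest and nothing is at stake).

`percentile_summary()` reports the 5/25/50/75/95 linear-interpolation
percentiles used for the cohort box plots.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; internal draws restore the
  caller's RNG state (`with_seed`), and per-session seeds are derived
  arithmetically from the master seed within the 32-bit range.
* Quantizer: round-to-nearest with saturation; out-of-range samples are
  clipped and the clip fraction reported, never fatal.  Trailing partial
  blocks are dropped with a warning.
* `fit_gain()` rejects designs with fewer than three distinct amplitudes or
  zero input variance; `ica_unmix()` rejects rank-deficient data with
  advice; zero-noise budgets report unbounded effective resolution rather
  than NaN; an all-zero difference vector makes the signed-rank test
  explicitly degenerate (`p = NA`) rather than silently significant.
* Problem sizes in the shipped tests: Monte-Carlo oracles use 2·10⁴–2·10⁵
  draws, the oversampling check 10⁵ blocks, coverage 60 synthetic
  characterization runs, and the cohort-recovery check one full
  study-scale cohort (10 × 3 sessions of 7–10 min); these sizes put the
  Monte-Carlo error well inside each asserted tolerance.

## Known limitations

* The twin models the signal chain, not electrode-skin impedance, DC
  recovery transients, or transmission framing.
* Synthetic channels are spatially independent; ICA component topographies
  on such data are arbitrary for the Gaussian background, and only strongly
  non-Gaussian sources (blinks, line) are identifiable.
* The simplified ASR zeroes rejected directions instead of re-imputing them
  from calibration correlations, slightly biasing power downward in
  reconstructed windows.
* The upper −3 dB cutoff implied by the stated time constants (~30 Hz)
  disagrees with the quoted 44 Hz bandwidth; the package treats the slopes
  and lower cutoff as the checkable facts and leaves the discrepancy
  documented.
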