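---
title: "Methods: neurovascular analysis of line-scan velocimetry and DC-coupled LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neurovascular analysis of line-scan velocimetry and DC-coupled LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurovasc)
```

## The experimental setting this package models

In the endothelin-1 (ET-1) model of focal cortical ischemia, a
vasoconstrictor is micro-injected into rat cortex while two modalities are
recorded simultaneously: red-blood-cell velocity (vRBC) in individual
penetrating microvessels, measured by two-photon line scanning along the
vessel axis, and the DC-coupled local field potential (LFP) from
micropipettes at the injection site and in the surrounding peri-injection
zone.  The injection produces a rapid vRBC drop, a period of ischemia,
spreading depolarizations (SDs) while perfusion is critically low, a
transient recovery of vRBC above 80% of baseline followed by a plateau
around a third of baseline, and — after the last SD — sustained
theta/alpha-band discharges termed post-ischemic potentials (PIPs).

`neurovasc` implements the computational chain for such experiments:

1. **LS-PIV** — line-scanning particle image velocimetry: vRBC from
   kymographs (`estimate_velocity()`, `quality_filter()`).
2. **LFP conditioning** — zero-phase 1 Hz high-pass and 60 Hz notch,
   FFT band power, band-wise Morlet wavelet magnitude series
   (`preprocess_for_power()`, `band_power()`, `cwt_band_series()`).
3. **Event detection** — SDs on the raw DC-coupled trace, PIPs on the
   wavelet series (`detect_sds()`, `detect_pips()`).
4. **Timeline segmentation and metrics** — baseline / ischemia / partial
   recovery, RBC distance, band-power changes, vRBC fraction at SD onset
   (`segment_periods()`, `rbc_distance()`, `power_change()`,
   `vrbc_fraction_at_onset()`).
5. **Optogenetic stimulus synthesis** — band-limited drive waveforms and a
   randomized schedule (`synthesize_band_waveform()`, `build_schedule()`).
6. **Statistics and reporting** — location chi-squared, AUC–PIP
   correlation, JSON report (`chi_squared_uniform()`,
   `pearson_correlation()`, `build_report()`).

Because no recordings from such experiments are publicly deposited, the
package ships a first-class synthetic-data generator
(`generate_kymograph()`, `generate_lfp()`, `generate_scenario()`) that
emulates both modalities with machine-readable ground truth.  All validation
is property-based against this generator.

## LS-PIV: velocity from kymographs

A kymograph stacks repeated line scans (rows = lines, ~1.1–1.3 ms apart;
columns = position, ~1 µm/px).  Unlabeled RBCs exclude the intravascular
dye, so cells appear as dark streaks on a bright plasma background; a cell
moving at $v$ mm/s displaces by $d = v\,\Delta t / \Delta x$ pixels per line
($\Delta t$ in ms, $\Delta x$ in µm — conveniently, mm/s ≡ µm/ms).

`estimate_velocity()` works on blocks of `window_lines` lines (default 32,
50% overlap).  Each line is mean-subtracted (removing the illumination
offset that would otherwise dominate the correlation) and normalized to
unit energy; the cross-spectra of all consecutive line pairs in the block
are averaged and inverted to one normalized circular cross-correlation.
The peak position is the displacement per line; `quality` is the peak
height in $[0,1]$.  Sub-pixel localization uses Fourier upsampling of the
correlation (16×) followed by a 3-point parabolic fit on the fine grid;
plain parabolic interpolation on the integer grid exhibits classical
peak-locking bias of up to several hundredths of a pixel, which matters at
the slow end of the 0.5–10 mm/s range, while the upsampled fit leaves a
residual well below 0.1%.  Ties between equal peaks resolve toward the
smaller absolute shift (minimal-motion prior).  Blocks with no texture
(all-constant lines) yield `NA` velocity at `quality` 0 rather than a
spurious estimate.

The sign convention — positive velocity is motion toward increasing column
index — is recorded on the output.  Arteriole/venule identity depends on
scan orientation relative to the pial surface and is therefore
caller-supplied metadata, never inferred.

## LFP conditioning

SD detection needs the raw DC-coupled trace, so conditioning never touches
the input object; `preprocess_for_power()` returns a filtered copy used by
the spectral analyses.  The 1 Hz high-pass and 60 Hz notch are realized by
frequency sampling: mirror padding, FFT, multiplication by a real
raised-cosine response (high-pass ramp 0.7–1.3 Hz; notch zero within
±1 Hz of 60 Hz with 2 Hz shoulders), inverse FFT.  At a 1 Hz cutoff on a
10 kHz recording the normalized cutoff is $10^{-4}$, where recursive
filters in transfer-function form are numerically fragile; the
frequency-sampling filter is unconditionally stable, exactly zero-phase
(event timing unbiased), and idempotent everywhere outside its narrow
transition bands.

`band_power()` integrates the Hann-tapered one-sided periodogram over the
five bands (theta 2–10, alpha 10–15, beta 15–30, low gamma 30–80, high
gamma 80–120 Hz).  A frequency bin on a shared boundary belongs to the
lower band — a declared convention; the band powers then partition the
2–120 Hz total exactly.  The reference window is 120 s; shorter windows are
accepted with a classed warning (`nv_short_window`) since synthetic and
clipped segments are routinely shorter.

`cwt_band_series()` computes the magnitude of an analytic Morlet transform
($\omega_0 = 6$, i.e. ≈6 cycles — the standard compromise between time and
frequency resolution for band-localized LFP power) on a logarithmic scale
grid of ≥8 voices per octave spanning the band, and averages magnitude
across scales.  The trace is decimated beforehand to ≥4× the band's upper
edge (anti-aliased; the output rate is declared on the result) — the series
feeds a threshold rule operating on multi-second timescales, so full-rate
sampling is pure cost.  The transform is exactly linear in input
amplitude.

## SD detection

The rule: a candidate opens when the trace falls below
$\mu_b - 10\sigma_b$ (baseline mean minus ten baseline SDs); it is
confirmed after more than 10 s below threshold; it closes when the trace
recovers to 80% of the baseline mean, after which baseline statistics are
re-estimated from the post-event segment before detection resumes (so a
second SD on a shifted baseline is still found).  Implementation choices
the rule itself does not fix:

* **Smoothing.** Detection runs on a 0.5 s moving average of the raw
  trace: SDs are multi-second DC events and 10 kHz noise would chatter the
  threshold.  Baseline statistics are computed on the same smoothed series
  so threshold and signal are commensurate.  Amplitude, however, is
  measured on the raw trace (baseline mean minus raw minimum), a declared
  choice.
* **Recovery vs. candidate threshold.** When baseline variability is small
  the candidate threshold ($\mu_b - 10\sigma_b$) can lie *above* the 80%
  recovery level, and vice versa.  Recovery therefore closes the event any
  time after confirmation, regardless of the candidate threshold.
* **"Recovered to 80% of the baseline level"** is read as the trace rising
  to at least $0.8\mu_b$ for a positive baseline; sign conventions differ
  across rigs, so this is stated explicitly.
* **Truncation.** A trace that never recovers yields an event ending at
  the trace end with a `truncated` flag.
* AUC is the trapezoidal integral of $\max(0, \mu_b - x(t))$ over the
  event, reported in mV·min.

The synthetic SD waveform is a smooth trapezoid: raised-cosine fall over
5 s, plateau at the stated amplitude, raised-cosine recovery, inside the
nominal `[onset, onset + duration]` footprint.  The ramp shape is
not fixed by the SD definition; 5 s is a modeling choice.  The
ground-truth table therefore also reports *rule-consistent* onset/end times
computed analytically from the noiseless waveform (where the deflection
crosses $10\sigma_b$, and where it recovers to 80% of baseline): this is
what an ideal noise-free detector applying the definition verbatim would
measure, and it is the reference for duration-recovery checks — comparing
against the raw footprint would penalize the detector for the ramps of the
waveform itself.

## PIP detection

PIPs are periods when the theta- and alpha-band wavelet coefficients stay
more than two baseline SDs above the baseline mean for longer than 2 s.
Choices:

* **Band combination.** Whether the theta-and-alpha condition is a
  conjunction or a disjunction is ambiguous; both are implemented
  (`combine = "either_band"` / `"both_bands"`).  The default is
  `either_band`: under the conjunction reading a pure-theta burst could
  never qualify, which would make the alpha specification redundant for
  the dominant theta events.
* **Boundary refinement.** For a strong burst the fixed 2-SD level sits
  deep in the Morlet magnitude tail (the magnitude decays as a Gaussian in
  time around the burst), which smears a 3 s burst into a ≈4 s
  supra-threshold run.  After the 2-SD rule nominates a run, its
  boundaries are refined at half of the event's peak $z$; for events whose
  peak barely exceeds threshold this is a no-op, so the weak-burst limit —
  the regime the rule was written for — is unchanged.  The >2 s
  persistence is applied to the refined duration.
* Events from the two bands overlapping or closer than 0.5 s are merged
  with band sets unioned.
* The series derives from the high-passed trace, so detection is invariant
  to trace-wide DC offsets; a baseline window shorter than 10 s is
  rejected as statistically unstable.

## Timeline segmentation and metrics

`segment_periods()` defines: baseline = pre-injection span (its mean is
the baseline vRBC); peak drop = argmin of the smoothed post-injection
velocity; ischemia = the five minutes after the peak drop; partial
recovery = from the first sustained (≥10 s) return of smoothed velocity to
80% of baseline after the end of ischemia, to the end of the recording,
flagged absent if the threshold is never re-crossed.  Smoothing is a 30 s
running median — robust to isolated LS-PIV outliers, which must not define
the nadir — with the width configurable.  Two refinements keep boundary
placement at the data resolution: the 80% crossing is interpolated
linearly between the bracketing samples (removing the half-sample
quantization bias of "first sample above threshold"), and sub-2 s dips
below threshold do not break sustainment, since they are single-sample
measurement noise at the velocity sampling rate.  All thresholds are
relative, so segmentation is invariant to uniform velocity rescaling.

`rbc_distance()` is the trapezoidal integral of velocity over a period
(mm); interior gaps are bridged linearly, but if gaps (including uncovered
period edges, with a tolerance of 3 median sample spacings, at least 2 s)
exceed 20% of the period the function refuses and reports the coverage.
`power_change()` is $100\,(P_{test}-P_{ref})/P_{ref}$ per band plus the
2–120 Hz total.  `vrbc_fraction_at_onset()` evaluates the smoothed
velocity at each SD onset relative to baseline vRBC, undefined (with a
flag) when the onset falls in a gap wider than 10 s.

## Optogenetic stimulus synthesis

`synthesize_band_waveform()` sums equal-amplitude sinusoids at every
integer frequency from the band's lower to upper edge inclusive (1 Hz
increments; shared edge integers such as 10 Hz belong to both adjacent
bands), with seeded random phases to bound the crest factor, then
normalizes to $[0,1]$ and quantizes to $2^{12}$ mid-riser levels at
500 Hz — emulating export to a 12-bit DAC.  The description of the
waveform construction admits several readings (literal convolution of
sinusoids is degenerate); superposition is implemented as the only
interpretation that yields the described band-limited drive, and this is
the one substantive reinterpretation in the package.  Mid-riser
quantization keeps the maximum quantization error at exactly
$2^{-(bits+1)}$ of full scale.  All five default bands fit under the
250 Hz Nyquist limit; a band that does not fit raises an error naming the
offending components.  `build_schedule()` presents each band once per
block in seeded random order, 60 s on / 60 s off.

## Statistics

`chi_squared_uniform()` is the uniform goodness-of-fit test
($\sum (o_i - e)^2/e$, $e = n/k$, $df = k - 1$, p from the chi-squared
survival function, via `stats::chisq.test`).  For the reference example
counts (39, 18) the statistic is 7.737 and the closed-form p ≈ 0.0054; a
reference value of p = 0.02 circulates for these counts and presumably
reflects a test variant (continuity correction or per-animal structure)
that cannot be reconstructed, so the closed form is implemented and the
discrepancy simply documented.  At small totals the asymptotic p can differ from the
exact multinomial probability by several tenths, so an `exact = TRUE` mode
enumerates the uniform multinomial exhaustively; the tests cross-check it
against independently coded binomial/trinomial oracles.
`pearson_correlation()` wraps `stats::cor.test`.  Group-level
mixed-effects comparisons are deliberately out of scope — they are routine
statistics on animal data this package cannot have; the report confines
itself to per-experiment descriptive summaries and the two bespoke tests.

## The synthetic-data generator

**Kymographs.** Particles advected by the prescribed velocity profile are
rendered as Gaussian-profile dips (σ = 1.3 px ≈ point-spread plus cell
size at 1 µm/px) on a bright background, wrapping at the line edges so
streak density is stationary; additive Gaussian noise on top.  Per-line
displacement exceeding half the line width raises an aliasing error.  The
streak slope is analytically exact, which is what makes the 0.5% LS-PIV
recovery bound a meaningful test.

**LFP.** Gaussian baseline noise around a 4 mV mean (0.1 mV SD by
default), SD trapezoids and PIP bursts as above.  PIP bursts are
band-limited tones under a flat-top envelope with 0.25 s raised-cosine
ramps, amplitude specified as a multiple of baseline RMS.

**Scenarios** (`generate_scenario()`) couple the two: the velocity profile
is piecewise — baseline, cosine drop to the nadir fraction (default 0.2)
over 90 s, a two-phase creep (brisk early rebound, then slow drift — the
sharp V keeps the nadir localized in time, as in the recorded time
courses), a fast 20 s recovery volley to 0.95 of baseline at 500 s, and a
decay to the 0.35 plateau; total 900 s with injection at 60 s.  SD onsets
are placed only where the profile is below the trigger fraction (default
0.35 of baseline, matching the observed perfusion threshold for SDs), in
non-overlapping slots with ≥30 s spacing; PIPs start only after the last
SD ends, with ≥3 s quiet between events and durations drawn from the
characteristic ≈2.3 ± 0.5 s with a floor at the >2 s detectability limit the
PIP definition itself imposes.  A configuration whose profile never
crosses the trigger raises an error naming the unreachable threshold.
The synthetic velocity component samples the profile at 1 s with 0.15 mm/s
Gaussian noise — chosen to match (with margin) the empirical error of the
package's own LS-PIV stage aggregated to 1 s on matched synthetic
kymographs at SNR 5.  The seed controls all noise streams; identical
config and seed give bit-identical output.

**What the generator does not emulate** — and hence what passing tests do
and do not show: no biophysics (ion dynamics, receptor or channel
kinetics), no pulsatility or motion artifacts in the kymographs, no 1/f
background or non-stationary rhythms in the LFP, no negative ultraslow
potential following SDs, single-channel recordings only.  Passing the
suite demonstrates that the algorithms implement their definitions
correctly and recover known ground truth under realistic noise; it does
not certify performance on recordings whose artifact structure differs
from this model.

## Problem sizes and numerical choices

Validation uses desk-scale problem sizes chosen to exercise every code
path with comfortable statistical power: kymographs of 1–2 k lines for
parameter-recovery checks; 200 seeded SDs (5–40 mV, 15–600 s) at 250 Hz;
100 pure-noise 5-min traces at 500 Hz for the PIP false-positive rate; 50
seeded scenarios for segmentation; one full 900 s scenario (kymograph at
1.25 ms/line × 64 px, LFP at 2 kHz) through the command-line interface.
Sampling rates below the hardware's 10 kHz are used where the quantity
under test is rate-independent; the full-rate default remains on the
containers.  FFT lengths are padded to 2·3·5-smooth sizes.  Degenerate
inputs (flat windows, zero baseline SD, empty band lists, zero-duration
events) raise explicit errors or flagged values rather than numerics.

## Known limitations

* The FFT filter assumes the trace is long relative to 1 s; very short
  traces (< a few seconds) see boundary transients.
* SD amplitude from the raw-trace minimum carries a positive noise bias of
  order the expected extreme of the baseline noise over the event; for the
  default 0.1 mV noise this is ≤2% at typical amplitudes.
* The CWT magnitude near the first/last ~2 s of a trace is affected by
  edge padding; detectors ignore this region only implicitly via the
  baseline window.
* `exact = TRUE` enumeration is exponential in the number of cells and is
  limited to small tables (total ≤ 40, k ≤ 4).
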