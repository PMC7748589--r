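---
title: "Methods: acoustic identification of audible medical alarms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic identification of audible medical alarms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmid)
```

## The problem and the model

Audible medical alarms compliant with IEC 60601-1-8 have a highly
constrained structure: a burst of one or a few fixed-frequency tones
(a fundamental and harmonics), repeated at a device-characteristic
interval. `alarmid` exploits exactly this structure. An alarm is
reduced to a **template** of between two and seven numbers:

* up to five characteristic frequencies $f_1 < \dots < f_k$ (Hz),
* the burst repeat interval $p$ (s), and
* optionally, the width $w$ (s) of the first autocorrelation peak,
  which reflects the tone duration within a burst.

The built-in database (`alarmTemplates()`) holds 14 such templates
from nine clinical devices, spanning 398–2713 Hz fundamentals and
0.325–3.68 s periods.

### Feature extraction

Given a mono clip at 44.1 kHz, the pipeline is:

1. **Decimate by 4** to 11 025 Hz (linear-phase anti-aliasing FIR;
   passband to 0.8× the new Nyquist, ≥ 70 dB stopband). Everything of
   interest lies below 4 kHz.
2. **High-pass filter** (linear-phase FIR, 300 Hz stopband / 350 Hz
   passband edges, ~60 dB attenuation) to remove rumble and hum below
   the analysis band. All analysis is restricted to **350–4000 Hz**.
3. **STFT**: Hamming window of 1024 samples (92.9 ms) with an overlap
   of 1008 samples, i.e. a hop of 16 samples (1.45 ms). The dense hop
   is what gives the periodicity estimate its millisecond resolution.
4. **Whole-clip PSD**: a Welch-averaged periodogram (Hamming segments
   of 4096 samples, 50 % overlap, 4× zero-padding) followed by
   parabolic interpolation of log-power across the three bins around
   each local maximum. Sub-bin interpolation matters: the identifier
   discriminates frequencies at the ±3–7 Hz level while a raw STFT bin
   is 10.8 Hz wide.
5. **Dominant frequencies**: up to five interpolated peaks ordered by
   power, separated by ≥ 30 Hz, and each at least 50 % as strong as
   the top peak (so modulation sidebands of one loud tone are not
   mistaken for extra alarm components).
6. **Band-power trace**: per STFT frame, the sum over the selected
   frequencies of $\log(P + \varepsilon)$ at the nearest bin.
7. **Periodicity**: the mean-removed, zero-lag-normalized, *unbiased*
   autocorrelation of the trace; peaks at positive lags need a height
   of ≥ 50 % of the maximum positive-lag value and a pairwise distance
   of ≥ 150 ms. The smallest qualifying lag is the repeat interval;
   the peak's full width at half prominence is the measured width.

### Identification

For an unknown clip, each database template is tested in stages:

* **Frequency prominence** — every template frequency must have an
  interpolated PSD peak within 6 Hz whose power reaches at least 50 %
  of the maximum in-band PSD. All templates passing form the candidate
  list. Requiring *all* frequencies (not any) is what separates
  templates whose frequency sets are nested.
* **Periodicity** — the band-power trace is rebuilt at the template's
  own frequencies and its measured period must lie within 37.5 ms of
  the template period.
* **Width** — only when the template carries a width: the measured
  width must agree within ±50 % (relative). This is what separates the
  two Philips monitor alarms, whose fundamentals are identical and
  whose periods differ by only 13 ms.

All positive matches are reported (two genuinely near-identical alarms
should both surface), ordered by period agreement. The operating point
(50 % PSD prominence, 37.5 ms period tolerance) sits on the 5 × 9
tuning grid searched by `tuneThresholds()` (PSD 40–60 % in 5 % steps,
period tolerance 30–50 ms in 2.5 ms steps, F1-maximal combination
selected; ties break toward the larger tolerance and lower fraction,
favoring sensitivity).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| decimation factor | 4 | — | 44.1 kHz → 11 025 Hz; band of interest ends at 4 kHz |
| analysis band | 350–4000 | Hz | covers all fundamentals/harmonics in the database |
| STFT window / hop | 1024 / 16 | samples | 10.8 Hz bins; 1.45 ms time resolution for periodicity |
| PSD prominence | 0.50 | fraction of max PSD | tuned operating point |
| frequency tolerance | 6 | Hz | consistent with full recall at ±3 Hz and zero positives beyond ±6 Hz |
| period tolerance | 37.5 | ms | tuned operating point |
| autocorrelation peak threshold | 0.50 | fraction of max positive lag | rejects sub-harmonic shoulders |
| min peak distance | 150 | ms | shortest database period is 325 ms |
| width tolerance | ±50 % | relative | database widths span 0.06–0.5 s; a relative window scales |
| log-compression floor ε | $10^{-2}\times$ max frame power | — | see below |

## Numerical choices

**Log-compression floor.** The trace uses
$\log(P + \varepsilon)$ with $\varepsilon = 10^{-2} \times$ the
maximum frame power. A much smaller floor (say $10^{-12}$) makes the
log-domain envelope of a burst rise the moment the analysis window
merely grazes the tone, smearing every burst by the full 93 ms window
and inflating the measured autocorrelation peak widths so far that the
narrowest database width (0.06 s) becomes unmeasurable. With a
$10^{-2}$ relative floor the measured width tracks the true tone
duration with a stable ~30 ms broadening, while scale invariance is
preserved (the floor is relative) and noisy clips are unaffected (in
noise, the noise power is the floor).

**Unbiased autocorrelation.** The lag-$k$ sum is divided by the
$n-k$ available terms. The more common biased estimator multiplies the
true correlation by $(1-k/n)$, which drags broad peaks toward smaller
lags — for a 2.1 s period measured on a ~6 s trace, an error of
~10 ms, enough to corrupt the ±30 ms discrimination band. The FFT
implementation is checked against a direct $O(n^2)$ oracle in the
tests.

**Peak interpolation.** PSD peaks and autocorrelation peaks are both
refined by a three-point parabolic fit (on log power for the PSD),
clamped to ±half a bin. Peak widths are only reported when the peak
has complete flanks inside the searched lag range; a peak whose
descent is cut off by the lag limit yields no width rather than a
wrong one.

**Lag range.** Periodicity peaks are searched at lags up to half the
trace length, so any reported period is covered by at least two full
repeats; clips too short for a template's period simply cannot match
it.

**Degenerate inputs.** Silence yields an all-zero PSD, hence no
candidates and no matches (not an error). A constant trace has no
autocorrelation peak and reports "no periodicity". Template
extraction from noise fails with an explicit error, because no stable
periodicity (normalized peak height ≥ 0.15) is found.

## Design decisions where the choice was genuinely open

* **DFT length.** The stated analysis combines a 1024-sample window
  with a short transform; a transform cannot be shorter than its
  window, so we keep the 1024/16 window/hop (which control the time
  resolution the periodicity estimate depends on) and a 1024-point
  transform; the ~256 retained in-band bins correspond to the shorter
  figure.
* **Frequency-match window (6 Hz).** No explicit value is tabulated;
  6 Hz is the only value consistent with full recall at ±3 Hz and
  zero positives beyond ±6 Hz in the discrimination grids.
* **All-frequencies-required.** Whether every template frequency or
  only a majority must be prominent is not stated; any-of would
  collapse templates with nested frequency sets (the Aisys pair vs.
  subsets), so all-of is used.
* **Autocorrelation input.** The autocorrelation operates on the
  log-compressed band-power trace (the plotted order of the pipeline),
  not on the raw power trace.
* **Which templates carry a width.** A width is stored at extraction
  only when it is below half the period and stable (±50 %) across the
  two halves of the trace — "when applicable" made operational without
  per-device rules.
* **Stereo reduction.** Multi-channel WAV input is averaged to mono;
  phone recordings of alarms are effectively mono sources.

## What the synthetic bench emulates — and what it does not

`synthesizeAlarm()` renders a template as equal-amplitude sinusoids at
the template frequencies, gated into bursts with 5 ms raised-cosine
ramps, repeating at the template period; phases are seed-randomized.
By default a clip contains **4 bursts** (the trace then covers about
three periods, so the first autocorrelation peak has complete flanks
for the width measurement; every clip contains at least the two bursts
the testing protocol requires). For width-bearing templates, the burst
duration is set to the tabulated width minus the pipeline's measured
~30 ms envelope broadening, so the synthesized device reproduces its
tabulated autocorrelation peak width; other templates use 40 % of the
period, capped at 1 s. Noise beds are seeded pink noise (exact
−3 dB/octave spectral shaping of white Gaussian noise), mixed by
digital summing at exact RMS SNR.

The bench deliberately does **not** model: room acoustics and
reverberation, microphone/loudspeaker coloration, device-specific
harmonic amplitude profiles or chirped/melodic alarms, or real
clinical soundscapes (a user-supplied WAV bed can stand in via
`noiseKind = "file"`). Consequently, passing the synthetic protocols
shows that the algorithm's decision logic and tolerances behave as
designed; figures measured on real device recordings with
real-world noise beds (operating-room soundscapes, music) can only be
approximated, not reproduced, by this bench. The noisy-condition
scores here should be read as order-of-magnitude agreement.

One template is structurally the hardest: the ventilator's critical
alarm has the shortest tone (0.06 s width, so a ~0.03 s synthesized
burst), giving it the lowest duty cycle in the database — at and below
0 dB SNR it is always the first alarm to drop below the 50 % PSD
prominence gate.

## Problem sizes used by the shipped protocols

The packaged tests and the acceptance script use: 70-clip corpora (14
templates × 5 seeded renditions), a 13-level SNR ladder (+6 to −6 dB),
53 no-alarm clips (a 10 s silent file plus 52 seeded pink-noise clips
across 13 amplitude levels), and discrimination grids over ±7 Hz ×
±50 ms (the full sweep is 15 × 11 = 165 tones per probe; the
summarized band checks evaluate the inner ±3 Hz × ±30 ms block and
the boundary rows/columns). All randomness is seed-derived, and every
corpus regenerates bit-identically from its seed.

## Known limitations

* Alarms must have fixed frequencies and a stable repeat interval;
  frequency-modulated or melodic alarms are out of scope.
* Identification needs at least two full repeats of an alarm in the
  analyzed clip (and ~three for a width verdict); very long-period
  alarms therefore need correspondingly long clips.
* The frequency prominence gate is relative to the loudest in-band
  component, so a much louder co-occurring alarm can mask a quieter
  one's weaker harmonics.
* Streaming/online detection and alarm onset timestamping are not
  provided; the unit of analysis is a finite clip.
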