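---
title: "Methods: dual-site pulse oximetry from PPG, and how this package validates itself"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-site pulse oximetry from PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earoximetry)
```

## The measurement model

Reflective photoplethysmography measures light reflected from perfused
tissue. Each heart beat transiently increases local blood volume, absorbing
more light, so the raw signal at any wavelength decomposes into a pulsatile
cardiac component (AC) riding on a slowly varying baseline (DC) set by
tissue, venous blood and non-pulsatile absorption. Oxygenated and
deoxygenated haemoglobin differ in their extinction coefficients at red
(~660 nm) and infrared (~880 nm) wavelengths, so the ratio of ratios

$$R = \frac{AC_{red}/DC_{red}}{AC_{ir}/DC_{ir}}$$

is a monotone proxy for arterial oxygen saturation. The package applies the
sensor manufacturer's linear calibration $SpO_2 = 104 - 17R$, which maps
$R = 4/17 \approx 0.235$ to 100% and $R = 1$ to 87%. Values above 100% are
arithmetically possible for small $R$ and are reported as-is by default
(`clip = TRUE` in `spo2_config()` clamps to [0, 100]); clipping silently
would hide calibration drift, so it is opt-in.

Assumptions worth stating explicitly: the calibration is a single global
line (no per-subject or per-device fitting); AC amplitude is read as the
peak-to-peak excursion of the band-passed signal; and both wavelengths are
sampled simultaneously at one site, so respiratory amplitude modulation and
perfusion drift affect them proportionally and largely cancel in $R$.

## The extraction chain and its numerical choices

`extract_spo2()` composes five steps, each exposed as a tested function.

**Band-pass AC isolation (1–30 Hz).** Realised as a 4th-order Butterworth
applied forward–backward (zero phase) over mirrored end padding, after
removing the record mean — digital filters start from a zero state, so
demeaning keeps start-up transients proportional to the AC excursion rather
than to the (much larger) DC level. Records shorter than three transient
lengths of the 1 Hz edge (3 s at the default) are rejected with an
instructive error.

**Prominence-based extrema detection.** Local maxima are filtered by
topographic prominence: the height of a peak above the higher of the two
saddles separating it from higher terrain, with windows running to the
record ends where no higher sample exists. Troughs are the peaks of the
negated signal. Prominence thresholds default to 150 arbitrary ADC units
(infrared) and 30 (red); they are raw-scale-dependent and fully
configurable. The implementation uses nearest-higher-peak bounds via a
monotonic stack plus a sparse-table range-minimum over inter-peak valley
minima ($O(n + k\log k)$), and the test suite pins it, index for index,
against a brute-force scanner that walks the definition directly.

**Envelope interpolation.** Peak values and trough values are interpolated
separately (linear, with end-value hold beyond the outermost extremum) and
their absolute values summed into a continuous AC-amplitude estimate.
Linear interpolation avoids overshoot between beats and makes the analytic
oracles exact: a unit sinusoid yields amplitude 2, an amplitude-modulated
carrier tracks twice its modulation envelope. Channels yielding fewer than
two peaks or troughs raise a degenerate-signal error naming the channel.

**DC baseline (0.01 Hz low-pass).** A 0.01 Hz corner at a 100 Hz sampling
rate corresponds to a normalised frequency of $2\times10^{-4}$, where a
transfer-function Butterworth is numerically unusable in double precision
(a constant input is not preserved). The package therefore block-means the
record down to ~1 Hz (which also annihilates all cardiac content), applies
a 2nd-order zero-phase Butterworth at the same physical corner over full
mirrored padding, and interpolates linearly back to the original grid.
Records shorter than 60 s fall back to the record mean with a warning.

**Ratio and calibration.** Samples with non-positive denominators are
masked; gaps shorter than 2 s are linearly interpolated in the SpO₂ trace,
longer gaps stay missing. A centred 3 s moving average (shrinking at the
record edges) produces the smoothed trace used for event detection; the
unsmoothed trace is always retained.

Heart rate is 60 divided by the median inter-peak interval of the infrared
pulse peaks — the median tolerates isolated missed or spurious beats.

## Breath-hold delay estimation

The protocol (435 s by default: 120 s rest, three repeats of 5 s exhale +
20 s hold separated by 60 s rests, 120 s final rest) has the subject hold a
button from exhale start to hold end, so the button release marks the true
oxygen minimum at the lungs. Per hold and site, the absolute delay is the
time from release to the *first* local minimum of the smoothed SpO₂ trace
in a bounded post-release window (default 45 s) whose prominence, measured
within the search segment, reaches 1% saturation. Operational choices the
underlying idea leaves open, fixed here: the search segment extends 15 s
before the release so a trough at the release itself still has left-side
context for its prominence; candidates more than 1 s before the release are
discarded; ties between equal minima go to the earliest. Per-site means and
ranges over the holds summarise a subject; the relative delay is defined as
finger mean minus ear mean, positive when the ear leads.

## Cohort statistics

Resting SpO₂ is the mean over the 60 s of normal breathing ending at the
first button press, per site. Site agreement is summarised by the RMS and
the mean of the per-subject ear−finger differences (positive mean = higher
saturation in the ear), plus the fraction of subjects on which the two
sites agree about membership of the closed healthy interval [94, 100]%.
Resting infrared AC amplitudes are normalised to the cohort maximum and the
per-subject finger/ear ratio averaged. Sex comparisons use the unpaired
Welch t-test by default: male and female groups carry no pairing, so a
paired test is statistically inappropriate, though a `paired` flag exists
for genuinely paired designs. Pearson correlations (with two-sided p-values
from the t transform) relate age to relative delay and heart rate to each
site's absolute delay. With a single subject, between-subject statistics
are reported as `NA` with a warning rather than failing the summary; an
empty cohort yields header-only tables.

`ttest_type1_error()` checks the sex test's calibration by simulation:
replicate cohorts drawn with *no* sex effect should reject at close to the
nominal 5% rate, and the acceptance suite verifies this over 1000
replicates.

## What the synthetic cohort emulates — and what it does not

The generator is first-class, tested code; its defaults *are* the study
conditions everything downstream is validated under.

* **Pulse shape**: an asymmetric two-Gaussian beat template — a fast-rising,
  slow-falling systolic peak plus a dicrotic bump that rides the falling
  edge as a shoulder. The template is normalised to zero mean and
  peak-to-peak 2, so a configured AC amplitude $A$ produces a $2A$
  excursion (verified to within 2% in the tests). Keeping the dicrotic wave
  a shoulder rather than a secondary local maximum means prominence-based
  detection sees exactly one peak and one trough per cardiac cycle at any
  amplitude in the simulated range, mirroring a sensor whose default
  thresholds work.
* **Wavelength coupling**: the red AC amplitude is scaled so the per-beat
  ratio of ratios equals $(104 - SpO_2(t))/17$ — the inverse of the
  calibration — making the injected saturation trajectory exactly
  recoverable in the noiseless limit (the tests demand $10^{-6}$ agreement
  on $R$ from the generated envelopes, and ±0.3% saturation through the
  full chain).
* **Desaturation kinetics**: each breath hold produces a dip of configurable
  depth whose minimum falls exactly `transit_delay` seconds after the hold
  end. The default dip is a symmetric Gaussian bell
  $d\,e^{-\frac{1}{2}((t-t_m)/\tau)^2}$. An asymmetric piecewise-exponential
  shape (saturating fall during hold + delay, exponential recovery after)
  is also available, but is *not* the default for a quantitative reason:
  its trough is a slope discontinuity with a nearly flat left side and a
  steep right side, and a centred boxcar smoother shifts the minimum of
  such a kinked profile early by up to half the smoothing window (~1.5 s
  here), which would contaminate delay estimates with an artefact of the
  dip's parameterisation rather than of the method. The symmetric bell's
  minimum is invariant under symmetric smoothing, so delay-recovery error
  measures the pipeline, not the simulator.
* **Nuisance structure**: respiratory amplitude modulation (default 15% at
  0.2–0.3 Hz) applied equally to both wavelengths, slow sinusoidal drift
  (period 120 s) scaled to each channel's DC level, and additive Gaussian
  noise (default 2 ADC counts, consistent with a high-SNR integrating PPG
  front-end and with saturation traces stable to ~0.1% after smoothing).
* **Cohort structure**: subject $i$ draws its parameters under seed
  `base_seed + i` (stable prefixes, bit-reproducible cohorts), sexes
  alternate F/M, resting saturation is drawn from 95.5–98.5%, heart rate
  55–85 bpm, ear transit delays from U[1, 7.5] s and finger delays from
  U[8.5, 28] s, ear infrared AC amplitudes from 150–400 counts with the
  finger fixed at 2.35× the ear, and infrared AC roughly 5× red AC so the
  150/30 prominence defaults are simultaneously sensible. Parameter draws
  carry **no** sex effect and no heart-rate–delay coupling, so group
  comparisons on simulated cohorts are null by construction.

Not emulated: motion artefacts, sensor displacement or contact loss,
melanin and perfusion optics, temperature-induced vasoconstriction,
nonlinear multi-wavelength physics, heart-rate variability within a
recording, and any physiological coupling between delay and covariates.
Passing tests therefore demonstrate correctness of the *pipeline* under a
controlled signal model — not robustness to the full messiness of recorded
data, for which the prominence thresholds and trough-qualification rules
would be the first knobs to revisit.

The sampling rate defaults to 100 Hz (configurable, minimum 25 Hz to
preserve pulse morphology); the hardware this emulates does not fix a rate,
so this is a simulator decision, not an inference. Problem sizes used in
the validation suite — a 14-subject cohort at 435 s × 100 Hz for delay
recovery, 120 s single-site records for plateau recovery, 1000 replicate
cohorts for t-test calibration, two-subject runs for bit-reproducibility —
were chosen as the smallest sizes at which each property is statistically
meaningful.

## Determinism and provenance

Every source of randomness flows from explicit integer seeds through
`withr::with_seed()`, leaving the global RNG untouched. `run_pipeline()`
writes a provenance snapshot (`config.json`) into each output directory;
the snapshot excludes the output path itself so that two runs of the same
configuration are bit-identical file for file. The only non-reproducible
output is `log.txt`, which records wall-clock stage timings.

## Known limitations

* The linear calibration is the manufacturer's nominal line; real devices
  need empirical calibration, and accuracy below ~80% saturation is not
  addressed.
* The first-trough rule assumes desaturations at least as prominent as 1%
  saturation; shallower dips (very short holds) are reported as missing
  events rather than guessed.
* The DC estimate is effectively a ~100 s-scale average; step changes in
  perfusion leak into $R$ on that timescale.
* Heart rate is taken from the ear infrared channel; with severe ear signal
  degradation the finger channel would be the natural fallback, which is
  not automated.
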