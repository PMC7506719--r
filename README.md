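# earoximetry

Analysis of dual-wavelength photoplethysmography (PPG) for comparing **in-ear
and finger pulse oximetry**. The package is aimed at researchers working on
wearable ("hearable") vital-sign sensing who need a tested, reproducible
pipeline from raw red/infrared PPG to blood-oxygen saturation (SpO₂),
breath-hold desaturation delays, and cohort-level site-comparison statistics
— together with a synthetic cohort generator so every stage can be validated
against known ground truth.

## The method

Pulse oximetry exploits the fact that oxygenated and deoxygenated haemoglobin
absorb red (~660 nm) and infrared (~880 nm) light differently. For each
wavelength the PPG signal is split into a pulsatile cardiac component (AC)
and a slowly varying baseline (DC), and the dimensionless **ratio of
ratios**

```
R = (AC_red / DC_red) / (AC_ir / DC_ir)
```

is mapped to percent saturation with the empirical linear calibration

```
SpO2 = 104 − 17 R
```

The extraction chain implemented in `extract_spo2()` is:

1. **AC isolation** — zero-phase 4th-order Butterworth band-pass, 1–30 Hz
   (`bandpass_ac()`).
2. **Peak/trough detection** — local extrema filtered by topographic
   prominence; defaults 150 ADC units for infrared, 30 for red
   (`detect_extrema()`).
3. **Envelope** — peak values and trough values interpolated separately over
   the record and their absolute values summed into a continuous AC
   amplitude (`ac_envelope()`).
4. **DC baseline** — 0.01 Hz low-pass of the raw channel (`lowpass_dc()`).
5. **Ratio of ratios and calibration** (`ratio_of_ratios()`,
   `calibrate_spo2()`).

Breath-hold analysis (`segment_breath_holds()`, `compute_delays()`) uses a
button channel held down from exhale start to hold end: the release marks
the moment of minimal blood oxygen at the lungs, and the **desaturation
delay** of a site is the time from release to the first qualifying trough of
its smoothed SpO₂ trace. The **relative delay** is the finger mean minus the
ear mean (positive when the ear leads). Cohort statistics
(`summarize_cohort()`) cover resting-SpO₂ agreement between sites (RMS and
mean ear−finger difference, healthy-range 94–100% classification
agreement), normalised resting PPG amplitudes and the finger/ear amplitude
ratio, sex-stratified delay tables with Welch t-tests, and Pearson
correlations of age and heart rate with delay.

Because no recorded data ship with the package, `simulate_cohort()`
generates dual-site, dual-wavelength recordings with fully known ground
truth: a staged protocol (default 435 s: 120 s rest, 3 × [5 s exhale + 20 s
hold] with 60 s rests, 120 s rest), a two-Gaussian pulse template at the
subject's heart rate, red AC scaled so the per-beat ratio of ratios encodes
the injected SpO₂ trajectory, site-specific transit delays, respiratory
amplitude modulation, baseline drift and sensor noise.

## Worked example

```r
library(earoximetry)

# one synthetic subject under the default study conditions
p   <- subject_params(subject_id = "S01", sex = "F", age = 27, seed = 42)
sub <- simulate_subject(p)   # ear + finger recordings, 435 s at 100 Hz

res <- process_subject(sub$recordings$ear, sub$recordings$finger)
glance(res$delays)
#>   mean_delay_ear_s mean_delay_finger_s range_ear_s range_finger_s ...
#> 1             4.47                16.8       0.440          0.410
```

The injected transit delays were 4.35 s (ear) and 16.75 s (finger); the
pipeline recovers 4.47 s and 16.8 s from the noisy recordings, with per-hold
spreads below half a second. At cohort scale:

```r
cohort  <- simulate_cohort(14, base_seed = 42)   # 7 F / 7 M
dataset <- process_cohort(cohort)
summarize_cohort(dataset)
#> <cohort_summary> 14 subjects
#>   Resting SpO2 (ear - finger): RMS 0.15%, mean -0.14%; healthy-range agreement 100%
#>   Resting amplitude: mean finger/ear ratio 2.35
#>   SpO2 delay, mean +/- sd (s):
#>            Relative        Finger          Ear canal
#>   Female   14.41 +/- 5.43  17.90 +/- 5.29  3.49 +/- 1.50
#>   Male     11.28 +/- 5.37  14.61 +/- 5.36  3.34 +/- 1.84
#>   Total    12.84 +/- 5.44  16.26 +/- 5.39  3.41 +/- 1.61
```

Every subject's ear delay precedes their finger delay, the injected 2.35×
finger/ear amplitude contrast is recovered, and resting SpO₂ agrees between
sites well inside the healthy band. `tidy()` on the summary returns the
per-subject table; `autoplot()` methods and `plot_delay_summary()`,
`plot_resting_agreement()`, `plot_amplitudes()` draw the standard figures.

An end-to-end run with provenance, per-stage outputs and a summary directory:

```r
run_pipeline(run_config(out_dir = "run1", n_subjects = 14, seed = 1))
```

A thin command-line front-end over the same functions lives at
`inst/cli/earoximetry.R` (subcommands `simulate`, `extract`, `delays`,
`analyze`, `run`).

## Output formats

Recordings are CSV (`time_s,green,red,infrared,button`) with a JSON
metadata sidecar (`format_version`, `fs`, subject id, site, sex, age).
Cohort results are flat CSV tables (`per_subject.csv`, `delay_by_sex.csv`,
`tests.csv`, `correlations.csv`) plus `cohort.json` with the cohort-level
scalars; see `write_recording()` / `write_results()`.
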