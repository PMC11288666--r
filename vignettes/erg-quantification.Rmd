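---
title: "Quantifying flash and flicker ERGs: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flash and flicker ERGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergkit)
```

## The measurement problem

A corneal electroretinogram (ERG) of the larval zebrafish eye sums the
electrical response of the outer retina to a light stimulus: a small
negative a-wave dominated by photoreceptor hyperpolarisation, followed by
a large positive b-wave driven by ON-bipolar cell depolarisation. Two
scalar read-outs carry most of the physiology:

* the **b-wave amplitude**, a proxy for the strength of ON-bipolar cell
  depolarisation, and
* the **implicit time**, here the time from light onset to the *onset* of
  the b-wave, a read-out of synaptic transmission kinetics.

A third read-out, the **flicker fusion frequency** (FFF), probes temporal
resolution: the highest stimulus rate whose periodic ERG response is
still detectable.

`ergkit` implements these quantifications, the supporting photometry, and
per-intensity cohort statistics, together with a synthetic generator that
produces all of these signals with known ground truth.

## Flash quantification

For each flash recording the trace layout places light onset after a
pre-stimulus segment (default onset at 100 ms in a 1000 ms trace at
1 kHz). The analysis chain is:

1. **Baseline** — the arithmetic mean of the first 50 ms of the
   recording.
2. **Amplitude** — the maximum voltage in a search window (default onset
   to onset + 300 ms) minus the baseline; baseline-to-peak, never
   trough-to-peak, with ties broken by the earliest sample.
3. **20%/80% crossings** — the *last* upward crossings of 20% and 80% of
   the amplitude (baseline-subtracted) before the peak, each located by
   linear interpolation between the bracketing samples. Taking the last
   crossing selects the final rising limb, so the a-wave recovery limb
   can never be picked and isolated noise crossings are harmless.
4. **Implicit time** — extrapolate the straight line through
   `(t20, 0.2 A)` and `(t80, 0.8 A)` down to the baseline level and
   subtract light onset. In closed form

   `implicit_time = t20 − (t80 − t20) / 3 − onset`.

5. **Validity filter** — implicit times below 50 ms or above 230 ms are
   flagged invalid (`below_filter` / `above_filter`); the boundary values
   themselves are kept. Traces without a positive amplitude, without a
   crossing, or with a degenerate (non-increasing) rise carry their own
   reasons and never produce a silent number.

Two conventions deserve a note because the construction leaves them
open. First, the "X-axis" the 20/80 line is intersected with is taken to
be the *baseline level* after baseline subtraction, not absolute zero
volts — with a defined baseline step this is the only choice that makes
the implicit time independent of amplifier offset. Second, the implicit
time is measured from light onset, which is what makes the validity
band meaningful. Both choices are exposed rather than hidden: baseline
window, search window and filter bounds are all arguments.

A useful analytic check: for a logistic rise
`A / (1 + exp(−(t − t0)/τ))` the crossings are `t0 ∓ τ ln 4`, so the
construction gives `t0 − (5/3) τ ln 4` exactly; the pipeline reproduces
this within interpolation error (< 0.01 ms at 1 kHz), which the test
suite asserts at 0.1 ms.

## Flicker fusion frequency

Flicker trains (15 ms pulses from 7 Hz in 1 Hz steps, 2 s per frequency)
are analysed in the frequency domain:

* **Power spectrum** — mean-detrended, un-windowed one-sided discrete
  power restricted to 0–50 Hz. The convention is fixed by two
  identities: a pure sinusoid of amplitude *a* with an integer number of
  cycles contributes `a²/2` at its bin, and the one-sided powers sum to
  the mean square of the detrended signal (Parseval). With 2 s records
  the resolution is 0.5 Hz, so every integer-Hz stimulus falls exactly
  on a bin and no taper is needed; a non-integer stimulus frequency
  raises an error rather than silently leaking.
* **Peak criterion** — a stimulus frequency is *resolvable* when the
  power at its bin exceeds `θ` times a noise floor, the median band
  power after excluding DC, the stimulus bin with its immediate
  neighbours, and the stimulus harmonics (same radius). Harmonics are
  excluded from the floor but never counted as evidence.
* **FFF** — frequencies are evaluated in ascending order; the default
  *contiguity* rule reports the last resolvable frequency before the
  first unresolvable one, which is robust to isolated spurious peaks
  above fusion; the literal *highest resolvable* rule is always reported
  alongside. A sweep that is resolvable throughout is censored at the
  sweep maximum; one that never resolves yields `NA`.

**Why θ = 5.** For white noise the detrended periodogram bin powers are
(asymptotically) exponential, so the probability that the stimulus bin
exceeds `θ` times the median floor is `2^−θ`. A threshold of 3 would
therefore false-alarm on 12.5% of pure-noise records — incompatible with
a 5% false-positive budget — while `θ = 5` gives 3.1%. This calibration
is analytic, not fitted; the Monte-Carlo suite confirms ≤ 5% per swept
frequency.

## Photometry

Source intensity is the area under the spectral-irradiance curve,
integrated by the trapezoidal rule on the native wavelength grid over
189–800 nm, with linear interpolation where the grid does not sample the
band edges; this is exact for piecewise-linear spectra. Stimulus series
are decadic: attenuation `log −k` multiplies the source intensity by
`10^−k`, producing the five-step ladder from `log −4` to `log 0`. For the
two reference sources (1874.4 and 12 652.8 μW cm⁻²) the ladder endpoints
round to 0.19 and 1.3 μW cm⁻², the published working ranges. Attenuation
is assumed spectrally neutral across the band.

## Cohort statistics

Per-eye metrics are compared per stimulus intensity between each mutant
genotype and the wild-type reference with a two-tailed two-sample
t-test. The pooled-variance (Student) variant is the default and the
variant used is always recorded; Welch is available. Degenerate variance
raises an error instead of returning a fabricated p-value. Box-and-
whisker summaries use Tukey hinges with whiskers at the data extremes —
no 1.5 IQR fencing. Invalid implicit times are excluded listwise and the
exclusion counts are reported per cell; no multiple-testing correction
is applied across intensities (a Holm adjustment can be applied
downstream if wanted). Eyes are treated as independent units, a
documented assumption rather than a claim.

## The synthetic generator

The generator exists so that every stage above can be validated against
known ground truth without any recorded data.

**Flash kernels.** The a-wave is a negated unit-peak alpha function; each
b-wave component is a unit-peak rise–decay kernel
`(1 − e^(−x/τr)) · e^(−x/τd)` with closed-form peak normalisation, so the
amplitude parameters are peak microvolts. The b-wave is the sum of a
fast (metabotropic-like) and a later-onsetting slow (transporter-like)
component; deleting the slow component both shrinks the b-wave and
advances its onset, which is exactly the phenotype structure the
cohort defaults emulate. The kernels are phenomenological: no
conductance or second-messenger model is implied, and any smooth
unimodal kernel satisfying the superposition identity would serve.

**Intensity dependence.** Component amplitudes scale with a
Naka–Rushton saturation of irradiance (half-saturation 18.7 μW cm⁻²,
Hill exponent 1 by default), so the five-step ladder spans threshold to
saturation.

**Defaults as study conditions.** 1 kHz sampling (1 ms ≪ every latency
of interest), 1000 ms traces with onset at 100 ms (so the 50 ms baseline
window is pre-stimulus), a 30 μV a-wave, 100 + 50 μV b-wave components
with latencies 80/110 ms and rise constants 40/60 ms, shared 300 ms
decay, and 5 μV white noise. These produce bright-flash implicit times
near 77 ms — mid-band for the 50–230 ms filter — and amplitude SNRs in a
realistic range for larval recordings. Eye-level variability is a
log-normal amplitude factor (CV 15%) plus a normal latency jitter
(SD 5 ms) applied as a rigid shift.

**Latency shifts are rigid.** A genotype's or eye's latency shift moves
the whole response (a-wave and both b components) in time. This makes
the shift-equivariance identity exact — a Δ ms shift changes the
implicit time by exactly Δ — which is what lets parameter-recovery tests
assert equality to within a sample period instead of a vague tolerance.
Kinetic phenotypes that are not rigid shifts can be emulated through the
per-component amplitude scales instead (e.g. removing the slow
component).

**Flicker trains.** A train superposes a fast unit pulse response
(latency 15 ms, rise 8 ms, decay 30 ms) at the stimulus times — computed
by discrete convolution of the impulse train with the sampled kernel —
with its amplitude set by a logistic rolloff of frequency around the
ground-truth cutoff (gain 30 μV, sharpness 4 per Hz: 98% of gain one
step below the cutoff, under 2% one step above, so fusion is effectively
hard at the 1 Hz sweep resolution). Noise is white (5 μV).

**Seeding.** One master seed; every eye and every trace derives a child
seed by a fixed affine rule (`child_seed()`), all recorded in the cohort
manifest, so any simulated object can be regenerated bit-identically.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: correlated or 1/f noise, amplifier
filtering and drift, photoreceptor adaptation across the stimulus
series, rod intrusion (responses are modelled as pure cone signals, as
appropriate for 5 dpf larvae), oscillatory potentials, eye-to-eye
correlation within an animal, and any non-rigid change of waveform
shape with intensity beyond amplitude scaling. Conclusions about the
*analysis code* transfer to real recordings; conclusions about
biological effect sizes do not.

## Numerical and validation choices

* Fractional crossings and filter behaviour are checked against
  brute-force scans and analytic constructions (ramps, logistic rises).
* The spectral path is checked bin-wise against a direct O(N²)
  transform and the Parseval identity at 10⁻⁹ relative tolerance.
* Statistical calibration uses the full simulate → quantify → test
  pipeline: 1000 replicate null cohorts (two identical genotypes, 8
  eyes, bright flash) must reject at 5% ± 1.5% for both amplitude and
  implicit time; FFF recovery uses 100 sweeps per ground-truth cutoff
  (15, 25, 35 Hz) with a ±1 Hz criterion, and 1000 noise-only records
  for the false-positive budget. These sizes keep the whole suite in a
  few minutes while leaving Monte-Carlo error well inside the asserted
  bands.
* Text outputs round-trip: numbers are written at 9 significant digits
  and re-writes are byte-identical, so provenance diffs are meaningful.

## Known limitations

* The peak criterion (`θ`, exclusion radius) is a parameterised
  convention, not a reconstruction of any particular lab's unpublished
  criterion; results should be reported with the criterion used, which
  the output tables include.
* The implicit-time construction assumes a monotone final rising limb
  between 20% and 80%; pathological multi-peaked rises are flagged
  rather than resolved.
* `summarize_cohort` deliberately offers no mixed-effects modelling;
  repeated eyes per animal violate its independence assumption.
* Censored FFF values (sweep top reached) enter group comparisons at
  the censoring value; with many censored eyes a rank or survival
  approach would be more appropriate than the t-test.
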