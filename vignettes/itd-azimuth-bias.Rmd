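---
title: "From interaural time differences to azimuth-estimation bias: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From interaural time differences to azimuth-estimation bias: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdbias)
library(dplyr)
```

## The scientific question

Below roughly 1500 Hz, the dominant cue for the horizontal position of a
sound source is the interaural time difference (ITD): the microsecond-scale
difference in arrival time between the two ears. Headphone (dichotic)
experiments can impose an ITD directly and ask listeners where they hear the
sound. Two things can then be compared:

* the **acoustic** relationship between azimuth and ITD, measured from
  head-related impulse responses (HRIRs); and
* the **perceptual** relationship, measured psychophysically by asking
  listeners to report a position for tone bursts carrying different ITDs.

The difference between the two — perceived azimuth minus the azimuth that
would acoustically produce the same ITD — is the *azimuth-estimation bias
curve*, the end product of this package's pipeline. Human cohorts show a
characteristic pattern: estimates are accurate at 0 µs, biased toward the
periphery for intermediate ITDs, and saturate near ±50° for extreme ITDs
even though the acoustics would justify up to ±90°.

## The acoustic front end

### Spherical-head HRIR model

No raw HRIR measurements ship with the package; instead `spherical_hrir()`
synthesizes impulse-response pairs from a spherical-head approximation. At
low frequencies, diffraction around the head inflates the interaural delay
relative to the straight-line path, giving

$$\mathrm{ITD}(\theta) = s \cdot \frac{a}{c}\,\sin\theta,$$

with head radius $a = 8.75$ cm, speed of sound $c = 343$ m/s, and the
low-frequency diffraction factor $s = 3$. We deliberately use this
low-frequency form rather than Woodworth's high-frequency ray formula
$(a/c)(\theta + \sin\theta)$: for a 500-Hz stimulus the low-frequency
regime applies, and it is the form whose predictions line up with measured
human low-frequency ITD curves — saturation near ±765 µs at ±90° (measured
curves put it around ±750 µs), and 480 µs falling at ~38–39° azimuth. The
interaural level difference of the model is a broadband gain of
$5\sin\theta$ dB, matching the ±5 dB span that measured 500-Hz-band ILD
curves show at ±90°.

Delays are split symmetrically between the ears (±ITD/2) and realized at
sub-sample precision with a windowed-sinc fractional-delay kernel (64 taps
by default — at 44.1 kHz this is band-limited interpolation accurate to
well below a microsecond, and the kernel length only matters below ~500 Hz
of passband edge). `spherical_cohort()` adds log-normal jitter to the head
radius (5% coefficient of variation by default) so that across-subject
median/IQR summaries are non-degenerate; single-subject maps have zero IQR
by construction.

`read_cipic_hrir()`/`write_cipic_hrir()` handle per-subject HRIR files in
the array layout of the public CIPIC HRTF database (25 interaural-polar
azimuths × 50 elevations × time, 44.1 kHz), serialized as JSON so that test
fixtures remain plain text; the reader extracts the elevation-0 slice. The
CIPIC azimuth convention (negative = left) already matches this package's
(degrees, 0 = front, positive = right; positive ITD = right ear leading).

### Cue extraction

`build_cue_map()` mirrors the standard measurement chain: a white-noise
probe is rendered through each subject's HRIR pair, decomposed by a
cochlear filterbank, and reduced to one ITD and one ILD per band:

1. **Gammatone filterbank.** 4th-order gammatone filters with ERB-derived
   bandwidths ($b = 1.019\,\mathrm{ERB}(f)$), implemented as FIR impulse
   responses applied by FFT convolution and normalized to unit gain at the
   centre frequency. The default band list is 500 Hz and 3000 Hz — the two
   bands needed to contrast the unambiguous low-frequency map with the
   phase-ambiguous high-frequency one.
2. **Analytic signal.** Instantaneous phase and amplitude come from the
   Hilbert-transform analytic signal (FFT half-spectrum method; inputs are
   zero-padded to a 5-smooth length purely so the FFT stays $O(n\log n)$,
   which perturbs only the trimmed edges).
3. **Circular-mean IPD.** The per-sample interaural phase difference is
   wrapped to $(-\pi, \pi]$ and averaged circularly (angle of the summed
   unit phasors). Arithmetic averaging would fail near the ±π branch cut;
   the unit tests exercise exactly that case.
4. **Conversion.** $\mathrm{ITD} = 10^6 \, \mathrm{IPD} / (2\pi f)$ µs;
   $\mathrm{ILD} = \langle 20\log_{10}(A_\mathrm{right}/A_\mathrm{left})
   \rangle$ dB.

Median and interquartile range are taken across subjects, and each band
carries *ambiguity branches*: copies of the median ITD curve offset by
$\pm k \cdot 10^6/f$ µs for $k = 1, 2$, the delays acoustically
indistinguishable from the principal curve at that frequency. Two branches
per side are attached because further multiples leave the physiological
range entirely at the frequencies of interest.

Two aggregation details are not fixed by common practice, so they are
explicit package choices: 10% of samples are trimmed at each end before
averaging (filter and Hilbert transients), and the probe is 1 s of Gaussian
white noise, seeded. The end-to-end tests show the chain recovers imposed
pure delays within a few µs and imposed gains within 0.01 dB, so the
conclusions are insensitive to these two settings.

## Stimuli and trial design

`synthesize_stimulus()` builds the dichotic probe used in the perceptual
tasks: a 500-Hz carrier gated into ten consecutive 50-ms elements, each
with 25-ms raised-cosine rise and fall (500 ms total). The ITD is applied
as a whole-waveform interchannel delay of ±ITD/2 per channel — onset and
ongoing delay together, the plain reading of "one channel delayed" — again
via the windowed-sinc kernel. A raised-cosine (Hann-flank) gate was chosen
because only rise/fall durations, not the flank shape, are conventionally
specified; any smooth flank gives the same extracted ITD.

`build_block()` produces the trial order: five ITDs (−480 to 480 µs in
240-µs steps), nine repetitions each, 45 trials. "Controlled first-order
transitions" is operationalized as: over the block's 44 ordered transitions
across 25 ordered level pairs, the per-pair counts differ by at most one
(perfect equality being arithmetically impossible). The order is found by a
seeded randomized greedy search — always continuing with a least-used
transition, restarting on dead ends — which in practice succeeds within a
handful of restarts; infeasible designs raise an error rather than return
an unbalanced order.

## The response simulator

No per-trial human data are available, so `simulate_cohort()` generates
them. The simulator is a first-class, tested component: the analysis stage
is validated against it, and its defaults *are* the study conditions —
14 subjects, 5 ITDs × 9 repetitions per block, three tasks.

One latent percept model drives all three tasks:

$$\psi(\mathrm{ITD}) = A\left(\frac{2}{1 + e^{-k\,\mathrm{ITD}}} - 1\right),$$

an odd sigmoid saturating at ±A, rescaled into each task's native range.
This reflects the empirical observation that z-scored mean estimates are
nearly indistinguishable across response methods. Task calibrations follow
the reported cohort ranges:

| task | A | SD front → periphery | bounds | confidence |
|---|---|---|---|---|
| azimuth pointer | 50° | 36.3° → 14.0° | ±90° | periphery-high |
| linear bar | 0.85 | 0.5 → 0.2 | ±1 | periphery-high |
| ILD match | 4.2 dB | 1.9 → 1.2 dB | ±7 dB | front-high |

The shared slope default is $k = 0.008$ /µs, which puts $\psi(480) \approx
48°$ — visibly saturated at the extreme design ITDs, as the human curves
are. A consequence worth stating: with the spherical acoustic map
(asin-shaped, reaching 58° at 650 µs), a 50°-asymptote sigmoid must cross
the acoustic curve *before* 650 µs — here near ±575 µs — because the
acoustic azimuth at 650 µs already exceeds the perceptual asymptote. The
qualitative structure is unaffected: bias is zero at 0 µs, peripheral-ward
(positive for positive ITD) below the crossing, frontal-ward beyond it.

Other generator components, chosen where no distributional form is
reported and documented as invented: Gaussian trial noise applied before
clipping to the task bounds; an even Gaussian-bump SD profile pinned to the
front/periphery anchors (width τ = 300 µs); log-normal reaction times
(moment-matched to the subject's mean and SD; positive support); linear
confidence profiles between the front/periphery anchors with Gaussian trial
noise, clipped to [0, 100]; ILD-match iteration counts
$1 + \mathrm{Poisson}(0.5 + 2|{\mathrm{ITD}}|/480)$. Cohort heterogeneity
(`cohort_models()`) jitters A, the SD scale and k log-normally (10% CV) and
the per-task mean reaction time normally (SD 0.2 s, drawn independently per
subject × task — a shared subject offset would cancel out of paired task
comparisons and make between-task reaction-time tests artificially
powerful).

What the generator does **not** emulate: sequential effects, learning or
fatigue, lapses, left/right asymmetries, response quantization from a mouse
or screen, and the iterative acoustic feedback loop of the ILD-match task
(only the iteration count is modelled). Passing tests therefore show the
*analysis* is correct under a plausible response model, not that real
listeners obey that model.

## The analysis stage

`summarize_subjects()` computes the four per-subject, per-ITD summaries
(mean estimate, SD of estimates with the n−1 denominator, mean reaction
time, mean confidence). `zscore_pool()` puts subjects on a common scale:
each subject's 5-ITD mean-estimate vector is centred and divided by its own
SD, making the pooled curves invariant to any per-subject affine rescaling
of the response scale (dB, bar units or degrees). The SD vector is divided
by the *same* per-subject scale factor, preserving the shape of relative
variability across ITD; z-transforming SD vectors on their own mean/SD is
available via `sd_scaling = "independent"`, but the shared-scale form is
the default because it keeps mean and SD panels in the same units after
normalization.

Uncertainty is percentile bootstrap throughout (10,000 resamples by
default), always resampling subjects, never trials; `paired_bootstrap_test()`
resamples per-subject paired differences and doubles the smaller tail
fraction at zero. BCa corrections are deliberately not applied — the plain
percentile interval is the convention in this literature. Its known cost is
mild undercoverage at small n: at 14 subjects the nominal-95% interval
covers a Gaussian mean about 90–91% of the time. The package reports the
interval as defined rather than silently substituting a different method.

`fit_sigmoid()` fits $\psi$ by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), with confidence bands from refitting under subject
resampling. The symmetric two-parameter logistic through the origin is the
default family; degenerate all-zero data short-circuits to $A = 0$ rather
than letting the optimizer wander in an unidentifiable direction.

`invert_acoustic_map()` interpolates the 500-Hz median ITD curve with a
natural cubic spline in azimuth, verifies strict monotonicity (the 3000-Hz
band correctly refuses), and inverts numerically with `uniroot` to
machine precision. `compute_bias_curve()` then evaluates
perceived − acoustic on an ITD grid; its confidence band propagates only
the sigmoid-fit uncertainty, since the acoustic curve is conventionally
drawn as a fixed reference.

## Numerical and reproducibility choices

* Every stochastic step (noise probes, cohort draws, trial noise, block
  orders, bootstrap) takes an explicit seed, and seeded helpers restore the
  caller's RNG state.
* Default problem sizes are chosen to make each stage's checks sharp but
  quick: 19-azimuth maps for inversion (spline error ≪ 0.1° on a sine-like
  curve), 1-s noise probes, 100 simulated cohorts for parameter-recovery
  summaries, 500–2000 bootstrap resamples in tests (10,000 for final
  figures).
* Degenerate inputs fail loudly with the offending quantity named:
  non-monotone maps, zero within-subject variance, out-of-domain ITD
  queries, infeasible block designs, amplitudes ≤ 0 in ILD.

## A worked pipeline

```{r, eval = FALSE}
library(itdbias)

# acoustic side
map <- spherical_hrir(azimuths = seq(-90, 90, 10)) |>
  build_cue_map(bands = c(500, 3000), seed = 1)
acoustic <- invert_acoustic_map(map, band_f = 500)

# perceptual side: simulate, summarize, fit
trials <- cohort_models(14, seed = 1) |>
  simulate_cohort(n_blocks_per_task = 2, seed = 1)
est <- summarize_subjects(trials) |>
  dplyr::filter(task == "azimuth_pointer") |>
  dplyr::rename(estimate = mean_estimate)
fit <- fit_sigmoid(est, n_boot = 1000, seed = 1)

# the bias curve
bias <- compute_bias_curve(fit, acoustic)
autoplot(bias)
```

## Known limitations

* The spherical-head map is a stand-in for measured HRIRs: it has the right
  low-frequency saturation and stimulus–azimuth correspondences but none of
  the pinna/torso fine structure, and its single-subject IQR is zero unless
  cohort jitter is enabled.
* The simulator's latent model is itself a sigmoid, so sigmoid-fit recovery
  tests are consistency checks of the pipeline, not evidence that human
  response curves are logistic.
* The bias curve's confidence band ignores acoustic-map uncertainty.
* Reaction-time and confidence models are calibrated only to reported
  coarse ranges and orderings, not to distributions.
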