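---
title: "Methods: contractility, pacing and imaging analysis for cultured atrial trabeculae"
author: "trabkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contractility, pacing and imaging analysis for cultured atrial trabeculae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabkit)
```

## Scope

Human atrial trabeculae (pectinate muscles) can be kept beating in culture
for weeks under continuous electrical field stimulation, with twitch force
recorded from the deflection of a calibrated spring wire (25 mN/mm; a
0.02 mm deflection is 500 uN, the standard diastolic preload). `trabkit`
implements the complete downstream analysis for such preparations:

1. conditioning and beat analysis of the 400 Hz force stream,
2. S1-S2 extrastimulus and frequency-ladder capture analysis (mechanical
   refractory period RP and maximum captured frequency f~max~),
3. synchronized Ca^2+^/force co-analysis,
4. 3D confocal segmentation of immunostained myocardium,
5. qPCR expression ratios and MTT/Bradford viability statistics,

plus a synthetic-data generator that emulates all five raw input kinds with
known ground truth, so every stage has a parameter-recovery test surface.

## Force conditioning and noise model

The device streams force at 400 Hz. Analysis operates at 200 Hz after a
two-point mean downsample, followed by a centred moving **median filter of
radius 10 samples** (21-sample window) and a centred moving **mean filter of
radius 5 samples** (11-sample window). Radii are interpreted in samples at
200 Hz — the only self-consistent reading; edge windows are truncated rather
than padded, so series length is preserved.

Sensor noise is estimated from the 200 ms windows immediately before
stimuli delivered at slow pacing (preceding inter-stimulus interval
≥ 1000 ms, ties included): contractions are always over well before the
next slow stimulus, so these windows contain noise only. Windows are
restricted to rocker-off periods (the medium-agitation rocker produces
low-frequency artifacts); a window crossing a rocker transition is
shortened to its rocker-off part and dropped if less than half remains —
purity over count. The estimate pools the mean-removed windows
(`sd`) and records the largest within-window peak-to-peak excursion
(`max_amplitude`, the max−min reading of "maximum noise amplitude"; the
alternative reading, max |deviation from the mean|, differs only by a
factor ≈ 2 and would change no downstream decision).

## Beat detection and kinetics

A candidate beat is a local maximum whose height above the local diastolic
level strictly exceeds `max_amplitude + sd`. The diastolic force F~D~ is
the minimum within ±50% of the local stimulus interval around the peak;
F~amp~ = F~max~ − F~D~. TTP90 is the time from the last sample at or below
F~D~ + 0.1 F~amp~ before the peak to the peak; TTR90 the time from the peak
to the first such sample after it; CD90 = TTP90 + TTR90 by construction.
Crossings are reported **at sample resolution** (5 ms at 200 Hz), with no
sub-sample interpolation: "first occurrence" is a sample-level rule, and
all recovery tolerances are one sample. When two candidate peaks fall in
one stimulus interval the higher wins (ties: earlier). Beats inside
rocker-on spans are never measured. A beat whose 10% crossing is not found
inside its window (fused beats at fast pacing) is flagged unmeasurable and
excluded from period summaries; period summaries are arithmetic means over
measured beats with `n_beats`/`n_stimuli` bookkeeping for capture analysis.

A preparation is screened as *beating* iff any F~amp~ strictly exceeds
50 uN.

## Capture analysis: RP and f~max~

The S1-S2 protocol paces at 0.5 Hz baseline; after a 22 s settling train,
three S2 extrastimuli are delivered at the coupling interval of the current
ladder step (750, 500, 400, 300, 275, 250, 240, 230, 220, 210, 200, 190,
180, 170, 160, 150, 140, 130, 120, 110, 100 ms), each anchored to a
regular S1 with the S1 grid continuing unshifted and three S1 beats between
consecutive S2s (the spacing is not dictated by the protocol definition;
it is fixed here for reproducibility). A 6 s constant train at the
corresponding frequency (1000/interval) follows each step. An S2 is
*captured* iff the open window between it and the next stimulus contains a
local maximum rising strictly more than the minimum peak height above the
preceding within-window minimum — the beat detector's rule applied to one
window, so there is exactly one capture definition. A step is captured iff
all three S2s are; **RP is the interval before the first not-captured
step**. Full capture flags `below_min`, failure at 750 ms flags
`above_max`; censoring is always explicit, never a sentinel number.

For f~max~, each frequency of the ladder (0.2–5 Hz, 25 beats per step) is
captured iff **each of the last five stimuli** elicits a detected beat;
f~max~ is the last captured frequency before the first non-captured one,
with `at_max`/`below_min` censoring.

One edge case is inherited from the window definition: at S2 intervals
shorter than the twitch time-to-peak (≈150 ms), the anchor S1's own rising
twitch peaks *inside* the S2 window and registers as a capture. This
affects only ladder steps far below any realistic atrial RP and is
invisible to the interval-before-first-failure rule, but the capture table
tail should not be over-interpreted. The RP reported here is a mechanical
surrogate measured through force, not the electrical refractory period.

## The excitation model of the simulator

Refractoriness follows a restitution curve
$$RP(DI) = rp_{min} + (rp_{max} - rp_{min})\,(1 - e^{-DI/\tau}),$$
where DI is the diastolic (coupling) interval that preceded the most
recent activation. A stimulus activates iff the time since the last
activation is at least the current RP. With `rp_min == rp_max` the tissue
has a fixed threshold (useful for constructing exact worked examples);
with the control defaults (rp_min = 150 ms, rp_max = 380 ms,
τ = 1800 ms) the model reproduces the characteristic dissociation between
the S2-derived RP and steady-state capture: at the 0.5 Hz baseline
(DI = 2000 ms) the effective RP is ≈304 ms, so the S2 ladder fails first
at 300 ms and reports RP = 400 ms, while during fast trains the shortened
DI lowers the effective RP below 200 ms (at DI = 400 ms,
RP ≈ 196 ms < 200 ms), so 5 Hz trains regain full capture after at most
one skipped stimulus. τ was chosen analytically from exactly these two
constraints (escape from 2:1 at 5 Hz requires τ ≥ ≈1600 ms; baseline RP in
the 300–400 ms ladder gap requires τ not much larger), before any
simulation was run.

Each activation superimposes a twitch scaled by: the force-frequency
relationship, `1 + ffr_slope × (f_inst − 0.5)` with f~inst~ the reciprocal
coupling interval (anchored at the 0.5 Hz culture baseline; default slope
−0.1/Hz, a negative FFR as typical for human atrial tissue); post-rest
potentiation (`post_rest_gain`, default 1.3, after pauses ≥ 4 s); and, when
alternans is enabled (dofetilide preset), an `alternans_ratio` scaling of
every second beat once the coupling interval falls below 1.25 × the current
RP. Gaussian sensor noise (default sd 5 uN, consistent with a 50 uN
beating screen) is added throughout, and during rocker-on spans a 1 Hz
sinusoid (60 rpm rocker) plus slow wander of configurable amplitude.
Drug presets are conveniences: isoprenaline (amplitude ×2.15, kinetics
×0.63, RP −30%) and dofetilide (amplitude ×1.2, RP +25%, alternans); all
factors are overridable. Everything is bit-reproducible given
(params, protocol, seed).

### Twitch shape

The generated twitch is built from a shallow symmetric parabolic summit
(half-width 50 ms, 2% droop), near-linear flanks, and a raised-cosine foot
whose midpoint — an inflection — sits exactly at the 10% level, `ttp90`
before and `ttr90` after the peak. This morphology is deliberately
*filter-robust*: the 21-sample median filter passes monotone segments
unchanged and barely attenuates the locally symmetric summit, and the mean
filter is unbiased at inflection points, so the analytically known
crossing times survive the full conditioning chain to one-sample accuracy.
Smooth shapes with exponential tails (a natural first choice) lose 3–4% of
peak amplitude in the median filter and acquire a ≈15 ms relaxation-time
bias, which would make parameter-recovery statements about the analysis
chain impossible to interpret. The sampled peak equals the requested
amplitude exactly, and the waveform has compact support (starts and ends
at zero).

## Ca^2+^/force co-analysis

The photometry rig records the same stimulation pulses on its own clock.
Synchronization matches the two event sequences: near-diagonal pairwise
time differences provide candidate offsets, the candidate pairing the most
events wins, and the offset is the least-squares (mean) difference over
the matched pairs — exact to well under one sample whenever the logs share
the stimulus sequence, and robust to isolated missing events. The
fluorescence trace is linearly interpolated onto the force time base
(photometry rates far exceed the signal bandwidth). Both channels are
measured with the *same* beat machinery (diastolic offset via F~D~, 10%
threshold); per-beat amplitudes are normalized to the beat of the first
0.5 Hz stimulus, making the Ca channel scale-invariant by construction. No
Ca kinetics beyond amplitude are reported, and no absolute calibration is
attempted. The post-rest ratio compares the first beat after a pacing
pause (≥4 s) with the mean of the last three captured pre-rest beats; the
count is configurable because nothing in the protocol fixes it.

## Confocal pipeline

Stacks are corrected for depth attenuation by per-plane gains that match a
robust statistic (median of above-mode voxels) to the top plane, smoothed
by a 3-plane running median and made monotone non-decreasing — attenuation
only deepens with z, and the monotonicity guard prevents planes dominated
by a single structure (e.g. a z-wall of ECM) from being crushed. In the
full pipeline the gain profile is estimated once on the WGA channel
(present at every depth) and shared across channels, since attenuation is
an optical property of the tissue, not of the stain. Richardson–Lucy
deconvolution (FFT-based multiplicative updates, non-negativity preserved,
total intensity conserved within 1%) is available and used in tests with
the generator's known PSF, but is off by default because measured PSFs are
rig-specific.

Channels are binarized at mode + k·SD (k = 1 WGA, 3 Cx43, 2 DAPI; mode on
a 256-bin histogram of the intensity range — the binning is a numerical
choice). The alpha-actinin channel varies too much for a global cut: a
20×20×2-voxel box mean is subtracted and the residual thresholded at its
mode + 1 SD, which cancels slowly varying gain fields. The Cx43 mask is
opened with an ellipsoidal element of 0.2 um physical radius (voxel radii
per axis, minimum one voxel in-plane; axes coarser than the radius are not
eroded) to remove speckle.

Cells are partitioned by a seeded 3D watershed on the inverted anisotropic
Euclidean distance map of the non-WGA space. Seeds are regional maxima of
the distance map quantized to 0.5 um — quantization merges near-flat
ridges into single plateaus, and a plateau seeds only if no neighbour is
deeper — followed by greedy suppression of seeds closer than 4 um
(default) to a deeper one. Flooding is by immersion with a deterministic
FIFO tie-break, so segmentations are reproducible. Segments with **at
least 7.5%** alpha-actinin-positive voxels (inclusive, per the
classification rule) are myocytes. Volume fractions use the full stack
volume as denominator, with the non-WGA, non-myocyte remainder reported
separately as `unclassified` rather than folded into either class.

### The volume phantom

The generator renders a jittered brick lattice (nominal cell edge 6 um,
ECM walls 0.8 um — wide enough to survive the 0.4 um axial sampling),
narrow alpha-actinin bands (2 um sarcomere period, 25% duty cycle, the
Z-line lattice), Cx43 puncta (0.6 um radius) on longitudinal junctions,
ellipsoidal nuclei, then Gaussian PSF blur (σ = 0.1, 0.1, 0.25 um,
representative of a 63×/1.4 oil objective), exponential depth attenuation
(λ = 40 um) and Poisson + Gaussian noise. The default phantom is pure
myocardium (every cell alpha-actinin-positive), matching the dense myocyte
content of trabecula cores; `aact_positive` introduces non-myocyte cells
for classification tests. Default test volumes are 64×64×32 voxels at
0.2×0.2×0.4 um — a few cells per field — which keeps the 10-seed recovery
suites fast while exercising every pipeline stage; real 1280×1280×100
stacks differ only in scale.

What the phantom does *not* emulate: irregular cell shapes, fibrotic
patches, intracellular Cx43 redistribution, anisotropy of the real PSF's
side lobes, bleaching. Recovery of the phantom's fractions within ±10%
relative therefore validates the pipeline's internal consistency, not its
accuracy on arbitrary tissue.

## qPCR, viability and statistics

Amplification efficiency per gene comes from the least-squares slope of Ct
against log10 relative template over a 1:5 dilution series:
E = 10^−1/slope^. Expression ratios are efficiency-corrected and
normalized to the reference genes EEF2 and HPRT1:
$$ratio = \frac{E_t^{\Delta Ct_t}}{\operatorname{geomean}_r E_r^{\Delta Ct_r}},
\qquad \Delta Ct = \overline{Ct}_{control} - \overline{Ct}_{treated},$$
so upregulation gives ratio > 1 (the sign convention is recorded in the
output). Two reference genes are combined by the geometric mean, the
standard convention where the combination rule is not otherwise fixed.
Efficiencies are applied per experiment; when replicated experiments
disagree, both are reported rather than pooled.

Bradford protein quantification inverts a linear BSA standard curve, with
explicit extrapolation flags outside the standard range; MTT viability is
formazan absorbance divided by total protein. Comparisons use the paired
two-sided t test within trabeculae, Welch's two-sided t test between
groups, and Holm–Bonferroni correction across multiple comparisons of one
parameter (α = 0.05). Zero-variance degenerate inputs return p = 1 with a
message rather than erroring.

## Numerical conventions and degenerate inputs

* All crossing times at sample resolution; one sample (5 ms) is the
  quantization floor of every kinetics statement.
* Strict inequalities where the rules say "exceeding" (peak height,
  beating screen); inclusive where they say "at least" (7.5% myocyte
  content, ≤1 Hz noise windows).
* Censored RP/f~max~ always carry flags; arithmetic on censored values is
  refused.
* Empty masks, constant images, all-zero traces and zero-amplitude tissue
  all return well-defined degenerate results (empty mask, zero noise, no
  beats) rather than errors, except where the result would be meaningless
  (no qualifying noise window; watershed of a full mask).

## Known limitations

* The minimum-peak-height rule is calibrated on 200 ms noise windows but
  applied to longer search windows; at very low signal-to-noise a few
  spurious sub-threshold-scale "beats" can appear. They never pass the
  50 uN screen, but beat *counts* on silent noisy preparations should not
  be over-interpreted.
* On a blank (signal-free, noisy) alpha-actinin channel the mode + 1 SD
  residual threshold marks the upper noise tail (~16% of voxels), so
  myocyte classification is only meaningful when sarcomeric signal exists;
  the all-negative test case is run noiseless for this reason.
* Fused beats at pacing rates where CD90 exceeds the stimulus interval are
  systematically under-measured in amplitude (F~D~ cannot reach baseline);
  capture detection is unaffected.
* Simulation inserts activations on the 400 Hz device grid, so
  sample-phase alignment between stimuli and the 200 Hz analysis grid is
  deterministic; measured kinetics can sit a full sample from truth rather
  than straddling it.

## Problem sizes used in the test and acceptance suites

S1-S2 runs use the full 21-step protocol (≈18 min of simulated recording,
≈1100 stimuli); frequency-ladder runs the full 12-step, 25-beats-per-step
protocol (≈5.5 min). Beat-recovery suites use 100-beat 0.5 Hz trains.
Confocal suites use 64×64×32-voxel phantoms over 10 seeds. These sizes
were chosen so the full validation cycle runs in about a minute on a
laptop while every stage still operates on the protocol structure it would
see in production.
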