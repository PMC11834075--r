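---
title: "Laminar detection and characterization of hippocampal sharp-wave ripples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar detection and characterization of hippocampal sharp-wave ripples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrlamina)
```

## The problem

Hippocampal sharp-wave ripples are compound events: a fast 90–200 Hz
oscillation in CA1 stratum pyramidale (the ripple, reflecting local
recurrent activity) riding on a slower 2–20 Hz deflection in stratum
radiatum (the sharp wave, reflecting CA3 Schaffer-collateral input). On a
laminar probe the two components live on different channels, so they can be
detected *independently* and their co-occurrence used as a taxonomy:

* **R** — a ripple with no overlapping sharp wave,
* **SW** — a sharp wave with no overlapping ripple,
* **SWR** — a ripple overlapping exactly one sharp wave,
* **cSWR** — a long ripple overlapping two or more sharp waves
  ("complex" events reflecting sustained CA3 drive).

`swrlamina` implements that analysis end to end for urethane-anesthesia
recordings (which alternate between NonREM-like epochs with 0.5–1 Hz
cortical slow oscillations and REM-like epochs with 3–6 Hz theta), plus the
laminar physiology around it: current-source-density (CSD) maps, average
rectified CSD (AVREC) layer profiles, aperiodic (1/f) spectral slope as an
excitation/inhibition proxy, and slow-oscillation phase coupling. A seeded
synthetic-data generator provides laminar recordings with complete ground
truth so that every stage is testable without animal data.

## The detection model

Both detectors are threshold detectors on band-limited traces at an
analysis rate of 600 Hz (recordings are first low-passed at 300 Hz with a
3rd-order zero-phase Butterworth filter and decimated).

**Ripples.** The pyramidale channel is band-passed 90–200 Hz (4th-order
Butterworth, forward–backward). A voltage criterion cannot hold for tens of
milliseconds on a 150 Hz oscillation, so the detection magnitude is the
Hilbert envelope of the filtered trace (a 10 ms sliding RMS is available as
an alternative). The detection level is

$$\mathrm{detect} = \mu + k\,\sigma, \qquad k = 5 \text{ by default},$$

with $\mu$, $\sigma$ the mean and SD of the magnitude over artifact-free
NonREM-like samples (thresholds are meant to describe sleep-like
background, so REM-like and blanked samples are excluded from the
baseline). Supra-threshold cores shorter than 50 ms are discarded, the
surviving cores are extended outward to the half-threshold crossings, and
events separated by less than 80 ms are merged. The event peak is the
envelope maximum.

**Sharp waves.** The radiatum channel is band-passed 2–20 Hz and troughs
below $\mu - k\sigma$ of the filtered trace define events; start and end
are the threshold crossings and the (negative) peak is the minimum.

**Classification.** Overlap is counted with two deliberately literal,
non-mutually-exclusive endpoint cases: the sharp wave's end lies inside the
ripple's `[start, end]`, or its start does (closed intervals; ties count as
containment). Zero, one, or two-plus overlaps make the ripple an R, SWR, or
cSWR; sharp waves attached to no ripple are SWs. A consequence of the
literal rule: a sharp wave *strictly containing* a ripple has neither
endpoint inside it and counts as no overlap. We keep that behavior as the
default because it is the published rule, and expose
`classify_events(..., rule = "intersect")` for plain interval intersection;
both behaviors are unit-tested.

One open choice was whether the 50 ms minimum applies before or after edge
extension; it is applied before, on the supra-threshold core, so the
criterion expresses "sustained high power" rather than event width.

## State scoring

Scoring works on 10-s epochs of one hippocampal and one prefrontal channel.
Per epoch and area we compute a multitaper PSD (time–bandwidth product 4,
7 DPSS tapers — computed from the Slepian tridiagonal eigenproblem, at
reduced length with spline interpolation for long windows) and sum it over
seven bands (slow oscillation 0.1–1 Hz, delta 1–3, theta 3–6, low beta
10–20, low gamma 30–45, high gamma 55–80, ripple 90–300), adding the
theta/SO ratio and the epoch amplitude $\max|x|$. Epochs whose amplitude
exceeds the median by more than 3 scaled MADs are excluded; the rule is
one-sided because its purpose is artifact rejection and artifacts are
large — a two-sided rule would discard genuinely low-amplitude REM-like
epochs wholesale.

Features are log10-transformed (band powers are heavy-tailed; without the
transform a few extreme epochs dominate the covariance) and z-scored, PCA
retains PC1–PC2, and 2-means with 10 restarts at a fixed seed splits the
epochs. PC1's sign is oriented so the slow-oscillation-power and amplitude
loadings sum positive, and the cluster with the higher mean PC1 is labeled
NonREM-like — a deterministic automation of the usual visual labeling step.
Whether the two areas' features should be concatenated or averaged was
unspecified in the source method; we concatenate (18 features), which keeps
area-specific signatures visible to the PCA.

## Event features and the AUC power law

Features are computed on the filtered traces of both layers within the
event window — the ripple's `[start, end]` for R/SWR/cSWR (so a cSWR's
window spans all its sharp waves), the sharp wave's own window for SW. The
area under the curve is the trapezoidal integral of the absolute filtered
trace, deliberately *not* amplitude-normalized, so it grows with both
amplitude and duration. Amplitude is the envelope maximum; mean frequency
is the first spectral moment of the one-sided periodogram; power is
$\sum f(x)^2 / N$; peaks are strict local maxima with no prominence
requirement. The sharp-wave frequency uses a 6-cycle Morlet spectrogram
(1–200 Hz) of a 6-s radiatum context: power is summed over the event,
normalized to unit mass, and dotted with the frequency vector.

Cross-layer AUC relationships are fit by least squares in log10–log10
space; non-positive values are dropped with a reported count. Slopes of two
fits are compared through their correlations with the Fisher z-test
$z = (\operatorname{atanh} r_A - \operatorname{atanh} r_B) /
\sqrt{1/(n_A-3) + 1/(n_B-3)}$. For density displays, a bivariate Gaussian
kernel estimate is partitioned into levels enclosing equal probability
mass. For spectra and CSD, the analysis uses the 2000 events closest to the
median amplitude per type (pyramidale amplitude for ripple-bearing types,
radiatum amplitude for SWs — the source method does not say which; this is
our documented choice).

## CSD, AVREC, and the aperiodic slope

The CSD is the second spatial difference
$\mathrm{CSD}_i = \Theta_{i-1} - 2\Theta_i + \Theta_{i+1}$ over interior
channels of 6-s raw peri-peak windows, with unit-spacing normalization
(reported CSD units are arbitrary, as is conventional when the conductivity
is unknown). Boundary channels are dropped by default — the assumption-free
choice — with Vaknin edge duplication behind a flag. AVREC is the rectified
channel mean $\frac{1}{n}\sum_i |\mathrm{CSD}_i(t)|$, overall or per layer.
Delta-AVREC subtracts the SWR layer means from each type's layer means
(absolute) and divides by the reference (normalized); since the subtraction
direction in the source description is ambiguous, both orientations are in
the output table.

The aperiodic slope/offset machinery shares a single Morlet definition with
the sharp-wave frequency: six cycles, $\sigma_t = n_{cyc}/(2\pi f)$, on a
1–200 Hz grid. Wavelets are unit-energy (L2) normalized, which makes the
time-averaged wavelet power of stationary noise track its PSD — the
property the slope analysis needs; the trade-off is that a unit tone's peak
power scales as $1/f$ rather than being flat, which is irrelevant for
broadband slope fitting and is the normalization of the scipy continuous
wavelet transform this analysis style descends from. Power is averaged over
±250 ms around the event peak, floored at $10^{-12}$ of its maximum
(occurrences counted), and a least-squares line of log10 power on log10
frequency gives slope and offset. Slope analysis is applied to CSD-derived
signals by default (layer-averaged radiatum CSD in the pipeline) because
CSD is less contaminated by volume conduction than the LFP; the operation
itself accepts any single-channel trace.

## Phase, delta waves, and rates

The slow-oscillation phase is the analytic-signal angle of the 0.5–4 Hz
band-passed (3rd-order Butterworth) prefrontal signal over concatenated
NonREM-like bouts, mapped to [0°, 360°) with the cosine convention: signal
peak = 0°, trough = 180°, down-to-up transition (ascending zero crossing) =
270°. The source method never states its 0° reference, so absolute
positions are validated against synthetic ground truth rather than against
printed figures. Cortical delta waves are zero-crossing-delimited 1–6 Hz
cycles with a positive peak followed by a trough, kept when peak and trough
exceed their thresholds (defaults 2 and 1.5 SD; per-animal absolute
overrides exist because the published thresholds were manual) and the
duration lies in 150–550 ms. Bout-edge ripple rates use NonREM-like bouts
longer than 15 min and count ripple peaks in the first and last 10% of each
bout. The long/short ratio divides ripple-bearing events at a configurable
duration cutoff, 100 ms by default (the defining threshold comes from prior
work, not this method, so it is prominently a parameter).

## The synthetic generator

`sim_config()` / `generate_recording()` emulate a urethane session:

* **Background**: per-channel $1/f^{\beta}$ noise ($\beta = 2$, 30 µV RMS)
  built by frequency-domain shaping (exact slope control for the
  slope-recovery tests), flat below a 0.1 Hz corner like an AC-coupled
  amplifier. Hippocampal channels are smoothed across depth with an
  RMS-preserving Gaussian kernel (250 µm), mimicking volume conduction —
  without it the background CSD would dwarf any physiological sink.
  NonREM-like bouts carry a 1.3× broadband gain and REM-like 0.75×
  (brain-state comodulation; this is what makes two principal components
  explain ~90% of the feature variance, as on real data).
* **States**: alternating bouts (means 240 s NonREM-like, 120 s REM-like),
  edges snapped to the 10-s epoch grid so that every scored epoch is
  single-state — a fixture convenience real data does not share; boundary
  epochs in real recordings are genuinely ambiguous and cap attainable
  agreement. NonREM-like bouts put a 0.5–1 Hz slow oscillation on the
  prefrontal channels (120 µV, inverted and attenuated on the deep
  channel) with a depth-uniform 30% echo on hippocampal channels
  (contributing zero CSD); REM-like bouts carry 3.5–5.5 Hz theta.
  Oscillation amplitudes ramp over 1.5 s at bout edges to avoid broadband
  steps.
* **Events**: phenomenological templates — a Gaussian-windowed 120–180 Hz
  burst on the pyramidale depth profile (FWHM 70–150 ms; 180–300 ms for
  cSWR), negative Hann half-waves (50–90 ms) on the radiatum profile, and a
  small dipolar SLM deflection on ripple-bearing types. Depth profiles are
  Gaussian bumps, so the second spatial difference yields one sink with
  flanking sources. Amplitudes are stated as detection-band SNR: the ripple
  envelope peak is 12× the 90–200 Hz background SD and the sharp-wave
  trough 9× the 2–20 Hz background SD *after* the detection band-pass
  (narrow half-waves lose up to ~30% of their trough to the filter, so the
  template is pre-compensated). These values were fixed from detection
  theory — a 5 SD envelope threshold sits near 4.5× the band SD on clean
  noise, higher once events inflate the baseline — and from typical
  urethane CA1 amplitudes, where ripples exceed background by an order of
  magnitude. Events are placed only in NonREM-like bouts (configurable),
  phase-locked to the slow oscillation: ripples at the upstate peak (0°),
  sharp-wave-bearing types at the down-to-up transition (270°).
  `sr_input_gain` scales every radiatum component ("CBD-like" at 0.6);
  `slm_input_gain` scales the SLM components; all randomness is drawn
  before the gains apply, so paired fixtures share event times exactly.
  With `couple_ripple_duration = TRUE` (default) burst durations scale with
  the radiatum gain, encoding the hypothesis that sustained CA3 drive is
  what makes ripples long.

What the generator does **not** emulate: biophysical CA1 compartments,
drug pharmacokinetics (a "CBD-like" fixture is purely an input-gain
manipulation), mixed-state epochs, electrode drift, and real artifact
morphologies (injected artifacts are square pulses). Passing tests
therefore demonstrate the *machinery* — detector calibration, classifier
correctness, oracle-exact CSD/AVREC arithmetic, slope and phase recovery —
not field performance on arbitrary recordings, where thresholds may need
the per-animal adjustment the configuration exposes.

## Numerical choices

* Zero-phase filtering uses odd-reflection edge padding
  (20 / low-cutoff seconds) to suppress `filtfilt` start/end transients.
* The analytic signal is computed by the FFT Hilbert construction with
  reflection padding to a fast FFT length.
* Artifact blanking widens each interval by 0.5 s before and 3.5 s after
  and substitutes the per-channel clean mean. Two washout values appear in
  the source description (3.5 s and 3.33 s); 3.5 s is the default
  everywhere and the parameter is per-stage configurable. Band-pass
  filtering for detection must run *before* blanking; the pipeline enforces
  that ordering.
* The automatic artifact threshold is mean + 8 SD of the summed absolute
  signal (the published thresholds were visual; reproducibility wins here).
* Welch PSD: 4-s Hann segments, 0.25-s overlap, 0.25 Hz grid to 100 Hz,
  2nd-order IIR notch (Q = 30) at 50 Hz before the PSD.
* Degenerate inputs have defined behavior: flat traces yield no detections,
  an all-zero spectrum is flagged rather than log-transformed, the
  long/short ratio is flagged undefined when no short events exist, and a
  single-state recording produces labels plus a degenerate-clustering
  warning.

## Problem sizes

The test-suite and acceptance fixtures use 10–60 min recordings at 600 Hz
with 32 + 2 channels, five seeds for detector calibration, and 20 seeds per
exponent for slope recovery; these sizes give stable statistics (binomial
SE of a recall estimate at n ≈ 150 events is ~2%) while keeping a full run
in minutes on one core.

## A worked run

```{r, eval = FALSE}
out <- run_pipeline(config = sim_config(duration_s = 1800, seed = 1),
                    out_dir = "run1")
table(out$nrem_events$type)
out$delta_avrec
out$phase$summary
```

## Known limitations

* Performance numbers quoted anywhere in this package refer to the
  synthetic conditions above; real thresholds were tuned per animal in the
  source workflow and the config exposes the same overrides.
* The literal endpoint overlap rule ignores a sharp wave strictly
  containing a ripple; use `rule = "intersect"` when that matters.
* CSD assumes full laminar coverage in depth order; the pipeline's
  `csd_capable` flag is the user's assertion of that.
* The multitaper implementation interpolates DPSS tapers for windows longer
  than 1024 samples; for the 0.4 Hz bandwidth used here the approximation
  error is far below the estimator's variance.
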