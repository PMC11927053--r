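---
title: "Methods: movement-related beta dynamics, interhemispheric coupling and paired-pulse inhibition"
author: "betaConnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-related beta dynamics, interhemispheric coupling and paired-pulse inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaConnect)
```

## The problem

Unilateral voluntary movement reorganises sensorimotor beta-band
(14--30 Hz) rhythms over both motor cortices.  During movement, beta
power drops below its pre-movement baseline (movement-related beta
desynchronization, MRBD); after movement ends it rebounds above
baseline (post-movement beta synchronization, PMBS).  The two motor
cortices also interact: their EEG signals show frequency-specific
coherence, a directed (Granger-type) component of that coupling, and
-- measurable with paired-pulse transcranial magnetic stimulation
(TMS) -- interhemispheric inhibition (IHI), in which a conditioning
pulse over one motor cortex suppresses the motor-evoked potential
(MEP) elicited by a test pulse over the other.

betaConnect implements this analysis chain for epoched two-channel
(C3/C4) EEG and single-trial EMG/MEP waveforms: time--frequency
power, baseline normalisation, MRBD/PMBS feature extraction,
sectioned cross-spectral coherence, multivariate autoregressive
(MVAR) directed coherence with an analytic significance threshold,
and the IHI ratio.  Because the emulated study's recordings are not
publicly available, the package ships a first-class synthetic-data
module that generates bilateral epochs, coupled signal pairs,
AR-coupled processes and MEP trials with known ground truth, so that
every estimator can be validated by parameter recovery.

## Time--frequency power and ERSP features

Power is estimated with a sliding-window Fourier transform using a
frequency-adaptive window of three cycles (window length 3/f seconds),
a Hanning taper, and window centres advanced in 20 ms steps over a
5--40 Hz grid with 0.25 Hz spacing.  Epochs run from 0.25 s before to
2.5 s after the imperative stimulus.  Window positions that would
cross an epoch boundary are marked unavailable rather than zero-padded.

Power at each node is converted to relative power
\[
RP = \frac{P - P_{rest}}{P_{rest}} \times 100,
\]
where \(P_{rest}\) is the mean power over the available window
centres in the 250 ms pre-stimulus baseline, per channel and
frequency.  The beta time course is the unweighted mean of RP over
the 14--30 Hz bins (boundaries inclusive).

Feature extraction follows 10 %-threshold rules: the MRBD onset is
the first time after the stimulus at which the beta time course falls
to or below −10 % and stays there, the MRBD end is the first later
return above −10 %, and the MRBD value is the mean RP over a 200 ms
window centred on the trough; PMBS landmarks are defined analogously
with the +10 % crossing and the burst maximum, searched after the
MRBD end.  Features of a deflection that never crosses threshold are
reported as NA.

Three numerical choices harden these rules against estimation noise;
all are configurable arguments with the defaults given here:

* **Sustain count** (`sustain = 3`): a threshold crossing only counts
  as an onset if it persists for three consecutive 20 ms steps
  (60 ms).  A single-crossing rule fires on isolated noise
  excursions.
* **Peak tie tolerance** (`peakTol = 2` percentage points): all
  points within 2 points of the burst extreme are treated as an
  extremal plateau and the peak is placed at the median of that set.
  On a flat-topped burst the raw argmax is decided by noise and can
  land within 100 ms of the burst edge, where the 200 ms averaging
  window dips into the flanks; in our validation this single choice
  reduced the failure rate of amplitude recovery from roughly a
  quarter of runs to the percent level.  Two points is deliberately
  small relative to the 10-point threshold that defines a burst, so
  genuinely peaked bursts are unaffected.
* **Full-band coverage** (`minCoverage = 1`): the band-mean time
  course is only reported where every in-band frequency bin has an
  available window.  At the first and last window positions only the
  short high-frequency windows fit, and a "band mean" over that
  truncated subset is frequency-biased and noisy (on stationary test
  data it produced spurious 5--13 point deflections).  This is
  stricter than simply skipping unavailable bins, and we consider it
  the correct reading of a band average.
* Value windows that would cross the epoch edge are clipped, with a
  warning, rather than dropped.

The baseline is anchored to the imperative stimulus (time 0), not to
EMG-derived movement onset, because the epochs are stimulus-locked.

## Sectioned coherence

For two channels the analysis window of every kept trial is cut into
non-overlapping 50 ms sections (55 sections for a full 2.75 s epoch).
Each section is demeaned and Hanning-tapered; the cross-spectrum
\(X_{12}(f)\) and auto-spectra \(S_i(f)\) are averaged over all L
sections pooled across trials, and the magnitude-squared coherence is
\[
C_{12}(f) = \frac{|X_{12}(f)|^2}{S_1(f)\,S_2(f)}.
\]
Before forming the ratio, all three spectra are smoothed across
frequency with the 0.25/0.5/0.25 kernel; at the two endpoints the
available weights are renormalised to sum to one, so constant spectra
pass through unchanged.

Fifty-millisecond sections natively resolve only a 20 Hz frequency
grid, which cannot express a 14--30 Hz band average.  Sections are
therefore zero-padded to 1 s before the FFT, giving a 1 Hz display
grid; zero-padding interpolates the spectrum without adding
information, and the native-resolution spectra are retained in the
result object.  Sections are pooled across trials (L = trials x
sections per trial) because the significance threshold below is
parameterised by the *total* number of non-overlapping sections.

The band mean over 14--30 Hz is reported per analysis period.  The
MRBD- and PMBS-period windows are taken from the extracted feature
landmarks (onset to end on the trial-averaged time course), since the
periods have no fixed clock-time definition; the pre-stimulus
baseline serves as a control window.

## MVAR directed coherence

Coherence is symmetric; directionality is estimated by fitting the
bivariate autoregressive model
\[
X(t) = \sum_{i=1}^{p} A(i)\,X(t-i) + E(t), \qquad p = 10,
\]
to the analysis window.  Lag covariances are computed per kept trial
(each trial demeaned) and averaged across trials, and the multivariate
Yule--Walker equations are solved by the Levinson--Wiggins--Robinson
recursion; the implementation is verified in the test suite against a
direct block-Toeplitz solve of the same equations (agreement to
1e-10) and against least-squares regression on lagged values.  The
model order is fixed at 10 as in the reference analysis;
`selectOrder()` reports AIC- and BIC-optimal orders for diagnostics
and recovers the true order on simulated AR ground truth.  Stability
is checked via the companion-matrix spectral radius.

With the transfer function \(H(f) = A(f)^{-1}\),
\(A(f) = I - \sum_i A(i) e^{-i 2 \pi f i / f_s}\), directed coherence
is computed in its normalised form
\[
DirCoh_{i \leftarrow j}(f)
 = \frac{|H_{ij}(f)|^2 \sigma_j^2}{\sum_k |H_{ik}(f)|^2 \sigma_k^2},
\]
with \(\sigma_j^2\) the innovation variance of channel j.  The
denominator is the model autospectrum of channel i, so values lie in
[0, 1] and rows sum to one for diagonal innovation covariance.  A
literal autospectrum-over-autospectrum reading
\(|H_{ij}|^2 S_{jj}/S_{ii}\) (not bounded by 1) is available behind
`mode = "literal"`; the normalised form is the default because the
reference results lie in [0, 1] and are compared against a
coherence-scale threshold.  That threshold is
\[
Z = 1 - \alpha^{1/(L-1)}, \qquad \alpha = 0.05,
\]
with L the pooled section count of the matching spectral estimate.

## IHI

Each MEP trial is a 5 kHz EMG trace around a TMS test stimulus.  The
peak-to-peak amplitude is max − min inside a 15--50 ms post-stimulus
search window; the window is configurable because the reference
protocol does not state one, and 15--50 ms spans typical hand-muscle
MEP latencies.  IHI is the ratio of the mean conditioned (CS--TS)
amplitude to the mean unconditioned (TS) amplitude.  The ratio of
means is used, not the mean of per-trial ratios, because the two
trial types are interleaved but unpaired.  IHI is reported as a
fraction (0.52-style), with the equivalent percentage alongside: the
reference formula text multiplies by 100, but its results and figures
are on the fraction scale, and internal consistency wins.  The 10 ms
CS-to-TS interval is protocol metadata; no computation depends on it.

## The synthetic-data generator

`genBilateralEpochs()` emulates the statistical structure of the
study's recordings: 1 kHz sampling, epochs from −0.25 to 2.5 s, 60
trials per speed condition, a beta-band oscillation whose amplitude
follows per-channel plateau envelopes with 50 ms raised-cosine ramps
(step edges would leak broadband power across the time--frequency
plane), optional 1/f background, and configurable interhemispheric
coupling (none, shared source, or a lagged unidirectional mixture).
`defaultEnvelopes()` encodes plateau factors reproducing the
group-mean MRBD/PMBS levels of ballistic and self-paced movement on
both hemispheres, with an amplitude factor \(g = \sqrt{1 + p/100}\)
per relative-power level p; amplitudes are unitless (read them as
µV), since the reference reports no absolute baseline amplitude.

**Carrier model.**  The default beta carrier is a constant-envelope
oscillation whose instantaneous frequency sweeps the band with a
triangular profile (mean sweep rate 6.5 Hz, slowly jittered, with
random sweep and carrier phases per trial).  This choice is
deliberate: for band-limited *Gaussian* noise, a three-cycle window
holds only about two degrees of freedom of a 16 Hz-wide process, so a
60-trial average recovers a plateau amplitude with a standard
deviation near 16 percentage points -- amplitude ground truth would
be unrecoverable at useful precision.  The sweep carrier's short-time
band power equals its variance at every instant, which makes the
envelope the *exact* ground truth for the TFR pipeline (recovery
noise drops below one point), and one band traversal fits inside a
mid-beta analysis window so each window sees the same spectral
occupancy.  A `"gaussian"` carrier remains available where Gaussian
section statistics matter.

In pure-band mode (the default) the epochs contain only the enveloped
beta component; this is what makes analytic ground truth exact, and
it is the mode used by all parameter-recovery suites.  Realistic mode
adds a 1/f background (high-passed at 0.5 Hz like the emulated
acquisition) scaled by the in-band beta-to-background variance ratio.
With a realistic background, the three-cycle windows leak the
dominant low-frequency power into band bins and the relative-power
map fluctuates by tens of points, exactly as in real EEG -- passing
the pure-band recovery suites therefore demonstrates estimator
correctness, not field-ready robustness on noisy recordings.

`genSharedSourcePair()` builds x = s + n1, y = s + n2 from three
independent band-limited Gaussian processes, giving in-band coherence
\(\mathrm{var}_s^2 / (\mathrm{var}_s + \mathrm{var}_n)^2\) in closed
form (the Gaussian model is used here because its pooled sections are
nearly independent, making the sectioned estimator's spread several
times smaller than with the sweep carrier).  `genArCoupledPair()`
simulates a stable bivariate AR system with unidirectional coupling
for directed-coherence benchmarks, and `genMepTrials()` superposes a
biphasic MEP template, scaled to truncated-normal peak-to-peak
amplitude draws, on Gaussian baseline noise.

What the generator does **not** emulate: electrode geometry and
volume conduction, eye-blink/EMG artifacts (hence no ICA stage), mu
(8--13 Hz) rhythms, between-subject variance components, and
EMG-derived movement speed (speed is a condition label).

## Validation scale and reproducibility

The parameter-recovery analyses simulate eight subjects of 60 trials
per condition -- the emulated study's own group structure -- and
evaluate recovered MRBD/PMBS values on the subject-averaged beta time
course, coherence as the across-subject mean of per-subject estimates
(each pooling 600 sections), and IHI as the across-subject mean of
per-condition ratios (30 + 30 trials each).  At this scale the
recovery spread is well below the acceptance bands (about 0.4
percentage points for PMBS, 0.005 for coherence, 0.005 for IHI).
Every stochastic function takes a seed and restores the caller's RNG
state; a fixed seed reproduces results bit-for-bit.

## Known limitations

* EDF import/export is not provided (no EDF codec among the package's
  R dependencies); epochs interchange through a documented TSV + JSON
  sidecar layout instead.
* The artifact-screening statistics (M, SD per time point) are
  computed per channel; the reference text does not specify
  per-channel versus pooled, and per-channel is the interpretation
  implemented.
* Because screening statistics include the candidate trial, a single
  outlying sample can only exceed k·SD when more than k² + 1 trials
  are present; with k = 5 this needs at least 27 trials.
* ANOVA-family group statistics are intentionally not reimplemented;
  reports export flat tables consumable by any statistics package.
* The IHI module extracts amplitudes and ratios only; resting motor
  threshold estimation, intensity titration and EMG background
  screening are out of scope.
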