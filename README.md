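# betaConnect

Analysis of movement-related beta-band dynamics and interhemispheric
coupling from bilateral EEG/TMS/EMG recordings, with a ground-truth
synthetic-data module.

Unilateral voluntary movement suppresses sensorimotor beta (14–30 Hz)
power during movement (movement-related beta desynchronization, MRBD)
and rebounds it above baseline afterwards (post-movement beta
synchronization, PMBS).  The two motor cortices also couple: their
EEG shows band-specific coherence and a directed (Granger-type)
component, and paired-pulse transcranial magnetic stimulation reveals
interhemispheric inhibition (IHI) — suppression of a test motor-evoked
potential (MEP) by a conditioning pulse over the opposite hemisphere.
betaConnect is for researchers who want this full analysis chain as
tested, reusable R functions: EEG physiologists analysing C3/C4
epochs, and methods developers who need estimators validated against
known ground truth.

## What it computes

* **Time–frequency power**: sliding-window Fourier power with a
  frequency-adaptive three-cycle Hanning window (ΔT = 3/f), 0.25 Hz
  frequency steps, 20 ms time steps; baseline normalisation
  RP = (P − P<sub>rest</sub>)/P<sub>rest</sub> × 100 against the
  250 ms pre-stimulus baseline.
* **ERSP features**: MRBD/PMBS values (mean RP over a 200 ms window
  centred on the trough/peak) and 10 %-threshold onset, end, latency
  and duration landmarks.
* **Sectioned coherence**: C₁₂(f) = |X₁₂(f)|² / (S₁(f) S₂(f)) from
  50 ms non-overlapping sections pooled across trials, with
  0.25/0.5/0.25 spectral smoothing and beta-band averaging.
* **Directed coherence**: bivariate MVAR model (order 10) fitted by
  the Levinson–Wiggins–Robinson recursion on trial-averaged lag
  covariances; DirCoh<sub>i←j</sub>(f) = |H<sub>ij</sub>(f)|² σ<sub>j</sub>² / Σ<sub>k</sub> |H<sub>ik</sub>(f)|² σ<sub>k</sub>²,
  with the analytic significance threshold Z = 1 − α^(1/(L−1)).
* **IHI**: peak-to-peak MEP amplitudes and the conditioned/
  unconditioned mean-amplitude ratio (values < 1 signal inhibition).
* **Synthetic data**: bilateral beta epochs with plateau amplitude
  envelopes, shared-source and AR-coupled signal pairs, and MEP
  trials — all with closed-form ground truth (see the methods
  vignette, `vignettes/beta-dynamics-methods.Rmd`).

## Worked example

```r
library(betaConnect)

## 1. A synthetic ballistic-movement condition: 60 bilateral beta epochs
cfg <- synthEegConfig(nTrials = 60, speed = "ballistic", seed = 42)
epochs <- rejectArtifacts(genBilateralEpochs(cfg))

## 2. Beta-band ERSP features (MRBD / PMBS values and landmarks)
tfr <- computeTfr(epochs, freqs = seq(14, 30, by = 0.25))
tc  <- betaTimecourse(baselineNormalize(tfr))
extractErspFeatures(tc)
#> ErspFeatures (band 14-30 Hz, threshold 10%, sustain 3 steps):
#>   channel mrbdValue mrbdOnset mrbdEnd mrbdDuration pmbsValue pmbsLatency
#> 1      C3    -45.30      0.11    0.71          0.6     84.26        1.15
#> 2      C4    -37.64      0.11    0.71          0.6     58.55        1.17
#>   pmbsEnd pmbsPeakTime pmbsDuration
#> 1    1.87         1.55         0.72
#> 2    1.85         1.53         0.68
```

The generator's default ballistic envelopes encode contralateral
dominance: beta power over C3 (contralateral to the moving right
hand) drops by ~46 % during movement and rebounds by ~84 % after it,
against ~38 % / ~59 % ipsilaterally — and the pipeline recovers those
levels together with the burst timing.

```r
## 3. Interhemispheric coherence of a shared-source pair
##    (true in-band coherence = 0.65574^2 = 0.43)
dat <- array(0, dim = c(60, 2, 500))
set.seed(43)
for (tr in 1:60) {
  p <- genSharedSourcePair(0.65574, 0.34426, duration = 0.5)
  dat[tr, 1, ] <- p$x; dat[tr, 2, ] <- p$y
}
pair <- EpochedSignals(dat, fs = 1000, t0 = 0)
est <- smoothSpectrum(sectionSpectra(pair, periodLabel = "pmbs"))
coherence(est)
#> CoherenceResult [pmbs]: band 14-30 Hz mean = 0.4468 (L = 600)

## 4. Directed coherence on a unidirectionally coupled AR pair (x -> y)
ar <- genArCoupledPair(0.8, lag = 1, nSamples = 30000, seed = 44)
model <- fitMvar(cbind(ar$x, ar$y), p = 10, fs = 1000,
                 channelNames = c("C3", "C4"))
directedCoherence(model, L = 600)
#> DirCohResult (normalized): band 14-30 Hz means
#>   C3 <- C4 : 0.0000
#>   C4 <- C3 : 0.7179
#>   significance threshold Z = 0.00499 (alpha = 0.05, L = 600)

## 5. Paired-pulse IHI from synthetic MEP trials (30 TS + 30 CS)
meps <- genMepTrials(synthMepConfig(seed = 45))
computeIhi(mepPeakToPeak(meps))
#> IhiResult [ballistic_peak]: IHI = 0.537 (CS 0.809 mV / TS 1.507 mV; n = 30 + 30)
```

The coherence estimate sits at the closed-form target (0.43), the
directed-coherence estimator finds the built-in C3→C4 drive (0.718,
far above threshold) while the reverse direction is indistinguishable
from zero, and the IHI ratio recovers the configured 0.78 mV / 1.50 mV
amplitude means.

`runCondition()` chains all stages (screening → ERSP → period-wise
coherence and directed coherence → IHI) into a `ConditionReport`
exportable as JSON/CSV, and `inst/cli/betaconnect.R` exposes the same
steps as shell subcommands (`simulate`, `ersp`, `coherence`,
`dircoh`, `ihi`, `run`, `correlate`).

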