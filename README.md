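# gammaSME

Single-trial decoding of the **subsequent memory effect (SME)** from
gamma-band power in multichannel cortical field potentials (ECoG-style
recordings), for electrophysiologists and methodologists who want the
full chain — from continuous signal to cross-validated classification
accuracy — as tested, reproducible R code. Because patient recordings of
this kind cannot be redistributed, the package includes a first-class
synthetic generator with the statistical structure the analysis assumes,
so every stage is verifiable without any data download.

## What it computes

Starting from a continuous recording with word-onset events labelled
*remembered* / *forgotten* plus a pre-task resting segment:

1. **Common average reference**: `x_c(t) − mean_c x_c(t)` per sample.
2. **Epochs** around each onset (default −1 to +1.5 s, half-open sample
   windows).
3. **Morlet-wavelet power**: unit-energy kernels with envelope SD
   `σ_t = n / (2πf)` (default `n = 7` cycles) on a 30–150 Hz grid;
   power = squared magnitude, **normalized** by mean resting power per
   channel and frequency (a plain ratio).
4. **Band/window features**: mean normalized power per channel in low
   gamma (30–60 Hz) and high gamma (60–150 Hz) over the −0.5–0 s, 0–1 s
   and 0–1.5 s windows.
5. **SME map**: pooled-variance two-sample t per feature
   (remembered − forgotten, df = n₁+n₂−2), Bonferroni correction, and
   top-fraction selection by |t| (default top 20%).
6. **Decoding**: soft-margin SVM with RBF kernel
   `K(x,y) = exp(−‖x−y‖² / 2σ²)` (σ = 2, cost = 1), repeated stratified
   80/20 splits (default 10,000 iterations), feature selection
   recomputed inside each training fold by default (leakage-free), with
   label-permutation chance calibration and LDA/FLDA comparison on
   identical splits.

The synthetic generator produces band-limited `1/f^β` background noise
(0.1–150 Hz, β = 1) at 1,600 Hz with a 5-minute resting segment, and adds
independent band-limited bursts to remembered trials on chosen channels
so expected band power is exactly `(1 + effectSize)` × the forgotten
level after stimulus onset.

## Worked example

```r
library(gammaSME)

cfg <- pipelineConfig(
  synth = synthConfig(nChannels = 8, samplingRate = 400,
                      nRemembered = 24, nForgotten = 24,
                      effectChannels = 1:3, effectBand = c(60, 150),
                      effectSize = 0.6, restingDuration = 60,
                      epochWindow = c(-0.6, 1.2), interTrialInterval = 2.5),
  wavelet = waveletSpec(seq(30, 150, by = 8)),
  cv = cvSpec(iterations = 300),
  windows = list(pre = c(-0.5, 0), early = c(0, 1)),
  masterSeed = 42)
res <- runPipeline(cfg, verbose = TRUE)
#> session: 8 channels, 48 events (24 REM / 24 FOR)
#> kept 48/48 trials after screening
#> features: 32 (2 bands x 2 windows x 8 channels)
#> pre: mean accuracy 0.51, max 0.9
#> early: mean accuracy 0.993, max 1

res$windows$early$cv
#> CVResult: 300 splits (38 train / 10 test), mean 0.993, max 1.000, sd 0.025
```

The +60% high-gamma effect was injected post-onset on channels 1–3: the
pre-stimulus window decodes at chance (0.51) while the during-stimulus
window is near ceiling (0.993). The SME map recovers exactly those
channels as the top-ranked features:

```r
m <- res$windows$early$sme
fi <- featureIndex(m)
top <- order(-abs(tValues(m)))[1:3]
data.frame(fi[top, c("channel", "band")], t = round(tValues(m)[top], 2))
#>    channel      band     t
#> 26       2 highGamma 12.35
#> 25       1 highGamma 10.73
#> 27       3 highGamma  9.91
```

`writeResultsBundle(res, "out/")` writes a JSON summary (tagged with a
hash of the configuration) plus per-window accuracy and t-table CSVs;
`writeSession()` / `readSession()` round-trip sessions through a
plain-text container losslessly.

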