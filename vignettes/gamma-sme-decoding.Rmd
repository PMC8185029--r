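---
title: "Decoding the subsequent memory effect from gamma-band power"
author: "gammaSME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the subsequent memory effect from gamma-band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaSME)
```

## The problem

During encoding of a verbal memory task, cortical field potentials differ
between items that will later be remembered and items that will be
forgotten — the subsequent memory effect (SME). In intracranial
recordings the most reliable single-trial signature is a broadband
increase of gamma power (30–150 Hz, split into low gamma 30–60 Hz and
high gamma 60–150 Hz). gammaSME implements the complete single-trial
decoding chain for this signature: multichannel continuous recordings →
common average reference → epochs around word onsets → Morlet-wavelet
power → resting-baseline normalization → band/window power features →
per-feature t maps → top-fraction feature filtering → RBF-SVM
classification under repeated stratified random splits, with
label-permutation chance calibration and LDA/FLDA comparison.

Patient ECoG of this kind is not publicly distributable, so the package
ships a first-class synthetic generator whose statistical structure is
exactly what the analysis assumes; every downstream stage is tested
against it.

## The synthetic generator

`generateSession()` draws, per channel, Gaussian noise whose amplitude
spectrum is shaped as $f^{-\beta/2}$ (power $\propto 1/f^\beta$, default
$\beta = 1$) and band-limited to 0.1–150 Hz, emulating an acquisition
chain sampling at 1,600 Hz with a 0.1–150 Hz bandpass. Amplitude units
are arbitrary: every downstream statistic is a ratio to baseline or is
standardized, so no microvolt calibration is attempted. A resting
segment (default 5 minutes) is drawn from the same process, and word
events are scheduled at a fixed inter-trial interval (default 5 s, the
1-s fixation plus 4-s word display of a typical verbal encoding trial;
jitter is deliberately absent so sessions are reproducible
sample-for-sample). The default trial imbalance is 43 remembered / 10
forgotten, the average yield of the kind of recognition experiment this
models.

The memory effect is *induced*, not phase-locked: on each remembered
trial and each designated effect channel an independent band-limited
Gaussian burst is added over the post-onset portion of the epoch, scaled
from the analytically known background band variance so that the
expected band power is exactly $(1 + \text{effectSize})$ times the
forgotten-trial level. A separate `preEffectSize` can place an effect in
the pre-stimulus second; by default the effect is post-onset only, which
is what makes the pre-/during-stimulus comparison in the tests
meaningful.

What the generator does **not** emulate: movement and epileptiform
artifacts (screening is exercised with injected spikes instead), line
noise, electrode geometry and anatomical labels, inter-channel
correlation of the background, and slow nonstationarities across a
session. Passing tests therefore demonstrate correctness of the
pipeline's statistics and plumbing under its stated assumptions — not
clinical-grade decoding performance on real recordings.

## Preprocessing

`commonAverageReference()` subtracts the instantaneous channel mean from
every sample (and from the resting segment, so baselines live in the
same reference). Note one physical consequence the tests account for:
re-referencing mixes a fraction of the effect channels' bursts into all
channels, slightly diluting the injected effect — with 6 effect channels
out of 20, a +50% injection measures as roughly +45% after CAR.

`epochize()` uses half-open sample windows
$[\,\text{onset} + \text{round}(t_0 f_s),\ \text{onset} +
\text{round}(t_1 f_s)\,)$ with rounding half away from zero, so trial
lengths are deterministic (at 1,600 Hz a (−1, 1) s window is always
3,200 samples, (−1, 1.5) s always 4,000) and the onset sample belongs to
the post-stimulus side.

`screenTrials()` replaces irreproducible manual artifact review with an
automatic rule: reject a trial whose peak absolute amplitude on any
channel exceeds `threshold` (default 8) times that channel's robust SD
(1.4826 × MAD over all trials and samples). Under the Gaussian
background, 8 robust SDs is far in the tail, so clean data keep all
trials while a genuine spike is caught.

## Time–frequency power

`morletPower()` convolves each trial and channel with unit-energy
complex Morlet kernels, $\sigma_t = n/(2\pi f)$ with $n$ = `cycles`, and
squares the magnitude. Two conventions matter:

* **Cycles.** The default is $n = 7$. Wave-number conventions in the
  literature are not mutually consistent (a 7-cycle kernel has a 95%
  effective window of $2 \times 1.96\,\sigma_t \approx 87$ ms at 50 Hz;
  a 2.48-cycle kernel ≈ 31 ms), so the kernel is parameterized
  explicitly by `cycles` and `effectiveWindow()` reports the resulting
  window length rather than hard-coding any printed value.
* **Normalization.** Kernels are L2-normalized. Any per-frequency
  constant cancels in the baseline ratio, so downstream statistics are
  insensitive to this choice; unit energy simply keeps raw power
  comparable across frequencies.

Kernels are truncated at ±5σ. Samples within half the kernel support of
an epoch edge overlap the zero padding; their per-frequency count is
stored in `edgeCounts` and they are excluded from every window mean.
The default frequency grid is 30–150 Hz in 2-Hz steps; only the band
edges are scientifically meaningful, and band means are insensitive to
the step because neighbouring-frequency power is strongly correlated
(the acceptance script uses a 4-Hz step). A `downsample` argument
decimates the stored power time axis; the squared envelope has bandwidth
of order $f/n \le 21$ Hz here, so decimating 1,600-Hz power by 4 leaves
window means unchanged while dividing memory by 4.

`baselineNormalize()` divides trial power by the time-mean resting power
per channel and frequency — a plain ratio, not dB and not a z-score,
with the pre-task resting segment (not the per-trial fixation second) as
the baseline. A nonpositive or non-finite baseline is an error, never a
silent NaN. `bandFeatures()` then averages normalized power over each
band's frequencies and each analysis window's valid samples, yielding
one feature per (channel, band, window) with the three canonical windows
−0.5–0 s, 0–1 s and 0–1.5 s. Bands are half-open with the top grid edge
inclusive, so 60 Hz belongs to high gamma only and 150 Hz is not
dropped.

## SME statistics

`smeTMap()` computes, per feature, the pooled-variance two-sample t
(remembered minus forgotten, df $= n_1 + n_2 - 2$, two-sided p). The
equal-variance form is used deliberately — the classical independent
two-sample test — and its calibration under the global null is itself a
test (rejections at $\alpha$ fall inside binomial bounds).
`bonferroniCorrect()` multiplies p by the family size with a strict
`< alpha` mask. `selectFeatures()` ranks by $|t|$ (magnitude, not signed
t, so a hypothetical negative SME would rank too) and keeps
`ceiling(fraction × n)` features, default fraction 0.2; ties break
deterministically by channel, then band, then window. An explicit `k`
supports fixed-size rules such as a top-10.

Normality screening uses a Lilliefors test whose null distribution is
simulated (10,000 draws at the observed n, cached) rather than read from
an analytic table; this keeps the test exact at any n ≥ 4 and the
implementation self-contained.

## Decoding

The classifier is a soft-margin SVM with Gaussian kernel
$K(x, y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$, $\sigma = 2$ and cost
$C = 1$ by default. Features are standardized per training fold (mean/SD
from the training trials only) because an RBF kernel with fixed σ is
scale-sensitive; the flag is exposed. Validation is by repeated random
80/20 splits — default 10,000 iterations at full scale, reducible —
**stratified by class**: with as few as 10 forgotten trials,
unstratified splits frequently produce single-class test sets, so
stratification is what makes the protocol executable at realistic
imbalance. Both plain and balanced accuracy are recorded per iteration,
and both the mean and the max over iterations are reported, because a
max over 10,000 resamples is an optimistically biased summary and should
never travel alone.

Two selection protocols are supported and the distinction matters:

* `"pooled"`: features are ranked on *all* trials before
  cross-validation. Selecting on data that includes future test folds
  leaks information: under the null this biases accuracy above chance.
* `"within-fold"` (the default): the t ranking is recomputed inside each
  training fold. This is the statistically sound protocol, and it is the
  one under which the chance-level calibration below is an honest 50%.

`permutationChance()` estimates the decoding null by shuffling labels
(default 200 permutations, 100 CV iterations each; the Monte-Carlo error
of a null mean over 100 splits is a fraction of a percentage point). A
documented caveat: with 45/10 imbalance the null *plain* accuracy
concentrates near the majority proportion (~82%), not 50% — balanced
accuracy is the statistic whose null sits at 50%, and it is the default.
`compareClassifiers()` runs LDA (pooled-covariance Gaussian
discriminant, equal priors) and Fisher's discriminant (midpoint
threshold) on the identical split stream as the SVM; the two are
equivalent under equal priors and the comparison asserts it. A singular
pooled covariance is ridge-regularized with $10^{-6}\,\mathrm{tr}(S)/d$.

## Chance-level calibration and Monte-Carlo error

A subtlety drives the design of the null tests: for one finite dataset,
the accuracy averaged over arbitrarily many random splits does *not*
converge to 50% under the null — test trials are reused across splits,
so the split-average converges to a dataset-conditional value that
fluctuates around chance with SD of several percentage points at 60
trials. The split-level standard error `sd/sqrt(iterations)` therefore
understates the uncertainty of a single-dataset experiment. The honest
Monte-Carlo unit is the dataset: the calibration tests average several
independently generated null sessions and compare the grand mean against
50% using the empirical SE across sessions, and the acceptance script
does the same (eight sessions of 30+30 trials, 500 iterations each).

## Reproducibility

One master seed drives everything through a named-stream splitter
(`stageSeed()`): each pipeline stage draws from its own derived stream,
so stages can be re-run independently with identical randomness and a
fixed configuration reproduces accuracies bit-for-bit. Every results
bundle embeds a hash of the configuration that produced it. Sessions,
epochs and features round-trip through plain-text containers (`%.17g`,
lossless for doubles).

## Problem sizes

Full-scale defaults (20+ channels, 1,600 Hz, 2-Hz grid, 10,000
iterations) are what a real analysis would run. The test suite and the
examples in this vignette exercise the identical code paths at reduced
sizes chosen to keep a laptop run comfortable — typically 6–20 channels
at 400 Hz, a 12-Hz grid step, 20–60 s resting segments and 60–500 CV
iterations — with tolerances derived from the Monte-Carlo error at those
sizes, as documented test by test.

## A small end-to-end run

```{r pipeline, eval = FALSE}
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
res$windows$early$cv
```

With a +60% high-gamma effect on channels 1–3 this decodes the
during-stimulus window near ceiling while the pre-stimulus window stays
at chance, and the top-ranked SME features are exactly the three
injected high-gamma channels (the README shows the printed output).

## Known limitations

* The generator's channels are independent; real ECoG has strong
  spatial correlation, which would change feature redundancy and
  selection behaviour.
* Artifact screening is a single amplitude rule; it is a stand-in for
  review, not a detector of epileptiform activity.
* `"pooled"` selection reproduces a common published protocol and is
  retained for comparability, but its accuracies are optimistic; new
  analyses should keep the within-fold default.
* The permutation test permutes labels freely, which assumes
  exchangeable trials; slow drifts within a session would violate this.
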