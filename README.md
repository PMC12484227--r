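# coptgak

Similarity scoring for multichannel wearable-sensor time series, built
around a **class-optimized Global Alignment Kernel (GAK)**, with
early-stopping monitors for the training and sampling phases of
time-series diffusion models.

## The problem

Generative models for sensor time series (e.g. denoising diffusion
models trained on IMU activity windows) lack an objective criterion for
when to stop training or sampling: the usual training loss says little
about whether the synthetic sequences resemble real ones.  This package
scores synthetic-vs-real similarity with a kernel whose bandwidth is
calibrated per activity class, and turns that score into stop rules, so
that a generative run halts as soon as sample quality reaches the range
observed between real recordings.

## The score

For two univariate sequences *x*, *y* the Global Alignment Kernel sums,
over every monotone alignment path π (match / insert / delete steps),
the product of per-step local kernels

&nbsp;&nbsp;&nbsp;&nbsp;κ(x\_i, y\_j) = e^d / (2 − e^d),&nbsp;&nbsp;
d = −(x\_i − y\_j)² / (2σ²),

evaluated by a log-space dynamic program, and the normalized score

&nbsp;&nbsp;&nbsp;&nbsp;ϑ(x, y) = k(x, y) / √(k(x, x) · k(y, y)) ∈ [0, 1]

is applied per channel — on Welch power spectral densities by default,
so phase is discarded — and averaged across channels.  The bandwidth σ
controls selectivity: tiny σ collapses all scores toward 0, huge σ
toward 1.  The **class-optimized** choice (C-Opt GAK) maximizes the mean
train-validation score subject to the score standard deviation lying in
a preset range (default [0.09, 0.12]), selected by grid search per
activity class; the mean ± sd at the optimum defines the acceptance
range used by the training monitor.  Cosine, Pearson and RMSE baselines
are included, along with the classical median-heuristic bandwidth for
comparison.

Two stop rules consume the scores:

* **training monitor** — every 50th epoch a batch of synthetic sequences
  is scored against the real training set; training stops once at least
  25 % of the scores lie in the acceptance range at two consecutive
  checkpoints (calibrated-GAK rule) or after two checkpoints without a
  new score maximum (cosine rule);
* **denoising monitor** — every 30th reverse-diffusion step the
  intermediate batch is scored; sampling stops after two consecutive
  drops of the mean score and returns the best-scoring batch.

A seeded generator of IMU-like data (cyclic multi-harmonic activity
classes with per-subject variation; acyclic transient bursts) and a
minimal linear-denoiser diffusion harness make the whole pipeline
runnable end to end without any external dataset.

## Worked example

```r
library(coptgak)
d   <- makeCyclicDataset(SynthSpec(seed = 7))          # 12 subjects, 4 classes
cal <- calibratePerClass(d$train, d$validation, classes = "Cycling")[["Cycling"]]
cal
#> GAKCalibration [Cycling / all]
#>   sigma_opt = 0.961725  (aggregation: best_match)
#>   mean score = 0.8587, sd = 0.0912  (sd constraint [0.09, 0.12])
#>   acceptance range = [0.7675, 0.9499]; sweep: 60 grid points, 4 feasible
```

The calibration picked σ ≈ 0.96 for this class: the largest mean
train-validation similarity (0.86) whose spread (0.091) stays inside the
configured band.  Scoring one training window against a validation
window of the same class:

```r
x <- sequences(filterClass(d$train, "Cycling"))[[1]]
y <- sequences(filterClass(d$validation, "Cycling"))[[1]]
multichannelScore(x, y, "gak", "psd", sigma = sigmaOpt(cal))
#> $per_channel
#>     AX     AY     AZ     GX     GY     GZ
#> 0.9976 0.7938 0.9442 0.9888 0.7733 0.8503
#> $averaged
#> 0.8913
```

The averaged score 0.89 falls inside the acceptance range — these two
real windows are as similar as the calibration expects.  A white-noise
window against the same real window scores ≈ 1e-14 under the calibrated
kernel but 0.17 under cosine-PSD: the calibrated kernel separates noise
from signal where cosine similarity reports spurious resemblance.

The monitored demo pipeline (calibrate, train the bundled diffusion
harness until the monitor stops it, sample with the denoising monitor):

```r
r <- runDeskDemo(seed = 1)
stopStep(r$training$trace)     #> 100   (of a 1500-epoch horizon)
r$batchScore$mean              #> 0.599 (monitored best batch vs real)
r$noiseScore$mean              #> 0.007 (noise baseline)
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/coptgak.R synth     --preset cyclic4 --subjects 12 --seed 7 --out data/
Rscript inst/cli/coptgak.R calibrate --train data/train.rds --val data/validation.rds --out calib.json
Rscript inst/cli/coptgak.R score     --a data/validation.rds --b data/train.rds \
                                     --metric gak --sigma 0.96 --out scores.csv
```

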