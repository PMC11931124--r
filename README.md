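# DBayesNet

Uncertainty-aware classification of serum Raman spectra with a dual-branch
variational Bayesian 1-D convolutional network, plus the full preprocessing
chain such spectra need and a synthetic serum-spectrum simulator to exercise
every stage without clinical data.

## The problem and the method

Serum Raman spectra of diseased and control subjects share the same
biochemical bands — amide I (1653 cm⁻¹), lipid CH₂ (1432), protein/guanine
(1320), amide III/proline (1246), glycogen (1048), tyrosine (852), DNA
(720), and so on — and differ mainly in band *magnitude*, buried under a
large fluorescence background. The package implements:

* **Preprocessing** in the standard order: fingerprint-band selection
  (500–2000 cm⁻¹), Savitzky–Golay smoothing (window 9, order 2), airPLS
  baseline correction (adaptive iteratively reweighted penalized least
  squares on sparse Whittaker solves), leave-one-out-correlation outlier
  screening, and unit-area normalization.
* **A dual-branch Bayesian network.** Each branch: BayConv stem → four
  ResNet-style bottleneck blocks → squeeze-and-excite channel attention →
  adaptive average pooling; branches differ in stem kernel (3 vs 7, two
  receptive-field scales); pooled features are concatenated and classified
  by a BayLinear layer. Every conv/linear weight carries a Gaussian
  posterior `N(μ, σ²)`, `σ = softplus(ρ)`, against a `N(0, 0.1²)` prior;
  training maximizes the evidence lower bound

      L = CE(logits, labels) + β · KL(q ‖ prior) / N

  with reparameterized weight samples (`w = μ + σ⊙ε`) and Adam.
* **Monte-Carlo prediction**: class probabilities averaged over `T`
  posterior draws (each draw's batch-norm statistics recalibrated for that
  draw), predictive entropy as the uncertainty signal.
* **Evaluation**: confusion matrix (predicted × actual), sensitivity
  `TP/(TP+FN)`, precision `TP/(TP+FP)`, specificity `TN/(TN+FP)`, accuracy,
  threshold-sweep ROC/AUC, subject-grouped stratified splits.

See `vignettes/dbayesnet-methods.Rmd` for the model, its assumptions, and
every numerical choice.

## Worked example

```r
library(DBayesNet)

# simulate a labeled cohort: 2 x 80 subjects x 3 replicate spectra
cfg  <- syntheticConfig(scheme = labelScheme("diagnosis"), seed = 1)
raw  <- simulateSpectra(cfg)
raw
#> SpectrumSet with 480 spectra x 1501 points
#>   axis: 500 .. 2000 cm^-1
#>   subjects: 160
#>   labels: non-SLE=240, SLE=240

clean <- preprocessSpectra(raw)                 # band, S-G, airPLS, QC, area
parts <- splitBySubject(clean, train_frac = 0.8, seed = 2)

model <- buildDBayesNet(dbayesNetConfig(), input_length = nrow(clean), seed = 3)
fit   <- trainDBayesNet(model, parts$train, trainConfig(epochs = 100, seed = 4))
report <- evaluateModel(fit$model, parts$test, T = 30, seed = 5)
report
#> EvalReport on 96 spectra
#> confusion (rows = predicted, cols = actual):
#>          actual
#> predicted non-SLE SLE
#>   non-SLE      48   0
#>   SLE           0  48
#> positive class 'SLE': sens 1.000  prec 1.000  spec 1.000  acc 1.000  AUC 1.000
```

(The simulator's class separation is deliberately clean, so near-perfect
test metrics are expected; the point is that the machinery — grouping,
training, uncertainty — is exercised end to end.) The one-call version of
the same workflow, including the out-of-distribution entropy contrast on 50
peakless spectra, is

```r
res <- runDiagnosisExperiment(seed = 1)
res$summary$accuracy        # 1.0
res$summary$auc             # 1.0
res$entropy                 # id_median 0.073, ood_median 0.543 (nats)
```

— for this fit, blank spectra receive substantially higher predictive
entropy than in-distribution test spectra. (That ordering is a property of
the fitted posterior, not a guarantee: other seeds can produce fits where it
collapses — see the methods vignette's discussion before relying on entropy
as an out-of-distribution alarm.)

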