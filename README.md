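# adlHMM

Activity recognition for single-resident smart homes instrumented with
binary state-change sensors (reed switches on doors and cupboards, PIR
motion detectors, float sensors). Given a stream of timed sensor
activations and activity annotations, the package recognises activities of
daily living (sleeping, toileting, breakfast, leaving, ...) one time slice
at a time — the kind of labelling that ambient assisted-living and elderly
health-monitoring systems are built on.

## The model

The timeline is discretized into slices of Δt = 60 s. Slice *t* carries a
binary observation vector **x**_t ∈ {0,1}^N (sensor *i* fired for at least
a second during the slice) and a hidden activity label *y_t* ∈ {1..Q}.
A first-order hidden Markov model factorizes the joint distribution as

    p(y_1:T, x_1:T) = p(y_1) p(x_1|y_1) ∏_t p(y_t|y_t-1) p(x_t|y_t)

parameterized by initial probabilities π, the transition matrix A, and an
observation model. Two observation models are provided:

* **Generative:** each sensor is an independent Bernoulli given the
  activity, p(x_t|y_t = i) = ∏_n μ_in^x (1-μ_in)^(1-x). All parameters
  have closed-form supervised estimators (`estimateSupervised()`).
* **Hybrid generative/discriminative:** a static classifier — an MLP with
  softmax outputs, or RBF-kernel SVMs with Platt-calibrated decision
  values — supplies per-slice posteriors p(y_t|**x**_t). By Bayes' rule
  p(**x**_t|y_t) ∝ p(y_t|**x**_t) / p(y_t), so the *scaled likelihoods*
  (posterior over class prior) replace the Bernoulli emission terms, and
  Viterbi decoding recovers the maximum-probability activity sequence
  while the classifier contributes its discriminative power
  (`trainHybrid()`, `predict()`).

Three binary feature encodings of the sensor stream are supported and can
be concatenated: **raw** (sensor active), **change point** (sensor changed
state), and **last sensor** (most recently changed sensor holds a 1).

Evaluation follows the field's protocol: leave-one-day-out
cross-validation scored with macro-averaged precision, recall and
F-measure (so rare activities count as much as dominant ones), plus paired
Student and Wilcoxon signed-ranks tests across folds. A seeded synthetic
smart-home simulator (`sampleHome()`) generates event streams, annotations
and ground truth with realistic persistence and class imbalance, so the
entire stack is testable without external recordings.

## Worked example

```r
library(adlHMM)

sim  <- sampleHome(replicationConfig(), seed = 11)   # 6 simulated days
days <- lapply(splitDays(sim$truth), function(d)
  list(features = rawFeatures(d), labels = sliceLabels(d)))
cn <- classNames(sim$truth)

model  <- trainHybrid(days[1:5], emitterConfig("mlp", seed = 2),
                      trainOptions(), classNames = cn)
test   <- days[[6]]
hybrid <- predict(model, test$features)              # Viterbi decoding
static <- predictStatic(model@emitter, test$features) # per-slice argmax

macroMetrics(confusionCounts(test$labels, hybrid, cn))["fmeasure"]
#> fmeasure
#>  0.57204
macroMetrics(confusionCounts(test$labels, static, cn))["fmeasure"]
#> fmeasure
#> 0.3299945
```

The two numbers are the held-out day's macro F-measure with and without
the HMM's temporal smoothing: the same fitted MLP scores each slice, but
Viterbi decoding over the learned transition structure removes isolated
misclassifications that the per-slice argmax keeps, nearly doubling the
class-averaged F on this noisy simulated home.

A command-line front end over the same functions is in
`inst/scripts/adlhmm.R` (subcommands `simulate`, `featurize`, `train`,
`predict`, `evaluate`).

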