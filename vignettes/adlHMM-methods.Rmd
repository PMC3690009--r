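---
title: "Hybrid HMM activity recognition: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid HMM activity recognition: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adlHMM)
```

## The recognition problem

A single resident lives in a home instrumented with N binary state-change
sensors. Each sensor emits timed on/off intervals; an annotator (or a
simulator) provides activity intervals. The recognition task is: given the
sensor stream, label every Δt-second time slice with the activity being
performed. Two properties of this domain drive every design decision in
the package:

* **Temporal persistence.** Activities last many slices (sleeping lasts
  hours, toileting minutes), so neighbouring labels are strongly
  dependent; any per-slice classifier leaves easy accuracy on the table.
* **Class imbalance.** A handful of activities (sleeping, leisure,
  being out) occupy most of the day while clinically interesting ones
  (toileting, meals) are rare. Accuracy is therefore useless as a metric,
  and macro-averaged F-measure — which weighs every class equally — is
  used throughout.

## Data representation

`discretize()` cuts the span `[t0, t1)` into `T = floor((t1 − t0)/dt)`
half-open slices (`dt` defaults to 60 s). Entry (t, i) of the observation
matrix is 1 when an event of sensor i overlaps slice t by at least one
second; sub-second residue at slice boundaries does not count. Each slice
takes the label of the activity with the greatest temporal overlap, ties
going to the interval that started earlier; slices no annotation touches
get the explicit idle class (index 1), which participates in training and
scoring like any other activity. A trailing partial slice is dropped.
Timestamps are treated as timezone-naive local time (handled internally
as UTC), and days run midnight to midnight.

Three binary encodings of the slice matrix are available. *Raw* passes
the matrix through. *Change point* marks slices where a sensor flips
state; the slice before the stream counts as all-zero, so a stream that
begins active registers a change at its first slice. *Last sensor* keeps
a 1 on the sensor(s) that changed most recently; when several change in
the same slice they all carry the 1, because sub-slice ordering is not
observable at slice granularity. Representations are combined by column
concatenation, giving the seven standalone/combined configurations.

## The generative baseline

With fully labelled data the Bernoulli-emission HMM has closed-form
estimators, implemented in `estimateSupervised()` with a Laplace
pseudocount `alpha` (default 1) so that no transition or emission
probability is exactly zero on a training fold. Each recording day is an
independent sequence: the initial distribution applies at each day's
first slice and no transition pair is counted across midnight. This
matches the leave-one-day-out protocol, where a held-out day must be
decodable without context from its neighbours.

All decoding is in log space. Probabilities are floored at 1e-12 before
logs, so even degenerate parameters (`mu` of exactly 0 or 1 meeting a
contradicting observation) yield large negative but finite scores, and a
Viterbi column can never be all `-Inf`. Viterbi ties break toward the
lowest state index, making decoding fully deterministic.

## The hybrid model

The naive-Bayes assumption of the Bernoulli model — sensors conditionally
independent given the activity — is clearly wrong for real homes (a
kitchen PIR and a fridge switch fire together). The hybrid model replaces
the generative observation term with a discriminative one: a classifier
trained on the slices outputs posteriors p(y|x), and Bayes' rule converts
them to emission scores. Since p(x) is constant across states within a
slice, the *scaled likelihood* p(y|x)/p(y) can stand in for p(x|y) in the
Viterbi recursion; the class priors p(y) are the label relative
frequencies of the training slices (floored and renormalized when a class
is absent). Two useful exact contracts follow from the algebra, and are
enforced by tests:

* with uniform priors, decoding scaled likelihoods equals decoding log
  posteriors;
* with uniform `pi`/`trans` (and uniform priors), the Viterbi path
  degenerates to the per-slice posterior argmax — i.e. the hybrid model
  with no temporal information *is* the static classifier.

### Emitters

The **MLP emitter** is a single-hidden-layer perceptron with softmax
outputs fitted by maximum conditional likelihood (equivalently, minimum
relative entropy) via `nnet`. The hidden layer defaults to twice the
feature count. Capacity control uses weight decay (default 0.1) rather
than early stopping on a holdout: decay is the regularizer `nnet`
supports natively, it serves the same role, and it keeps training fully
deterministic given the seed (no extra random holdout split). Optimizer
runs are capped at `maxIterations` (default 200).

The **SVM emitter** reduces the multiclass problem to binary subproblems
(one-vs-rest by default; one-vs-one with averaged pairwise coupling is
available) with an RBF kernel `exp(−|x−y|²/(2σ²))`. σ defaults to the
median heuristic on pairwise training distances (computed on a subsample
of at most 400 slices) and the soft-margin cost to 1. Decision values are
mapped to probabilities by a Platt sigmoid
`p(s) = 1/(1 + exp(−(a·s − b)))` — the two-parameter form, equivalent up
to reparameterization to the unit-slope variant sometimes written as
`1/(1 + A exp(−s + B))` — fitted with Platt's smoothed targets
`(N₊+1)/(N₊+2)` and `1/(N₋+2)` by BFGS on the regularized negative log
likelihood. To avoid optimistically steep sigmoids the calibration pool
is built from 3-fold cross-validated decision values (with an in-sample
fallback only if a subfold loses one of the two classes). Per-class
sigmoid outputs are floored at 1e-12 and row-normalized so posterior rows
sum to 1 exactly.

Both emitters expose posteriors over the *full* class set: classes never
seen in training receive floored (effectively zero) mass, which is what
the leave-one-day-out protocol needs when a rare activity occurs only in
the held-out day.

### Training loop

The default `trainOptions()` performs one supervised pass: estimate
`pi`/`trans` from the labels, fit the emitter once, take the priors from
the labels. With fully labelled data this is the well-defined reading of
hybrid training. An optional EM-like refinement (`realign = TRUE`)
re-decodes the training days with the current model, refits the emitter
on the decoded labels, and repeats until the decoded paths are unchanged
or `maxIterations` is reached; `reestimateChain` extends the refresh to
`pi`/`trans`. Realignment that collapses to a single class aborts with a
warning and keeps the pre-collapse model. On separable data the original
labels are already Viterbi-optimal, so realignment is a fixed point —
another tested contract.

## Evaluation machinery

`macroMetrics()` computes per-class precision TPᵢ/TIᵢ and recall TPᵢ/TTᵢ
from the confusion matrix, averages each over all Q classes, and forms
F = 2PR/(P+R) from the two aggregates (not the mean of per-class F
values). Empty denominators contribute 0 to the average *and the class
still counts in Q*; under heavy imbalance this choice visibly lowers the
averages, which is why it is stated prominently here and tested against
hand-computed matrices. `leaveOneDayOut()` trains on all-but-one day and
scores the held-out day, reporting per-fold metrics (summarised as
mean ± sd). `pairedTests()` runs the paired two-tailed t-test and the
Wilcoxon signed-ranks test on matched fold scores, dropping zero
differences for the signed ranks, reporting W = min(W⁺, W⁻), using the
exact null distribution for ≤ 25 tieless differences and the normal
approximation otherwise, and flagging the degenerate cases (all
differences zero → p = 1; zero-variance differences → reported as a
strong rejection with a flag).

## The simulator

`sampleHome()` generates the three synchronized views of a recording —
event stream, annotation intervals, ground-truth slices — from a
semi-Markov activity schedule: dwell in an activity is geometric in
slices with the configured mean (matching the first-order HMM's implicit
dwell distribution), and the next activity is drawn from hour-of-day
weights excluding the current one. Sensor bits are per-slice Bernoulli
draws given the activity, optionally corrupted by independent flips at
`noiseFlipProb` (spurious firings and missed activations). Draw order is
fixed (schedule, then firings, then noise), so output is a deterministic
function of the seed. An optional lognormal dwell mode generates data
that *violates* the HMM's geometric-dwell assumption, useful for
robustness studies.

The packaged default `smallHomeConfig()` describes 8 activities
(including idle) over 12 sensors for 14 days at Δt = 60 s, with dwell
times and routines chosen once for realism (7 h sleeping, long leaving
and leisure blocks, 10–30 min meals and hygiene) and firing profiles that
overlap across activities (breakfast and lunch share the same kitchen
sensors and differ mainly by hour). The resulting marginals show the
expected imbalance: a dominant class above 30% of slices and several
below 2%.

What the simulator does **not** emulate: multi-resident interleaving,
sensor dropout or failure, annotation noise, and long-range routine
drift. Passing tests on simulated homes therefore demonstrate that the
algorithms are implemented correctly and that the hybrid's advantage
materialises under persistence + noisy emissions; they do not certify
recognition rates on any real deployment.

## The replication study

The package's own directional experiment (`replicationStudy()`) asks the
question the hybrid design stakes its value on: does Viterbi decoding
over classifier posteriors beat the same classifier used per-slice? It
runs 20 independently seeded simulated homes under
`replicationConfig()` — 6 days at Δt = 300 s (288 slices/day), the
default 8-activity/12-sensor home, raw features, sensor noise
`noiseFlipProb = 0.05` — and evaluates four models leave-one-day-out,
fitting each emitter once per fold and decoding it twice (hybrid Viterbi
vs static argmax). The 300 s slices and 6-day span keep the full
20-replicate grid at a few minutes on one CPU while leaving every
activity multiple slices of dwell; the noise level is set where per-slice
classification is visibly degraded but not destroyed, which is the regime
the hybrid is designed for. The study reports mean macro F per model and
paired t/Wilcoxon p-values for the hybrid–static contrasts; the tested
claim is the ordering (hybrid ≥ static for both emitter kinds), not any
particular percentage.

## Numerical and degenerate-input conventions

* Probability floor 1e-12 before every log; posteriors floored then
  renormalized.
* Viterbi and static argmax ties → lowest class index.
* `alpha = 0` estimation with an unobserved class (or a class with no
  outgoing transitions) is an error naming the class, not a silent NaN.
* Platt calibration requires both classes; emitter training requires at
  least two observed classes.
* All-floored posterior rows (one-vs-rest SVM) fall back to uniform with
  a warning.
* Slice labelling ties → earlier interval start; events shorter than 1 s
  of overlap with a slice do not set its bit.

## Known limitations

* The transition structure is first-order and time-homogeneous; hour-of-
  day information influences the simulator but is not a model feature.
* The MLP's weight-decay default (0.1) is a capacity heuristic, not a
  tuned value; on very wide concatenated representations stronger decay
  or fewer hidden units may be appropriate.
* One-vs-one coupling uses simple averaged pairwise probabilities rather
  than an iterative coupling scheme.
* Hybrid model persistence stores the fitted emitter as an RDS payload
  next to the JSON parameter document; only the generative `HMMParams`
  round-trips through pure JSON.
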