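---
title: "Self-recalibrating neural decoding: model, simulator, and evaluation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-recalibrating neural decoding: model, simulator, and evaluation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmagrl)
```

## The problem

Intracortical brain-machine interfaces decode movement intent from chronic
multi-electrode recordings.  The statistical relationship between spike
counts and intent drifts from day to day — electrode micromotion, tissue
response, and neuronal variability all move the class-conditional feature
distributions — so a classifier calibrated yesterday loses accuracy today.
Daily supervised retraining restores it but requires labelled data the user
of a prosthesis cannot conveniently provide.  This package implements a
*self-recalibrating* decoder that keeps itself calibrated from nothing but a
scalar reward signal observed during use, plus the machinery to evaluate it:
a nonstationary session simulator, reference baselines, and repeated-run
benchmark protocols.

## The decoder

### Attention-gated reinforcement learning

The core classifier is a three-layer network.  For a trial with feature
vector $x$ (bias $x_0 = 1$):

$$\gamma_j = \frac{1}{1+e^{-h_j}}, \qquad h_j = \sum_{i=0}^{N} v_{ij} x_i,$$

$$P(Z_k = 1) = \frac{e^{a_k}}{\sum_{k'} e^{a_{k'}}}, \qquad
  a_k = \sum_{j=0}^{M} w_{jk}\gamma_j,$$

with $\gamma_0 = 1$ the hidden bias unit.  The decoder *samples* its action
from the softmax — only the winning unit $s$ takes activity 1.  A correct
action earns reward $r = 1$; the reward-prediction error is
$\delta = r - E(r)$ on rewarded trials and $\delta = -1$ on unrewarded
trials, passed through the expansive function

$$f(\delta) = \begin{cases}\delta/(1-\delta) & \delta \ge 0\\
  -1 & \delta = -1,\end{cases}$$

so that an unexpectedly rewarded low-probability action drives a large
update.  The Hebbian updates are

$$\Delta w_{jk} = \beta\,\gamma_j Z_k f(\delta), \qquad
  \Delta v_{ij} = \beta\, x_i \gamma_j f(\delta)\,[w_{js}(1-\gamma_j)],$$

where $w_{js}$, the feedback weight of the winning unit, gates hidden-layer
plasticity — the "attention" that assigns credit to the hidden units
responsible for the selected action.  Defaults follow the standard
configuration: $M = 30$ hidden units, $\beta = 0.01$, weights initialised
uniformly in $\pm 0.1$, $r = 1$.

Three choices here were genuinely open and are worth recording:

* **Expected reward.** $E(r)$ is taken to be $p_s$, the softmax probability
  of the selected action (times the reward value), which makes the rewarded
  and unrewarded branches of $\delta$ consistent and is the convention of
  the attention-gated RL literature.  With $r = 1$, $\delta = 1 - p_s$.
* **Bias units.** The sums above start at $i = 0$ / $j = 0$; we read these
  as learnable bias weights on clamped units $x_0 = \gamma_0 = 1$,
  initialised like all other weights.  The hidden bias unit has no incoming
  $v$ weights and therefore receives no attention-gated feedback.
* **Update order.** $\Delta v$ depends on $w_{js}$, so ordering is
  observable.  Both deltas are computed from the *pre-update* weights and
  applied simultaneously; the test suite pins this semantics against an
  independently written elementwise oracle.

Numerical safety: the softmax subtracts its maximum, the sigmoid is clamped
to $(10^{-12}, 1-10^{-12})$, and $\delta$ is clipped so that
$f(\delta) \le 99$ — without the cap a rewarded action with near-zero
probability would produce an unbounded update.  At the decoder's operating
point ($p_s$ rarely below $10^{-2}$) the cap is essentially never active.

### Unsupervised domain adaptation

Before initial training, TMAGRL projects the historical data onto the
leading principal components of their covariance, retaining 90% of the
variance ([fit_pda()]).  The *same* mean and eigenvectors — source
statistics only — are applied to every incoming test trial, so the map
never peeks at the target session; this is what makes the transfer usable
online, where target labels do not exist.  Two details are deliberate:

* **Centering.**  The projection is written as a bare matrix product in the
  original formulation, but retaining "90% of the variance" presupposes a
  centred covariance; we subtract the source mean from both source and test
  samples.  This is the one place we read the equations non-literally.
* **No whitening.**  Raw counts are projected without per-feature
  standardisation, since none is stated; eigenvector signs are fixed
  (largest-magnitude entry positive) so repeated fits are bit-identical.

### Confidence-gated training and online mini-batch recalibration

Initial training ([train_initial()]) visits the (projected) historical
trials in a fresh shuffled order each epoch.  A trial the decoder already
classifies with probability above $k = 0.9$ is skipped — its weights are
left untouched — which both accelerates training and prevents over-fitting
to already-mastered samples.  The model is convergent when 98% of training
trials clear the gate; otherwise training stops at 1000 epochs and returns
the best epoch's snapshot (highest training accuracy under
most-probable-class prediction, earliest epoch on ties).  The gate check
uses the current weights immediately before each trial inside the epoch,
and the convergence criterion is evaluated after each full epoch.

During online testing ([run_online()]) every tested trial enters a FIFO
buffer of the latest $J$ samples (default $J = 30$; all tested samples
while fewer than $J$ exist).  If the decoder predicted the current trial
confidently ($P(\text{true class}) > k$) nothing is updated.  Otherwise
mini-batch passes run over the buffer — each pass forwards all buffered
samples with the pass-entry weights, samples winners, and applies the
summed Hebbian update once — until 98% of the buffer clears the gate.  The
inner loop is capped at 50 passes per trial to bound per-trial latency; the
cap is a practical addition (the flow chart leaves the loop open) and the
trace records how many passes each trial used.  Winners are re-sampled from
the current softmax on every pass rather than replayed from the trial's
original prediction, reading the per-sample quantities in the batch update
as per-pass quantities.

With a buffer of one sample the batch pass reduces exactly to the
single-trial rule; the tests assert this reduction and the trial-by-trial
causality of the online trace.

### Baselines

* **static** — an RBF-kernel SVM (via e1071/LIBSVM, the implementation the
  field uses) grid-searched by 3-fold cross-validation on the historical
  day and then frozen.  Grids follow LIBSVM's documented coarse search
  ($C = 2^{-5..15}$, $\gamma = 2^{-15..3}$, step 2 in the exponent).
* **retrained** — the same classifier retrained per repeat on a random
  2/3 : 1/3 split of the *current* day (630 trials split 420 : 210 at the
  monkey-M-like size): the practical upper reference.
* **nagrel** — the AGREL network trained once on raw features, never
  adapted online.
* **agrel** — AGREL without the confidence gate, adapting after every
  trial with a full buffer of all tested samples and exactly one update
  pass per trial.  One pass is the faithful reading of "uses all tested
  data to update after each trial": without the gate there is no
  convergence test to terminate an inner loop, and a single pass gives the
  full-batch method its characteristic per-trial update cost, linear in
  the amount of tested data.

The five methods are pure configurations over the same machinery
([make_method()]); `agrel` and `tmagrl` differ only in basis presence,
buffer capacity, and gate flags, which the tests assert structurally.

## The simulator

Real chronic recordings of this kind are not publicly deposited, so the
package ships a generative stand-in ([simulate_series()]) that reproduces
the *structure* of the data: per trial, spike counts of `n_channels`
channels in six 50 ms bins of a 300 ms decoding window, three balanced
classes, ~630 trials per day (80 channels, 480 features, monkey-M-like) or
~360 trials (66 channels, 396 features, monkey-B-like), across consecutive
days.

Counts are Poisson: channel $c$ has a baseline rate drawn uniformly from
5-40 spikes/s and a randomly assigned preferred class whose rate is scaled
by $1 + g\,\mathrm{ramp}(b)$, a linear ramp over the six bins emulating a
peri-event rise (`tuning_gain` $g$).  Day-to-day nonstationarity applies,
per channel *and class*, an independent multiplicative log-normal gain
$e^{\mathcal N(0,\sigma^2)}$ with $\sigma = 0.15$/day (a random walk across
days), and silences each channel with probability 0.02/day.

Two calibration decisions matter and were validated by measurement rather
than assumed:

* **Per-(channel, class) drift.**  A gain drawn per channel only rescales
  all of a channel's classes together and leaves the class-conditional
  *structure* intact; measured on the full monkey-M-like scale, a frozen
  kernel classifier still scored ~99-100% on drifted days at any drift
  scale.  Tuning drift — independent gains per channel and class — is what
  produces the defining phenomenon: accuracy of frozen decoders degrades
  with day separation while a retrained decoder does not.
* **Modulation depth 0.2.**  With deep modulation the 480-feature margins
  are so wide that no realistic drift hurts any classifier.  At $g = 0.2$
  the frozen kernel baseline scores ~65-70% one day out and lower at
  larger separations while the retrained ceiling stays above 95% — the
  regime the real recordings occupy and the one in which recalibration is
  actually at stake.

What the simulator does *not* model: raw waveforms, spike sorting,
threshold crossing (its counts are post-detection), correlated noise across
channels, within-day drift, electrode replacement events, or behavioural
co-adaptation of the subject.  Passing benchmarks on this simulator
therefore demonstrates correct adaptation mechanics under controlled
tuning drift, not performance on any particular animal's recordings.

## Evaluation protocols

[run_experiment()] drives three designs: previous-day calibration (train
on day $t-1$, test day $t$), day-separation sweeps (last day tested
against every earlier training day), and batch-size sweeps
($J = 1, 30, 60, \dots$ on a fixed pair).  Train/test data are fixed per
cell; repeats re-draw network initialisation and all action-sampling
streams from seeds fanned out of one master seed, and accuracies are
summarised with percentile-bootstrap 95% intervals over the repeats
(1000 resamples; the resample count is unstated in the protocols we
follow, and bootstrapping over repeats rather than trials matches
"confidence intervals of the mean decoding accuracies").  Reports expose
the per-repeat values so any significance machinery can be applied
downstream; none is built in.

## Problem sizes used by the shipped tests and acceptance script

The package's own studies run at two scales, chosen once: the full
monkey-M-like scale (80 channels, 630-trial days) wherever the network
methods are compared — training and online adaptation are implemented in
compiled code and run in seconds — and a reduced scale (20 channels,
120-trial days, reduced SVM grids) for the SVM-heavy day-separation and
retraining protocols, whose grid searches at 630 x 480 take minutes per
cell and add nothing to the comparison beyond runtime.  The vignette-level
conclusions are unchanged across the two scales.

## Known limitations

* Labels of tested trials stand in for the reward signal (offline replay);
  a deployed system would derive reward from task success.
* The mini-batch is plain experience replay; prioritised replay is out of
  scope.
* Only 3-class discrete decoding is implemented — no continuous kinematics,
  no closed-loop co-adaptation, and no multi-hidden-layer variants.
* Wall-clock update-time comparisons between methods are hardware-bound
  and deliberately not part of the test suite; the trace's update-pass
  counts are the portable proxy.
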