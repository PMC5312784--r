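---
title: "Modelling instructed probabilistic reversal learning and its ERP correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling instructed probabilistic reversal learning and its ERP correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RevLearnEEG)
```

## The problem

In probabilistic reversal learning, a learner must infer which of two
stimulus-response mappings is currently correct from feedback that is only
probabilistically valid, and must detect occasional unannounced reversals of
the correct mapping. When blocks are preceded by verbal instructions -- "the
rules in this block will probably change" versus "will probably remain
stable", or "feedback will (not) be reliable" -- the instructions change what
the learner expects of the environment without changing the trial-by-trial
contingencies of the critical conditions. `RevLearnEEG` provides the full
computational machinery to study this situation in simulation: the task
generator, the learners, per-subject model fitting and comparison, the
behavioural measures, and the ERP quantification pipeline exercised on
synthetic EEG.

## Task designs

Two experiment families are built in (`experimentConfig()`, or the YAML files
under `extdata`):

* **exp1a / exp1b** -- volatility instructions. 36 (1a) or 27 (1b) blocks of
  25, 33 or 41 trials; reversals occur in 2/3 of volatility-instructed and
  1/3 of stability-instructed blocks, always at the block midpoint (trial 13,
  17 or 21). Feedback validity is 0.75 throughout. exp1b lengthens the
  response-feedback interval from 500 to 1200 ms so that the slow
  pre-feedback potential (SPN) can be measured.
* **exp2** -- reliability instructions. 32 blocks of 33 trials in four types:
  highly reliable feedback (0.875, instructed reliable), unreliable feedback
  (0.625, instructed unreliable), and two critical types with identical
  intermediate reliability (0.75) under either instruction. A reversal occurs
  in 3/4 of the blocks, equally often at trial 9, 17 or 25.

`buildSchedule()` counterbalances instruction x block length x reversal
status *exactly* -- counts, not sampling probabilities -- wherever the design
divides (it does for exp1a and exp2), and shuffles block order by seed. The
27 blocks of exp1b cannot be crossed exactly over 2 instructions x 3 lengths
x thirds; there the cell counts come from largest-remainder allocation under
the schedule seed. Blocks without a reversal carry a nominal midpoint so that
"first half" and "second half" are defined for every block and matched-trial
comparisons use equal trial counts.

Two design decisions are not stated in the underlying task descriptions and
are our own: the stimulus sequence within a block is pseudo-random subject
only to each stimulus appearing on half the trials (rounded up/down), and
missed responses are not modelled -- simulated agents always respond, since
no analysis in scope uses missed trials.

## The learners

### Bayesian hidden-Markov observer with entropy-aversion switching

The observer tracks the probability `p` that the mapping it is currently
applying is the correct one, as a two-state hidden-Markov filter:

1. **Transition.** Before each response, `p <- p(1-h) + (1-p)h`, where the
   hazard `h` is the assumed per-trial reversal probability. Default
   `h = 0.03`, roughly one reversal per 33-trial block; it is shared across
   instructions because the instruction manipulation is modelled as acting
   on uncertainty aversion, not on the assumed hazard.
2. **Update.** After feedback, Bayes' rule with assumed reliability `rho`
   (default 0.75, the experienced contingency):
   `P(positive | correct) = P(negative | incorrect) = rho`. The update also
   yields the surprise `I = -log2` of the predictive probability of the
   outcome, and the entropy `H(p)` of the posterior (bits). The belief is
   reset to 0.5 at every block start, since each block brings new stimuli.
3. **Decision.** The observer abandons its mapping iff `p < 0.5` *and*
   `H(p) <= alpha`, where `alpha` (bits) is the entropy-aversion threshold.
   Informal statements of entropy-threshold switch rules ("switch when the
   threshold is crossed") leave the direction of the comparison ambiguous;
   we fix the direction under which larger `alpha` produces *earlier*
   switching, because that is the only reading consistent with the joint
   pattern this model family is meant to capture -- greater uncertainty
   aversion under volatility instructions *and* faster adaptation there.
   Transition structure, the treatment of `rho` and the threshold
   comparison are defined here as one internally consistent model; the
   package's definition is authoritative for everything it computes.

The **instruction-blind** variant uses a single `alpha` everywhere; the
**instruction-sensitive** variant selects `alpha` by the block's instruction
(one extra free parameter per additional instruction). Responses lapse with
probability `epsilon` (applied mapping flipped); after a lapse the belief is
re-referenced to the mapping actually applied, and the fitting replay treats
observed choices the same way, so generation and fitting are exactly
consistent. Surprise `I` is logged but does not enter the decision rule.

A brute-force path-enumeration filter over the two-state chain verifies the
recursive belief to 1e-12 in the test suite.

### Model-free learner

The Rescorla-Wagner learner used for the prediction-error control analysis
keeps one value per mapping (initialised at 0.5), updates only the chosen
mapping with learning rate `eta = 0.5`, and codes rewards positive = 1 /
negative = 0. `meanNegativeRpe()` averages the signed negative prediction
errors over pre-reversal rule-correct trials per instruction; because the
learner is instruction-blind, matched feedback streams give identical means
across instructions -- the null this control is meant to establish.

## Fitting and model comparison

The natural goodness-of-fit summary for a deterministic threshold model is
"percent correctly predicted trials", but BIC requires a likelihood. We
therefore attach a lapse-Bernoulli response model: each trial contributes `log(1-epsilon)` when
the observer's deterministic prediction matches the observed choice and
`log(epsilon)` otherwise. `epsilon` is a shared nuisance parameter counted
identically in both variants, so BIC differences reflect only the `alpha`
structure. The first trial of each block, where the prior is uninformative,
is predicted as the observed choice (equivalently, excluded from the
mismatch count).

`fitAlpha()` maximises this likelihood by exhaustive grid search over
`alpha` in steps of 0.01 on `[0, 1]` -- exhaustive because a binary entropy
cannot exceed 1 bit -- profiling `epsilon` analytically as the observed
mismatch rate clipped to `[0.01, 0.49]`, with ties broken toward the
smallest `alpha`. Because the belief replay conditions only on the observed
choices and feedback, the per-trial `(p, H)` pair is computed once and every
grid value is evaluated by thresholding; for the instruction-sensitive
variant the joint grid over `(alpha_v, alpha_s)` decomposes over
instructions since blocks are independent. This is the same estimator as the
literal 101 x 101 search, computed exactly.

`compareModels()` sums per-subject BIC differences (a fixed-effects
comparison) and reports a verdict on the conventional evidence bands
(differences of 2 / 6 / 10 as positive / strong / very strong). The
grid-with-smallest-tie-break estimator is slightly conservative for `alpha`
(it returns the lower edge of the maximum-likelihood interval); parameter
recovery at the reported group means (alpha_v = 0.7, alpha_s = 0.52, lapse
0.05, 28 subjects on the exp1a design) recovers group means within +-0.1 and
reproduces the alpha_v > alpha_s group difference, as the acceptance tests
check.

## Behavioural measures

`behaviourSummary()` computes, per subject x instruction: pre-reversal
accuracy (first halves of all blocks), post-reversal accuracy (second halves
of reversal blocks), trials-to-repetition -- the index of the second trial of
the first pair of consecutive rule-correct trials, from block start or from
the reversal -- the probability of switching mappings on the trial after a
surprising negative feedback (negative feedback on a rule-correct trial,
successor within the same block), and the pre-reversal negative-feedback
rate. Blocks where the correct rule is never repeated are excluded from
trials-to-repetition means and counted in `ttr_excluded` rather than
imputed. "Surprising negative feedback" is deliberately restricted to
rule-correct trials, i.e. to invalid feedback. Paired t-tests are two-tailed
at alpha = 0.05, Cohen's d for paired data uses the standard deviation of
the differences, and the 2 x 2 repeated-measures ANOVA uses standard
`aov()` error strata.

Under the generating conditions above, the simulated pattern mirrors the
qualitative findings: near-equal pre-reversal accuracy, higher post-reversal
accuracy and fewer trials-to-repetition under volatility instructions, and a
higher switch propensity. The switch-propensity contrast is a small effect
in this regime (about 0.072 vs 0.067); the acceptance test therefore runs it
on an 84-subject (~3000 block) simulation and asserts one-sided significance
for the two adaptation contrasts and the sign of the switch-propensity
difference.

## ERP quantification

`EpochSet` holds channels x samples x trials voltages (microvolts) with the
32-channel montage, time axis, locking event and per-trial labels; the
canonical disk form is a flat binary array plus a YAML sidecar and a TSV
label table. Preprocessing follows the standard contract: trials with a
within-epoch peak-to-peak range above 100 microvolts on any scalp channel
are discarded (count logged), data are decimated to 250 Hz, and a zero-phase
Hamming-window FIR band-pass (0.1-24 Hz; 0.05 Hz on the SPN path) is
applied. On 2-second epochs the realised high-pass edge is nominal -- the
filter order (128 taps at 250 Hz, capped by epoch length) cannot realise a
0.1 Hz transition -- while the low-pass contract is tested: 50 Hz activity
is attenuated below 1 percent. Baseline correction subtracts the per-channel
mean over -200..-100 ms (feedback-locked) or +200..+300 ms after the
response (SPN path).

Component measures operate on cluster- and condition-averaged waveforms,
averaging per subject before any group statistic:

* **FRN**: mean of the two flanking positive peaks (160-220 ms and
  300-420 ms) minus the trough (minimum in 240-280 ms). If a peak falls on
  a window edge, that edge -- and only that edge -- widens outward one
  sample (4 ms) at a time until the maximum is interior, never entering the
  trough window, with hard bounds at 0 and 800 ms. "Gradual widening" of
  peak windows admits several mechanics; one-edge-outward is the minimal
  deterministic one, it provably terminates, the windows actually used are
  reported, and the simple trough-minus-preceding-peak variant is available
  as an option.
* **SPN**: mean amplitude in -600..-400, -400..-200 and -200..0 ms before
  feedback over the left / central / right columns of the
  FC3-C3-CP3 / FCZ-CZ-CPZ / FC4-C4-CP4 cluster, the cells of the
  INSTRUCTION x TIME x LATERALITY analysis.
* **P3**: maximum 300-420 ms over CP3, CPZ, CP4, P3, PZ, P4, POZ;
  `p3ByNextTrialBehaviour()` additionally splits negative-feedback
  first-half trials by whether the *next* trial repeats or reverses the
  mapping (block-final trials have no successor and are excluded).
* **P1 / N1**: maximum 60-100 ms and minimum 140-200 ms over the parietal
  cluster P7, P3, PZ, P4, P8, POZ, O1, OZ, O2.

## The synthetic EEG generator

`generateEpochs()` builds each trial's epoch as a sum of raised-cosine
component templates (P1, N1, a pre-FRN positivity, FRN, P3) scaled by
per-trial amplitudes -- template base plus additive condition offsets keyed
to trial-log columns -- projected through fixed channel topographies, plus
white or 1/f noise. Raised cosines have compact support and analytic
extrema, and the default latencies sit on the 250 Hz sample grid with
non-overlapping supports at each latency, so every quantification window has
a closed-form oracle and noise-free measurements are exact to float
precision. The per-trial ground-truth amplitudes are emitted alongside the
data (`amp_*` columns) for injection-recovery testing.
`generateSpnEpochs()` produces response-locked epochs with a linear negative
ramp from 400 ms post response to feedback onset at 1200 ms, right-weighted
across the SPN cluster so the laterality gradient exists by construction.

What this generator emulates is the *statistical structure the analyses
assume* -- condition-dependent amplitude offsets on named components over
named clusters, plus stationary additive noise. It does not emulate real
EEG: no ocular artifacts, no channel drift or bad channels, no
trial-to-trial latency jitter, no biophysical forward model. Passing the
injection-recovery suite therefore demonstrates the correctness of the
measurement pipeline, not its robustness to the pathologies of real
recordings (eye-blink correction on real data, for instance, is a
pass-through here by design).

## Numerical choices and problem sizes

Entropy uses the convention `0 log 0 = 0`; a feedback with predictive
probability zero (possible only at `rho = 1` with an already-certain
belief) raises an error rather than returning infinity. All simulations
derive independent sub-stream seeds per component (schedule, feedback,
agent, noise) from one master seed, so feedback streams are reproducible and
matched across agents. The test suite's simulation scales -- 28 subjects for
parameter recovery (a typical sample size for this paradigm), 84 subjects for the
behavioural directional tests, 10^4-10^5 draws for contingency checks at
3-sigma binomial tolerance, 200 trials per cell for noisy
injection-recovery -- were chosen as the smallest sizes at which the checked
effects are stable across seeds.

## Known limitations

The hazard and assumed reliability are fixed by design defaults, not fitted;
softmax decision rules and volatility-learning models are out of scope, as
are reaction times, missed trials and monetary payoffs. The BIC comparison
is fixed-effects. The exp1b counterbalancing is approximate (above). Human
effect sizes -- accuracy percentages, microvolt amplitudes of real grand
averages -- are not reproduction targets anywhere in the package: all
quantitative checks run against the package's own generative models and
closed-form oracles.
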