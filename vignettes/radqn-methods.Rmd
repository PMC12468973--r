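---
title: "Reward-driven classification of radiomics tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-driven classification of radiomics tables: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radqn)
```

## The problem

Glioma grading (low- vs high-grade, LGG/HGG) and overall-survival
stratification (short 0–250 days, medium 251–500, long 501–1800) are
routinely attacked with radiomics: a segmented tumor region is summarized
into ~10^2 quantitative features per MRI modality (shape, first-order
intensity statistics, and the GLCM/GLDM/GLRLM/GLSZM/NGTDM texture
families; the packaged manifest carries 105 such features in seven
categories). Two methodological problems dominate: the feature space is
redundant and much larger than informative, and the cohorts are small and
imbalanced, with augmented copies of the same patient threatening to leak
across train/test boundaries.

`radqn` implements a pipeline for this setting with two unusual
ingredients:

1. **Wrapper feature selection by an ensemble of binary metaheuristics**
   (Harris Hawks, modified Gorilla Troops, Zebra), majority-voted and then
   refined by exact Shapley importances under a cumulative-share rule.
2. **Classification cast as an episodic reinforcement-learning task**: one
   state per sample, the action is the predicted class, reward is +1/-1,
   and a dueling deep Q-network with a context-attention fusion head is
   trained by experience replay.

## Feature selection

### Wrapper fitness

A candidate feature subset is scored by the stratified cross-validated
error `1 - accuracy` of a linear classifier restricted to that subset,
computed strictly within the training data handed to the optimizer. The
empty subset is penalized with error exactly 1. Two implementation
decisions matter:

* **The linear classifier** is an L2-regularized least-squares classifier
  on +1/-1 targets (one-vs-rest beyond two classes), i.e. an LS-SVM-style
  linear max-margin surrogate. No SVM implementation is available in the
  supported dependency set, and a closed-form solve is two to three orders
  of magnitude faster inside the wrapper loop — population x iterations x
  folds evaluations — than an iterative solver, with no loss of fidelity
  for a *linear* fitness surrogate. The ridge penalty defaults to
  `lambda = 1`.
* **Fitness CV folds default to 3**, assigned by deterministic
  round-robin within each class, so the fitness is a pure function of the
  mask and the table: optimizer convergence traces are exactly
  reproducible and never confounded by fold resampling noise. The outer
  evaluation protocol (5-fold, below) is independent of this inner loop.

### The three optimizers

The published configuration fixes population 20, 50 iterations, 10
seeded runs, a binary search space over the features, and the
`1 - accuracy` objective; it does not fix the optimizers' update
equations, which we take from their source algorithms:

* **HHO**: perch-based exploration while the prey's escape energy
  `E = 2 E0 (1 - t/T)` satisfies `|E| >= 1`; soft and hard besiege and
  Levy-flight rapid dives below that.
* **GTO**: migration / follow-a-member / combined exploration, then
  follow-the-silverback or adult-competition exploitation, switched by the
  control parameter `C`. As the "modified" refinement we replace the
  linear decay of `C` with a cosine decay, which holds exploration longer
  early and sharpens exploitation late.
* **ZOA**: foraging toward the pioneer (population best), then a defense
  phase that either performs a small local escape shrinking over time or
  converges on a randomly attacked herd member.

All three operate on the continuous relaxation `[0,1]^d`, clamped after
every move. A logistic transfer centered at 0.5 maps positions to masks;
selection requires the transferred value to *strictly* exceed the 0.5
threshold, so a coordinate at exactly 0.5 deselects. Proposals are
accepted greedily (only on strict fitness improvement) and the global best
is retained, so best-so-far traces are nonincreasing by construction —
the property the convergence-curve displays rely on.

### Ensemble vote and Shapley refinement

Features selected by at least 2 of the 3 best masks enter the ensemble
mask. The linear classifier is refit on the ensemble features and exact
linear Shapley values are computed in closed form,
`phi_ij = w_j (x_ij - mean_j)` on the standardized scale, with
per-feature importance `mean_i |phi_ij|`. Features are taken in
descending importance until their cumulative share first reaches
`theta = 0.9`, *inclusive* of the crossing feature; importance ties break
by original feature order. Both the inclusive crossing and the tie rule
are our conventions (the source protocol is silent); the exact linear
Shapley form is preferred over a sampling approximation because it makes
the refinement deterministic and unit-testable against hand-computed
values.

Selection is designed to run inside each training fold; a
whole-training-set convenience mode reproduces global feature-count
summaries.

## The reinforcement-learning formulation

Each episode traverses the full table once (order reshuffled per episode
under a seeded stream — the protocol does not fix an order, and shuffling
decorrelates replay without changing semantics). The state is the
sample's feature vector, the action the predicted class (2 grading / 3
survival actions), the reward +1 or -1. Episode accuracy is
`(sum(rewards) + n) / 2n`. The transition is action-independent; the
terminal "next state" is a zero vector whose Q-values are never used,
because targets at terminals are the bare reward.

### Architecture family

Six variants form the ablation lattice: plain DQN, double DQN, dueling,
dueling double, dueling double with a trunk attention gate, and the final
context-attention model. All share a trunk of two hidden layers of 64
rectified units (the source gives no widths; 64 is ample for <= 120-dim
radiomics vectors and fast on one CPU). On top of the trunk:

* dueling variants: `Q = V + A - mean(A)`;
* the gated ablation multiplies the trunk representation by a scalar
  sigmoid gate before the dueling heads (the ablation's attention is not
  further specified; we flag this interpretation explicitly);
* the final model computes a scalar sigmoid fusion weight `w(s)` from the
  trunk's last hidden representation and fuses
  `Q = w V + (1 - w)(A - mean(A))`, a convex combination that makes
  `mean_a Q(s,a) = w(s) V(s)` an exact identity (tested numerically).
  Note the `w = 1/2` slice of this family is *not* the plain dueling
  composition (the global scale differs); no compensation is applied.

Double-DQN targets (target network evaluated at the online argmax) are
the default for the double/attention variants, including the final model —
the ablation ordering implies the final model retains the double
extension even though the printed update rule shows the plain max; the
flag is configurable.

### Training loop and defaults

Defaults follow the published configuration: discount 0.99, epsilon from
0.5 to a floor of 0.01 with decay 0.995, 50 episodes, batch 16, Adam at
0.001, MSE loss on the taken actions' Q-values. Our additional choices:

* **Epsilon decays per environment step**, not per episode. With 50
  episodes a per-episode decay reaches at most `0.5 * 0.995^50 ≈ 0.39`,
  leaving the 0.01 floor unreachable and that printed parameter vacuous;
  per-step decay honors all three exploration constants. Per-episode mode
  remains selectable.
* Target sync every 100 environment steps ("periodically" made
  concrete); replay capacity 10,000; learning starts once the buffer
  holds one full batch; replay sampling is uniform without replacement
  within a batch; argmax ties resolve to the lowest action index.
* All randomness — initialization, exploration, replay sampling, episode
  shuffles — derives from one seed hierarchy, so training is reproducible
  up to floating-point associativity.

The forward/backward passes and the Adam update are explicit matrix
algebra, verified against central finite differences for every variant in
the test suite.

## Leakage control

Augmented copies of a sample share its `group_id`. Both the 80/20
holdout and the k-fold assignment are group-atomic and class-stratified.
The holdout computes per-class train targets by largest remainder so that
cohorts whose `fraction * n` is integral split exactly (595 -> 476/119,
705 -> 564/141 with singleton groups); with multi-sample groups the split
is as close as atomicity allows, which can shift counts by a group's
size (e.g. 477/118 when the minority class comes in groups of four).
Normalization statistics are fit on training data and applied to held-out
data; per-fold selection sees fold-training data only.

## The synthetic cohort generator

The generator emulates the *structure* of the motivating cohort, not the
marginal distributions of real texture features: a 105-feature namespace;
grading imbalance 76 vs 293 (the augmented HGG count 291 printed in the
source differs unexplained from the 293 originals, so the count is a
parameter, not a rule); survival classes 75/86/74 over the three day
bands with uniform days within each band and a Normal(60, 12) age;
augmentation as label- and group-preserving Gaussian feature jitter
(default sd 0.1 x feature sd) at the published multiplicities (3 extra
copies take 76 to 304; 2 take 235 to 705 with class totals 225/258/222 —
neither multiplicity is printed, both are forced by the counts and
exposed as parameters). Informative features receive class-ordered mean
shifts (monotone across survival classes) of `effect_size` standard
deviations.

A green test on this generator establishes that the pipeline's logic is
correct under planted signal; it does not establish performance on real
radiomics, whose features are heavy-tailed, blockwise-correlated and
scanner-dependent.

### Calibration of the recovery scenario

The planted-recovery guarantee (the refined mask retains >= 80% of 5
informative features among 40 at effect size 3) needs the wrapper error
to discriminate between masks missing different planted features. With
small cohorts (~40 per class) random half-masks already reach CV error 0
and the optimizers stall on arbitrary subsets of the signal; the test
scenario therefore uses 120 samples per class and a 5-fold fitness, where
the error granularity (1/240) still resolves the gain from the fourth and
fifth informative features. This cohort size is comparable to the
motivating dataset (369 patients) and was fixed from this granularity
argument, not tuned against the test.

## Numerical edge cases

* Zero-spread features standardize to 0 rather than NaN.
* The sigmoid fusion weight is clamped to `[1e-7, 1 - 1e-7]`: in double
  precision the sigmoid saturates to exactly 1.0 beyond |z| ~ 37, which
  would violate the convex-combination contract.
* The all-zero mask short-circuits to fitness 1.0 before any fit.
* `cumulative_select` uses a `1e-12` slack on the threshold comparison so
  exact-fraction shares (e.g. ten equal shares at theta 0.9) include
  exactly the crossing feature.
* McNemar's test switches to the exact two-sided binomial tail below 25
  discordant pairs; with no discordant pairs it returns statistic 0,
  p = 1.
* Q-values map to probabilities by a temperature-1 softmax for Brier and
  ROC/PR summaries; this is a reporting convention, not a calibration
  claim.

## Known limitations

* The wrapper fitness classifier is linear; nonlinear class boundaries
  will under-rate feature subsets (the Shapley refinement inherits the
  same surrogate). A model-agnostic importance sampler behind the same
  interface would lift this at the cost of determinism.
* Training the agent is CPU-bound R; at the published scale (hundreds of
  samples, 50 episodes) it runs in minutes, but the implementation does
  not target GPU-scale problems.
* The discount factor 0.99 couples consecutive, unrelated patients
  through the TD bootstrap; we implement the protocol as specified and do
  not attempt to justify it — with episode-terminal gating the effect on
  the greedy policy is small in practice.
* Headline accuracies reported for the motivating BraTS cohort depend on
  that external dataset and are out of scope here; nothing in this
  package asserts them.
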