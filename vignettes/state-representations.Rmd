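---
title: "State representations in an odor-guided choice task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State representations in an odor-guided choice task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staterep)
```

This vignette documents the modeling assumptions, the task generator, the
inference machinery and the scripted simulation studies in `staterep`, with
the rationale for each design decision.

## The task

An animal samples one of three odors at a central port and responds at a left
or right fluid well. Two odors *force* the corresponding side (responding at
the other well is unrewarded); the third leaves the choice *free*. Each
session has four blocks. In blocks 1–2 the two sides deliver one reward drop
each but differ in delay: the short side delivers after 0.5 s, the long side
after an adaptively staircased 1–7 s. In blocks 3–4 both sides deliver after
0.5 s but differ in magnitude (two drops versus one). The better side
alternates at every block boundary without any cue, and block 3 reverts to the
block-1 better side, so the animal faces three reversals per session.

`session_config()` holds the generator settings. Block lengths are drawn from
a rounded Normal with mean 70 and SD 14 trials, resampled below a floor of 20
so a block always spans several reversals' worth of learning. Odors are
scheduled in 20-trial windows with exactly 7 free trials each; the 13 forced
trials split 7/6 with the majority side alternating between windows, keeping
forced experience balanced.

The long delay follows a weighted up/down staircase targeting 50% long-side
choice: choosing the long side lengthens the delay by
`2 * step * (1 - target)` and choosing the short side shortens it by
`2 * step * target`, clamped to [1, 7] s. Only free choices in delay blocks
move it, because forced trials carry no preference information. With
`target = 0.5` the two step sizes are equal and the staircase equilibrates
where the animal is indifferent.

```{r}
cfg <- session_config()
sched <- build_session_schedule(cfg, seed = 1)
sched$blocks
```

## The models

All four models are Rescorla–Wagner learners over a small set of states,
differing only in which states they carve the task into. After a trial in
state $s$ with $r$ reward drops delivered after delay $d$ seconds,

$$V(s) \leftarrow V(s) + \eta\,(\gamma^{d} r - V(s)),$$

so delays discount reward value per second and unrewarded (invalid) responses
drive the experienced state toward zero. Choices mix a softmax over decision
variables with a lapse:

$$DV(a) = V(s_a) + b\,[a = \text{right}] + p\,[a = a_{\text{prev}}], \qquad
P(\text{left}) = (1 - \lambda)\,\sigma\!\big(\beta\,(DV_L - DV_R)\big) + \lambda/2.$$

* **four_state** — states are the chosen side plus whether the response could
  be rewarded: Left, Right, Left-NoRwd, Right-NoRwd. Forced and free trials
  ending at the same well share a value, so forced-trial learning transfers
  fully to free choices.
* **six_state** — states are odor × action, so forced and free experience are
  fully segregated and nothing learned on forced trials moves free-choice
  values.
* **hybrid_value** — both tables are updated in parallel and the decision
  variable is the weighted sum $w_4 V_4 + (1 - w_4) V_6$. At $w_4 = 0$ it is
  exactly the six-state model, at $w_4 = 1$ exactly the four-state model.
* **hybrid_learning** — a six-state learner with a generalization rate
  $\eta_g \le \eta$: a rewarded valid response also nudges the paired
  same-side state (free ↔ valid forced) toward the outcome. At $\eta_g = 0$
  it is the six-state model; at $\eta_g = \eta$ it reproduces four-state
  behavior exactly.

The nested limits are exact, not approximate, and the test suite asserts them
to machine precision; they anchor the fitting code because any numerical
discrepancy between the hybrid and pure implementations would break them.

Parameter defaults in `model_params()` (`eta = 0.25`, `gamma = 0.8`,
`beta = 3`, `bias = persev = lapse = 0`) are mid-range values that make
demonstration agents learn within a block without saturating; every analysis
that depends on parameter values takes them explicitly.

Two implementations exist: a readable R reference path
(`state_value_table()`, `trial_step()`, ...) used in tests and documentation,
and a compiled core used by the simulator and all fitting. Both consume the
same RNG stream one uniform per trial, so matched agents under nested
parameterizations reproduce each other's sessions exactly.

## Inference

`session_loglik()` replays a model through a recorded log (values reset at
each animal/session boundary unless `carry_over = TRUE`) and returns
per-trial choice probabilities.

**Per-animal MLE.** `fit_mle()` maximizes each animal's likelihood by
L-BFGS-B on transformed parameters — logit for [0, 1]-bounded parameters, log
for `beta`, identity for `bias` and `persev` — with random multistart. The
hybrid-learning model is fit through `rho = eta_g / eta` so the constraint
`eta_g <= eta` holds by construction. Non-finite objective values at extreme
parameters are replaced by a large finite penalty so the bounded optimizer
never aborts, and a deterministic neutral start backs up the random restarts.

**Hierarchical Bayes.** `fit_hierarchical()` places independent Normal group
distributions on each transformed parameter across animals, with conjugate
hyperpriors `mu ~ N(0, tau0^2)` (`tau0 = 2`, weakly informative on logit/log
scales) and `sigma^2 ~ Inv-Gamma(a0 = 1, b0 = 0.02)`. The small `b0` matters:
it lets the group variance collapse toward zero when animals genuinely agree,
which is what produces shrinkage and tight group-mean intervals; a heavier
prior mass on large variances was observed to inflate group-level intervals
several-fold on synthetic data with known homogeneity. Because the likelihood
is a recursive function of the whole choice history, it cannot be expressed
in a graphical-model language, so sampling uses a purpose-built adaptive
Metropolis-within-Gibbs scheme: joint random-walk proposals per animal,
scaled by the current group SD and a per-animal step size adapted during
warmup toward 25% acceptance (Robbins–Monro decay), with exact conjugate
Gibbs updates for the group means and variances. Chains initialize at a cheap
per-animal MLE plus chain-specific jitter. Split-$\widehat R$ and acceptance
rates are reported, and $\widehat R > 1.1$ raises a warning. Reference
settings are 4 chains × 2000 iterations with 1500 warmup; the desk-scale
studies below use smaller, stated settings.

**Model comparison.** For hierarchical fits `compute_waic()` implements WAIC
from the pointwise posterior log-likelihood (`lppd` via stable
log-mean-exp, `p_waic` as the summed posterior variance). MLE fits carry an
AIC-style surrogate — per-trial `-2 ll + 2k/n` — in the same pointwise slot,
clearly labeled in printouts; it supports the same paired comparison
machinery but is not a posterior quantity. `compare_models()` refuses fits
on non-identical trial sets and reports paired difference standard errors
`sqrt(n) * sd(delta_i)` rather than the much larger standard errors of the
individual criteria.

## Behavioral analyses

Two analyses are deliberately model-free, so they can adjudicate between the
representations without fitting them.

`extract_generalization_cases()` scans each session for an incorrect free
choice, counts the rewarded forced trials until the next free choice, and
records whether that next free choice was correct. Under a shared
representation those forced rewards should raise free-choice accuracy; under
a segregated one they should not. `fit_generalization_regression()` fits a
hierarchical logistic regression of the outcome on the forced-reward count
(optionally also the within-block trial index, to guard against recovery over
time masquerading as generalization), using the same
Metropolis-within-Gibbs machinery, with an `lme4::glmer` fallback.

`compute_learning_curves()` aligns accuracy to block transitions (last 10 and
first 10 trials), averaging within animal before averaging across animals so
animals with more sessions do not dominate, and keeping empty cells `NA`
rather than zero.

## Scripted studies

All studies record every seed they consume in their output, and re-running
with the manifest seeds reproduces the tables exactly.

* `recovery_study()` draws a population of agents (defaults:
  `eta ~ U(0.1, 0.5)`, `gamma ~ U(0.6, 0.95)`, `beta ~ U(1, 5)`,
  `bias, persev ~ N(0, 0.3)`, `lapse ~ U(0, 0.1)`, `w4, rho ~ U(0.1, 0.9)` —
  ranges where the task is informative), simulates, refits, and reports
  per-parameter true-versus-recovered correlation and bias. At 20 animals ×
  20 sessions all headline parameters recover with correlation above 0.85.
* `identifiability_matrix()` simulates from each generator, fits every
  candidate, and tabulates which model wins by WAIC — a confusion matrix
  whose rows should be near-diagonal at usable data sizes (they are perfect
  at 20 replicates × 30 sessions).
* `reward_vs_w4()` sweeps the hybrid-value weight over a grid with a common
  seed per grid point, so the endpoints reproduce the pure-model simulations
  exactly. The shared representation speeds post-reversal relearning but
  adds only a few percent mean reward, because forced trials already steer
  the animal to both wells.
* `split_half_analysis()` splits each animal's sessions chronologically,
  refits both halves, and correlates the change in fitted `w4` with the
  change in the model-comparison margin.

## What the synthetic data can and cannot show

Every quantitative claim in this package is about the generative models and
the estimators, verified on data simulated from known ground truth: that the
likelihood is correct (hand-worked oracle), that the nested limits are exact,
that parameters and generating models are recoverable at stated data sizes,
and that the behavioral signatures (generalization regression, post-reversal
curves) separate the representations. Synthetic agents cannot show which
representation real animals use, and none of the defaults should be read as
empirical estimates.

## Limitations and open decisions

Several modeling choices are underdetermined and were resolved as follows:

* The lapse rate $\lambda$ is a model parameter fit by default;
  `fit_lapse = FALSE` freezes it at a supplied constant, supporting both
  readings of its status.
* Values do not carry over between sessions by default (`carry_over = FALSE`
  everywhere); the alternative is available but untested against any claim.
* In the four-state model an invalid (unrewarded) forced response updates the
  corresponding NoRwd state toward zero, mirroring the valid-trial rule
  rather than skipping the update.
* The hybrid-value model shares a single $\eta$ and $\gamma$ across its two
  tables; fitting them separately would break the exact nested limits that
  the implementation is verified against.
* Odor-port timing and trial omissions are not modeled: every scheduled trial
  yields a choice, because the models are fit to choices only.
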