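---
title: "Structure learning in two-armed bandits: models, solvers and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure learning in two-armed bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(structbandit)
```

## The problem

In a two-armed Bernoulli bandit, how much an agent should explore depends on
something it typically does not know: how the two options' rewards are
generated. If the options are *independent* — each with its own fixed success
probability — information about one option says nothing about the other, and
exploration has genuine long-run value. If the options are *coupled* — a
single latent success probability drives both, so that when one option pays
the other would not have — then every pull is fully informative about both
options, exploration is superfluous, and the greedy choice is optimal. An
agent that must *learn which of these worlds it is in* will take actions that
look like over- or under-exploration to an observer who assumes either world
is known.

This package implements that account end to end: the Bayesian belief
machinery, the optimal policies under fixed and uncertain structure, a
model-free Q-learning baseline, a simulator of the block/task/trial
experimental design, and the trial-level analyses used to compare the models
against recorded choices.

## Belief state and inference

Within a task, everything the agent knows is captured by the counts
$(s_1, f_1, s_2, f_2)$ of successes and failures per option together with
the priors. Under the independent model each option $i$ carries a
$\mathrm{Beta}(a_i, b_i)$ prior; under the coupled model a single
$\mathrm{Beta}(a_0, b_0)$ prior governs the shared parameter, with option-1
successes and option-2 failures counting toward it and the remaining counts
toward its complement. A Bernoulli prior $\kappa_0$ governs which structure
is in force.

The coupling posterior is the posterior odds

$$
\frac{P(\text{coupled}\mid D)}{P(\text{indep}\mid D)} =
\frac{\kappa_0}{1-\kappa_0}\,
\frac{B(a_0+s_1+f_2,\; b_0+f_1+s_2)/B(a_0,b_0)}
     {\frac{B(a_1+s_1, b_1+f_1)}{B(a_1,b_1)}\,
      \frac{B(a_2+s_2, b_2+f_2)}{B(a_2,b_2)}},
$$

mapped through the logistic function. The predictive reward of an action is
the structure-weighted mixture of the two posterior means
(`predictive_reward()`); under certain coupling the two actions' predictions
sum to one exactly.

**Numerical choices.** All Beta-function ratios are computed as log-gamma
differences and the odds are assembled in log space before the logistic map:
counts of a few hundred would overflow direct Beta evaluation. Degenerate
priors ($\kappa_0 \in \{0,1\}$) short-circuit to the fixed-structure models
so that $\log 0$ never arises.

**Belief reset protocol.** Arm counts reset to the priors at every task
boundary. The coupling posterior is carried forward as the next task's
coupling prior *within* a block, and resets to the configured $\kappa_0$ at
block boundaries, because blocks are distinct environments in the design.

## Policies

Three Bayesian policies share the belief state:

* **Fixed independent** (`independent_policy()`): each option is scored by
  the Gittins index of its own Beta posterior — the calibration reward
  $\lambda$ at which retiring to a sure payment of $\lambda$ per step and
  continuing with the arm are equally valuable. The index is found by
  bisection; each evaluation is a finite-horizon dynamic program on the arm's
  own (success, failure) lattice with retirement value
  $\lambda(1-\gamma^{\text{remaining}})/(1-\gamma)$ and terminal value 0.
  Defaults: bisection tolerance $10^{-4}$ and DP depth 500, whose tail weight
  at $\gamma = 0.98$ is $0.98^{500} \approx 4\times10^{-5}$.
* **Fixed coupled** (`coupled_policy()`): the posterior mean of the shared
  parameter, option 1 scored by $(a_0+s_1+f_2)/(a_0+b_0+N)$. Myopic choice is
  optimal here because exploration carries no information premium.
* **Structure learning** (`structure_policy()`): solves
  $V(c) = \max_a P_a(c)\,[1 + \gamma V(c^{+a})] + (1-P_a(c))\,\gamma
  V(c^{-a})$ over the count lattice, where $P_a$ is the mixture predictive
  reward and therefore embeds the coupling posterior at every future node.
  Because counts — not reward orderings — index states, a depth-$H$ lookahead
  costs $\binom{H+4}{4}$ evaluations instead of $4^H$. The lattice DP is
  implemented in C++ with two-level storage and integer-offset log-gamma
  tables.

**Discount.** $\gamma$ plays the role of the continuation probability of the
geometrically stopped task; the default 0.98 is the value used by the
solvers throughout. The experiment's stopping probability (default $1/48$,
mean stopping time 48) is a separate configuration field: the two printed
design quantities (mean 48, discount 0.98, i.e. mean 50) are not exactly
consistent with one another, and the package deliberately preserves both
rather than silently reconciling them.

**Horizons.** The default lookahead for a single `structure_value()` query
is 150, with documented truncation bound $\gamma^{H}/(1-\gamma)$ (about 2.4
reward units at $\gamma=0.98$, far smaller for value *differences* between
actions). Cohort-scale simulation and scoring use a lookahead of 30 per
belief state: action choices stabilize far earlier than values, and this
size keeps a full four-cohort recovery study in the minutes rather than
hours. The state-wise comparison of the structure policy against the Gittins
policy at structural certainty uses a single shared lattice pass of depth
330 (at least 300 trials of lookahead for every state with $N \le 30$)
because near-tie states need deep lookahead before truncation stops flipping
them.

**Tie-breaking.** All policies break exact value ties (tolerance
$10^{-12}$) toward the option with fewer pulls — the more informative pick —
then toward option 1. The tie flag is always recorded, and tied predictions
score one half in prediction rates.

**Mixture claim.** At structural certainty the structure policy provably
reduces to the fixed policies, and the package tests both limits
state-by-state; no mixture-of-policies shortcut is used at intermediate
beliefs — the Bellman equation is solved directly.

## The Q-learning baseline

`fit_qlearning()` fits the five free parameters (two initial values,
learning rate, inverse temperature, discount) by maximizing the fraction of
trials whose recorded action is the modal action of the soft-max — a
deterministic criterion, unlike sampled-action scoring, so fitted rates are
reproducible. The discount is retained inside the temporal-difference target
even though the task has a single state, preserving the five-parameter count.
The search is a coarse grid (initial values on $\{0,.25,.5,.75,1\}$,
learning rates $0.05$–$0.95$, temperatures spanning $-5$ to $20$ with
log-spaced magnitudes plus 0, discounts $\{0,.3,.6,.9,.98\}$) followed by
rounds of coordinate descent; the refined rate can never fall below the best
grid point's.

One caveat found while testing the baseline: with a *negative* temperature
(choosing in opposition to the values) and a high learning rate, Q-learning
partially predicts strictly alternating choice sequences even when choices
are uncorrelated with rewards. Chance-level fitted rates should only be
expected for choices that are independent of rewards *and* of choice
history.

## The synthetic experiment

`make_schedule()` and `run_cohort()` emulate the study design: 2 blocks
(one independent, one coupled, order configurable) of 16 tasks; reward
probabilities drawn uniformly per task (a coupled task draws one probability
and assigns its complement to option 2); stopping times geometric with mean
48 (support starting at 1). A shared-schedule mode exposes every agent in a
cohort to the same probabilities and stopping times, as in the study. Coupled
rewards are generated by one latent draw per trial — strict complementarity —
though belief inference is identical under per-arm complementary draws since
only the chosen arm is observed.

What the generator does *not* emulate: reaction times, display/score
framing, and any temporal dependence in human choice (stickiness,
memory limits). Model-recovery results on these cohorts therefore show that
the analyses can separate the four decision models under the design's
information conditions — not that human data would be equally separable.

Choice noise is modeled as flipping the policy's action with a configured
probability (0.1 in the recovery study; 16 agents per generating model).
The Q-learning generator in the recovery study uses moderate parameters
($q_{\text{init}}=0.5$, $\alpha=0.4$, $\beta=5$, $\gamma_q=0$) with the same
flip noise, so all four cohorts share one noise protocol.

## Trial-level analyses

* **Evidence / confidence** (`evidence()`, `confidence()`): smoothed log
  odds ratio of observed reward rates of the truly better option over the
  worse, and smoothed log ratio of their observation counts. Add-one
  smoothing per cell keeps both finite at zero counts and matches the
  uniform priors used everywhere else. The "better" option is defined by the
  true generative probabilities (known in simulation), ties toward option 1.
* **Diagnostic trials**: any pairwise disagreement among the four models'
  predictions from the counts-before-choice snapshot.
* **Under-/over-exploration** (`classify_exploration()`): on
  independent-environment trials where the subject contradicts the Gittins
  policy — under-exploration if the policy's pick was the lower-proportion
  (information-seeking) option, over-exploration if it was the
  higher-proportion option already observed at least 8 times (the "clearly
  worse option" cutoff; configurable, since only "high counts" is specified
  by the design).
* **Task-learning trials** (`task_learning_trials()`): both fixed models
  agree, the structure model opposes them, all three committing without
  value ties — choices attributable purely to reducing structure
  uncertainty. The tie exclusion matters: coupled-value ties
  ($s_1+f_2 = f_1+s_2$) are common exactly where these trials live, and a
  tie-broken "agreement" carries no real prediction. Whether such trials
  concentrate early can be asked with an ordinary Welch two-sample test on
  trial positions; note that in synthetic cohorts under the default
  conditions they in fact occur *later*, because the structure posterior
  stays mid-range for much of a block (see the learning-simulation
  limitation below), so early concentration should be expected only when
  structure uncertainty resolves quickly.
* **Prediction report** (`prediction_report()`): per-model rates on each
  subset; model pairs compared by a two-sided exact binomial test restricted
  to trials where the two models disagree and neither ties — there, exactly
  one model matches the recorded choice, so the null of equal predictive
  ability makes the match count Binomial$(n, 1/2)$. This conditioning is the
  McNemar-style exact form appropriate for dependent rates on shared trials;
  pairs that never disagree are reported as undefined rather than an error.
* **Coupling-belief curve** (`coupling_belief_curve()`): better-option
  choice fraction binned by the replayed coupling belief (10 equal-width
  bins by default; the binning is configurable since none is canonical),
  with Pearson correlations between the subject curve and each model curve
  over non-empty bins. Curves and surfaces score a model by its tie-broken
  action so that an agent identical to a model reproduces the model's curve
  exactly.
* **Choice surface** (`choice_surface()`): better-option choice fraction
  over (evidence, confidence) cells on diagnostic trials; empty cells are
  absent from the output rather than imputed.

## Known limitations

* The Bellman objective is within-task: structure knowledge carried to later
  tasks is used (the posterior becomes the next task's prior) but not
  *valued* during planning. Consequently the structure agent stops probing
  the off arm once its within-task posterior is extreme. In coupled
  environments this caps how fast the coupling posterior can converge: in
  the scaled learning simulation (4 tasks of 50 trials) the median final
  posterior toward the truth reaches ~0.99 in the independent environment
  but only ~0.8 in the coupled one, where a forced-alternation probe would
  reach ~0.98. This is a property of the within-task-optimal objective, not
  of the inference.
* Finite lookahead can flip near-tie decisions relative to the
  infinite-horizon Gittins ranking; state-wise limit comparisons use deep
  lattices (above), but cohort runs at lookahead 30 should be read as the
  policy family at that depth.
* Human phenomena outside the model family — the anti-diagonal persistence
  pattern, choice stickiness — are deliberately out of scope; the analyses
  label such trials, they do not explain them.

## Problem sizes used by the checks

Inference is verified against numerical integration on random count states;
the lattice DP against exhaustive raw-history induction (horizons ≤ 5);
Gittins indices against truncated-lattice value iteration (γ = 0.9,
pseudo-counts ≤ 10) and monotonicity/bonus properties on counts ≤ 50; limit
equivalence on all count states with N ≤ 30; the learning simulation with
100 seeds per environment; model recovery with four 16-agent cohorts under
flip noise 0.1.
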