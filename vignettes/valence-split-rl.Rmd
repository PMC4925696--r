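---
title: "Valence-split reinforcement learning: task, models, fitting and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valence-split reinforcement learning: task, models, fitting and model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valsplitrl)
```

## The scientific problem

Anxiety disorders are hypothesized to involve altered sensitivity to negative
feedback. A probabilistic category-learning task can dissociate learning from
reward and from punishment: four stimuli each belong to one of two categories
with 80/20 probability; for two stimuli (the positive-feedback task) a correct
response wins +25 points and an error yields nothing, while for the other two
(the negative-feedback task) an error loses 25 points and a correct response
yields nothing. The no-feedback outcome is therefore ambiguous — it can mean a
missed reward or an avoided punishment. Subjects complete 4 blocks in which
each stimulus appears 10 times (8 with its common category, 2 with the rare
one), i.e. 160 analyzable trials. If the final point tally falls below the
500-point starting stake, filler trials whose responses are "taken as
correct" are appended until the tally reaches at least 525; these carry no
analyzable structure and are excluded everywhere downstream.

`valsplitrl` implements this task as a simulator, a family of trial-by-trial
learning models with valence-split learning rates, per-subject
maximum-likelihood fitting, model comparison (a study-specific BIC variant,
the conventional BIC, and random-effects Bayesian model selection), a
synthetic-cohort generator for four groups (generalized anxiety, social
anxiety, panic disorder, healthy controls), and the descriptive behavioral
metrics (optimal-response proportions by block and valence, chance tests).

## The model family

All models share a two-option softmax choice rule for stimulus $s$:

$$p(c_t = A \mid s_t) = \frac{1}{1 + \exp\!\big[-\beta\,(x_t(s_t,A) - x_t(s_t,B)) - \varphi\,(C_t(s_t,A) - C_t(s_t,B))\big]}$$

where $x$ is the stimulus–action value $Q$ for the Q-learning and actor-only
models and the actor preference $P$ for the actor-critic models, $\beta \ge 0$
is the softmax noise ($\beta = 0$ gives chance responding), and
$C_t(s_t,\cdot)$ is a one-hot indicator of the response made on the previous
presentation of $s_t$, weighted by the perseveration parameter $\varphi$
(positive: tendency to repeat; negative: tendency to switch).

Outcomes are coded $o_t \in \{-1, 0, +1\}$ as the sign of the feedback points;
$\beta$ absorbs the point scale, keeping it comparable across models. The four
kinds are:

* **Q-learning** (2 free parameters: $\alpha, \beta$). Prediction error on the
  chosen stimulus–action pair, $\delta_t = o_t - Q_t(s_t, c_t)$, and a single
  learning rate for both error signs:
  $Q_{t+1}(s_t, c_t) = Q_t(s_t, c_t) + \alpha\,\delta_t$.
* **Actor-only** (3: $\alpha_a^+, \alpha_a^-, \beta$). The same
  stimulus–action learner but valence-split: $\alpha_a^+$ applies when
  $\delta_t > 0$ and $\alpha_a^-$ when $\delta_t < 0$. With
  $\alpha_a^+ = \alpha_a^-$ it reduces exactly to Q-learning (a tested
  invariant).
* **Actor-critic, fixed noise** (4: $\alpha_c^+, \alpha_c^-, \alpha_a^+,
  \alpha_a^-$; $\beta \equiv 1$). A critic learns stimulus values
  $V_t(s_t)$ with its own valence-split rates from
  $\delta_t = o_t - V_t(s_t)$, and broadcasts the same $\delta_t$ to an actor
  that updates its preference for the selected choice,
  $P_{t+1}(s_t, c_t) = P_t(s_t, c_t) + \alpha_a^{\pm}\,\delta_t$.
* **Actor-critic, free noise** (5: the four rates plus $\beta$). Identical,
  with $\beta$ free; at $\beta = 1$ its likelihood equals the fixed-noise
  variant on any log (tested).

Two printed-source ambiguities required a decision. First, the valence-split
update is implemented as $\alpha^+$ for $\delta_t > 0$ and $\alpha^-$ for
$\delta_t < 0$ — the only reading consistent with "learning rates for positive
and negative prediction error". Second, the actor-critic choice rule is
implemented on the actor's preferences $P$, not on $Q$: the critic has no
action-specific quantity, and the actor's preferences are the only
action-valued state the architecture defines.

Further choices, made once and documented here:

* **Initialization.** $Q$, $V$, $P$ and $C$ all start at zero (symmetric,
  uninformative). With outcomes in $[-1, 1]$ and learning rates in $[0, 1]$
  every $Q$ and $V$ entry then stays in $[-1, 1]$ (a convex-combination bound,
  tested along randomized trajectories).
* **No-feedback trials.** The ambiguous outcome is treated as $o_t = 0$ and
  *does* drive updates ($\delta_t = -$value), the minimal assumption; the
  `update_on_no_feedback = FALSE` switch in the likelihood and simulators
  turns this off for sensitivity analyses.
* **Perseveration.** $\varphi$ appears in the choice rule but not in the model
  family's free-parameter counts, so it defaults to 0 (not free); every model
  has a choice-kernel variant (`kernel = TRUE`) that frees it.
* **Top-up mechanics.** The source protocol states only that responses on
  top-up trials are "taken as correct" until the tally reaches 525. We
  present a random stimulus, force the optimal response, and award +25 per
  trial, which provably terminates; top-up rows are flagged and excluded from
  all likelihoods and metrics (a tested invariant).

## Fitting

`neg_log_likelihood()` replays a session log under teacher forcing — the
model state is advanced with the subject's actual responses and observed
feedback — accumulating $-\log \Pr(\text{response})$ over the 160 non-top-up
trials. A model with $\beta = 0$ predicts every response at probability 1/2,
so $160 \ln 2 \approx 110.90$ is the chance ceiling any fit should beat. The
replay is verified against an independently coded brute-force oracle to
1e-10 on randomized logs for all four model kinds.

`fit_subject()` minimizes this objective with bounded L-BFGS-B from (by
default) 10 random interior starts, falling back to a box-clamped
Nelder–Mead search when a gradient run fails and polishing the best solution
with a derivative-free pass. Search bounds are $[0,1]$ for learning rates,
$[0, 20]$ for $\beta$ and $[-5, 5]$ for $\varphi$ when free — with unit-coded
outcomes, $\beta = 20$ saturates the softmax, so the box is effectively
unrestrictive. Restart draws are row-wise from the seeded stream, so
best-of-$n$ negLLE is nonincreasing in $n$ (tested). On this task's
likelihood surface the learning rate and noise trade off against each other
in single sessions; `recover_parameters()` quantifies this, and with 100
simulated Q-learners (160 trials each) the true and recovered learning rates
correlate well above 0.5 with a median absolute error under 0.15.

## Model comparison

Two criteria are computed. The **study BIC**,
$k \ln n - 2 \ln(\mathrm{negLLE})$ applied to the cohort-mean negLLE, is the
arithmetic used in the source study's comparison table; note it is
*decreasing* in negLLE at fixed $(k, n)$ — the opposite sensitivity of the
conventional criterion — and its published values are reproduced exactly only
under two-decimal *truncation* (floor toward zero), which `bic_paper(...,
truncated = TRUE)` applies; the raw value is always available. The
**conventional BIC**, $k \ln n + 2\,\mathrm{negLLE}$ per subject, supplies
the per-subject log evidence $-\mathrm{BIC}/2$ for random-effects Bayesian
model selection, the field-standard approximation when no better evidence is
available.

`rfx_bms()` fits a Dirichlet population distribution over model identities by
variational Bayes (responsibilities proportional to
$\exp[\log \mathrm{ev} + \psi(\alpha_k) - \psi(\Sigma \alpha)]$, counts
$\alpha = \alpha_0 + \Sigma_n u_{nk}$, iterated to a 1e-6 tolerance on
$\alpha$), returning expected posterior model probabilities
$\alpha / \Sigma\alpha$ and exceedance probabilities estimated from $10^6$
Monte-Carlo Dirichlet draws. Symmetric evidence returns the exact uniform
distribution; the two-model case is cross-checked against the closed-form
Beta tail in the test suite.

## The synthetic cohort

No subject-level data from the original study are available, so the package
generates cohorts whose *qualitative* group signature matches the reported
dissociation: enhanced negative-feedback learning in generalized and social
anxiety, no group differences in positive-feedback learning. Group sizes are
18/20/17/18 (GAD/SAD/PAD/HC; 73 subjects).

The generating model is the **actor-only** learner — the group effect is a
valence asymmetry, which its $\alpha_a^-$ parameter expresses directly —
while model fitting in examples defaults to Q-learning; that mismatch is
intentional and mirrors the source study's own outcome, where the simplest
model won the comparison on parsimony. Per-group parameter distributions are
truncated normals, calibrated once by simulation (the tuning script is
shipped under `scripts/`) and frozen:

| parameter | GAD / SAD | PAD / HC |
|---|---|---|
| $\alpha_a^+$ | TN(0.38, 0.04) on \[0, 1\] | identical |
| $\alpha_a^-$ | TN(0.50, 0.05) on \[0, 1\] | TN(0.055, 0.02) on \[0, 1\] |
| $\beta$ | TN(4.8, 0.4) on \[0, 20\] | identical |

Only the negative-prediction-error rate differs between groups; positive-rate
and noise parameters are matched. Because no-feedback outcomes drive updates,
$\alpha_a^-$ also touches positive-stimulus dynamics (reward omissions
unlearn), so exact positive-rate equality is not guaranteed by construction —
the calibration keeps the four groups' expected positive-feedback rates
within about 0.01 of each other, with residual cohort-to-cohort variation of
a few percentage points from finite group sizes. During calibration a
generator that ignored no-feedback outcomes entirely was evaluated and
rejected: without the mean reversion those outcomes provide, both actions'
values drift to the same extreme and the group signature inverts.

Inside `generate_cohort()` all behavioral randomness (per-subject parameter
draws, then the session) is consumed before any metadata sampling, so the
inert demographic columns (age, education, disease duration, anxiety and
neuropsychological scores, drawn from group-level means/SDs) can never
perturb the behavioral trajectories a seed produces — a tested invariant.
Every log is paired with its generating parameters in the `truth` table,
enabling end-to-end parameter-recovery studies.

What passing cohort tests do and do not show: the generator reproduces the
task structure, the direction of the group dissociation, and realistic
accuracy levels; it does not model comorbidity, medication, dropout,
within-session fatigue, or any mechanistic claim about anxiety — it exists so
that every pipeline stage is exercisable without patient data.

## Behavioral metrics

`accuracy_table()` aggregates optimal responses (choosing the stimulus's
80% category, regardless of the sampled outcome) per subject × block ×
valence; 20 trials per cell under the default task. `group_summary()` adds
group means and standard errors (SEM defined as 0 for a single subject);
`chance_test()` runs one-sample t-tests of per-subject accuracies against
0.5, reporting the Bonferroni-adjusted level 0.0125 used across four groups,
and flags zero-variance cells as degenerate rather than testing them. For
the chance test, a subject's accuracy per valence is the mean of their four
block proportions (blocks averaged after, not before, forming proportions).
The omnibus ANOVAs of the original analysis are deliberately out of scope —
the tidy accuracy table is the interface to any statistics environment.

## Numerical choices and problem sizes

Likelihood replay is exact (no simulation); optimization tolerances are the
`stats::optim` defaults with a 1e-10 relative-tolerance Nelder–Mead polish.
Validation studies in the test suite use 100 agents for parameter recovery
and a 20-subject cohort for model-selection sanity; the calibration study
used 8–12 replicate 73-subject cohorts per setting. Exceedance probabilities
use $10^6$ draws by default ($10^4$–$10^5$ in fast tests, where the
tolerance is correspondingly loose).

## Known limitations

* Per-subject maximum likelihood, not hierarchical estimation: no pooling
  across subjects; the fitting module is an extension point for empirical
  Bayes schemes.
* The study BIC is reproduced as published arithmetic, including its
  nonstandard sensitivity to negLLE; scientific conclusions should rest on
  the conventional BIC / RFX-BMS columns that the comparison report carries
  alongside.
* Protected exceedance probabilities and family-level comparison are not
  implemented.
* The task simulator is not a stimulus presenter: no timing, images, or
  response-latency modeling.
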