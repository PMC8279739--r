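---
title: "Modelling inference-based credit assignment in a dual-outcome bandit task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inference-based credit assignment in a dual-outcome bandit task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credmap)
```

## The task and its cognitive map

`credmap` models behavior in a dual-outcome bandit task. Four choice
options ("persons") each deterministically yield one animal and one
vegetable outcome; there are only two animals and two vegetables, and every
outcome is favored by exactly two persons. This bipartite structure — the
task's *cognitive map* — implies that exactly four of the six person pairs
share exactly one outcome; only those four pairs are ever offered for
choice. Each outcome pays £1 with a probability that is constant within a
block (drawn independently and uniformly from [0.2, 0.8] per block) and
resampled between blocks. A session has 10 blocks of 36 trials; within a
block each valid pair is offered 9 times in random order.

After a choice, the two outcomes of the chosen person appear in random
temporal order, each with its reward. The *presentation format* varies
randomly per trial with equal probability:

* **S** (standard): both outcome identities visible;
* **PI** (prospective inference): the second outcome is hidden behind a
  curtain — its identity can be inferred as soon as the first outcome is
  seen;
* **RI** (retrospective inference): the first outcome is hidden — its
  identity can only be inferred after the second outcome appears, by which
  time its reward is no longer on screen.

Rewards are always visible. Because the two offered persons share an
outcome, reward feedback dissociates two credit-assignment (CA) routes: a
model-free (MF) route that credits the chosen person as a whole, and a
model-based (MB) route that credits the individual outcomes and therefore
generalizes across the persons who share them. Concealment only matters for
the MB route, which needs outcome identity; that is the scientific question
the model family is built to answer — how inference demands reshape MB
credit assignment across formats and outcome positions.

## The hybrid model

Latent values (all reset to 0 at every block start):

* $Q_{MF}(p)$ for each person $p$,
* $Q_{MB}(o)$ for each outcome $o$,
* $PERS(p)$, a perseveration value per person.

Rewards are signed: $r = +1$ for a coin, $-1$ for nothing. After a choice
of person $c$ whose outcomes at temporal positions 1 and 2 were $o_1, o_2$
with signed rewards $r_1, r_2$ in format $f$:

$$Q_{MF}(c) \leftarrow (1 - f_{MF})\,Q_{MF}(c) + c_{MF}\,(r_1 + r_2),$$

with the three non-chosen persons decaying by $(1 - f_{MF})$;

$$Q_{MB}(o_i) \leftarrow (1 - f_{MB})\,Q_{MB}(o_i) + c^{MB}_{f,i}\,r_i,
\qquad i = 1, 2,$$

with the two unrelated outcomes decaying by $(1 - f_{MB})$; and

$$PERS(p) \leftarrow (1 - f_P)\,PERS(p) + pr\,\mathbb{1}[p = c].$$

The six MB gains $c^{MB}_{f,i}$ (format × temporal position) are the
parameters of scientific interest. At choice, each offered person's net
value is

$$Q_{net}(p) = Q_{MF}(p) + Q_{MB}(\text{animal}_p) +
  Q_{MB}(\text{vegetable}_p) + PERS(p),$$

and the choice probability is the two-alternative softmax of the net
values. There is deliberately no inverse temperature: the CA gains carry
the choice scale, so gains are identified in likelihood.

A *cross-credit* extension adds, on RI trials only, two gains
$c^{cross}_{1\to2}, c^{cross}_{2\to1}$ that let each reward also reinforce
the *other* outcome — the behavior expected if credit is assigned online
from a belief state before the hidden outcome's identity is resolved. The
plain model is this extension with both cross gains at 0, and the
implementation exploits that: the RI update always uses the cross form.

### The model family

`model_spec()` exposes the full model, seven nested restrictions (pure MB,
pure MF, MBCA equal across everything / across positions / across formats,
additive format + position effects, and a two-parameter *functional
position* model in which the RI gains swap places because credit is
assigned in inference order rather than temporal order), and the
cross-credit extension in which the full model is nested. Every restriction
is a linear map from a reduced free vector to the canonical 13-entry
parameter vector, which keeps the optimizer generic and makes likelihood
nesting exact by construction.

## Fitting

`fit_participant()` maximizes the session log-likelihood with multi-start
L-BFGS-B, analytic gradients (forward accumulation through the value
recursion, in compiled code), and box constraints: forgetting rates in
$[0, 1]$; CA and perseveration gains in $[-5, 5]$ by default. Negative
gains must be admissible — the participant-exclusion rule is defined by all
seven CA gains being strictly negative. Starting points are uniform over
the box, one RNG block per start, so enlarging `n_starts` extends rather
than reshuffles the start set and the best log-likelihood is monotone in
the number of starts. Ties between starts are broken first-found at a
$10^{-6}$ log-likelihood tolerance, which is also the optimizer's
convergence tolerance. 200 starts mirror the original fitting protocol; 20
is the practical default in the bootstrap loops below, and the package's
own studies state the start counts they use.

## Model comparison: the BGLRT

Nested models are compared with a parametric-bootstrap generalized
likelihood-ratio test. Per participant: fit the sub- and super-model,
record $2\,\Delta\log L$; simulate `n_boot` synthetic sessions from the
sub-model at its ML parameters on fresh trial plans (new randomization,
same task map and configuration); refit both models to each; the p value is
the proportion of bootstrap statistics at least as large as the empirical
one, with no continuity correction. The group statistic sums participant
statistics, and its null distribution is built by drawing one bootstrap
statistic per participant uniformly and summing (10,000 resamples by
default).

Two design details matter for calibration:

* The super-model fit is warm-started from that dataset's fitted sub-model
  parameters (expanded to the super-model space), *identically* for the
  empirical and every bootstrap dataset. The statistic is therefore
  computed by one exchangeable pipeline, which is what makes the bootstrap
  p value approximately uniform under the null even with few random starts.
* Negative statistics (optimizer noise) are clamped to zero with a warning.

The package's calibration study runs 200 cohorts of 10 participants with
4-block sessions, `n_boot = 99`, and a single random start per fit on top
of the warm start. These sizes are the package's scaled-down design for a
desk-scale type-I-error estimate; the test checks the group-level rejection
rate at $\alpha = 0.05$ against the nominal level and the uniformity of the
participant-level p values.

## Recovery studies

`parameter_recovery()` simulates fresh datasets from each synthetic
participant's generating parameters, refits the full model, and reports the
Pearson correlation between generating and recovered values per MB gain
plus the matrix of estimation-error correlations (parameter trade-offs).
The packaged study uses 30 participants × 5 datasets at full session
length. A single 360-trial session estimates each MB gain with substantial
noise (the error spread is comparable to the between-participant spread of
the gains themselves, as the `table` element of the recovery result
shows), so recovery correlations are informative only if the generating
spread is realistic (below).

## The synthetic-data generator

`generate_synthetic_cohort()` draws, per participant, a fresh task map
(the person–outcome mapping is randomized anew per participant), a fresh
session plan, and choices simulated from sampled parameters.
`sample_plausible_params()` defines the default population:

* MB gains: independent $\mathcal{N}(0.2,\ 0.22^2)$. Group-level MB-gain
  estimates on this task are around 0.1–0.3, and the reported test
  statistics imply a between-participant standard deviation of roughly
  0.22 (e.g. a gain of 0.16 with $F(1,222) \approx 20$ over 38 participants
  gives an SEM of about 0.036, hence an SD of about
  $0.036\sqrt{38} \approx 0.22$). Negative gains occur with small
  probability, consistent with the existence of an all-negative-CA
  exclusion rule.
* MF gain: $\mathcal{N}(0.3,\ 0.2^2)$; forgetting rates uniform on
  moderate ranges ($f_{MF}, f_{MB} \sim U(0.05, 0.5)$,
  $f_P \sim U(0.2, 0.8)$); perseveration $pr \sim U(0, 0.4)$.

What the generator emulates: the exact trial bookkeeping (equal pair
allocation, random sides, formats, outcome orders, block-wise reward
probabilities) and choice behavior under the hybrid model. What it does
not: reaction times (the `rt_ms` column exists for real data and for
injected-RT tests but the simulator leaves it missing), missed-deadline
trials (representable, never generated), within-session parameter drift,
and any learning of the map itself (the familiarization phase trains the
map to criterion, so it is taken as known). Passing tests on synthetic
cohorts therefore validate the pipeline's statistical machinery, not claims
about real participants.

One model-agnostic subtlety the simulations expose: with very slow MF
forgetting, a pure-MF agent shows a small spurious common-reward effect on
*generalization*, because the shared outcome's block-level reward
probability correlates the regressor with the offered persons' accumulated
MF values across the block. At moderate forgetting
($f_{MF} \gtrsim 0.35$) the effect vanishes, and the package's
dissociation checks use that regime.

## Signature analyses

The trial-transition tables follow the original coding conventions: reward
regressors ±0.5; PI/RI indicator dummies with the standard format as
reference (which is why the composite main effect is
$(3b_{COMMON} + b_{COMMON:PI} + b_{COMMON:RI})/3$); serial position +0.5 =
first in the repetition/generalization and parameter analyses but −0.5 =
first in the full-transition design — tables store the temporal position
and apply the per-analysis coding when built. Transitions never cross block
boundaries, since values reset between blocks.

Mixed-effects models are fit with `lme4` (logistic models via the fast
`nAGQ = 0` approximation). The free-covariance random-effects structure of
the original analyses is frequently singular on small synthetic cohorts, so
every model walks a documented fallback chain (full structure → reduced
slopes → random intercept → ordinary regression) and records the structure
used. Contrast tests are Wald F tests on the fixed effects with the
backend's residual-style denominator degrees of freedom, which are
reported alongside each contrast rather than asserted to match any
particular small-sample method.

The RT analysis removes sub-250 ms responses and the first trial of each
block, classifies trials as replicas (same offered pair as the previous
trial) or new, and models mean RT per participant × previous-format × type.

## Earnings simulations

Baselines are defined per trial from the generating reward probabilities:
*guessing* earns the mean of the two offers' expected total reward,
*oracle* the maximum. An agent's standardized earnings on a session are
(realized points − guessing) / (oracle − guessing); the oracle policy
scores 1 and uniform-random choice about 0.

`grid_earnings()` simulates pure-MB agents over a grid of total RI-format
MBCA $t$ and allocation fraction $p$, with gains $t/2$ in the S and PI
formats and $(p\,t,\ (1-p)\,t)$ across the two RI positions. The MB
forgetting rate defaults to 0.2, a moderate value standing in for a
group-average fit when none is supplied. One session plan and one
choice-RNG stream are shared across all grid cells (common random
numbers), so cross-cell comparisons are paired; the reported argmax
resolves plateau ties by taking all fractions whose paired deficit to the
best cell is within two standard errors and returning the central one. At
5000 sessions per cell the argmax at $t = 1.5$ is stable at 0.5 to within
one grid step (0.05), and the surface is symmetric in $p \leftrightarrow
1 - p$ within Monte-Carlo error — prioritizing either outcome position
buys nothing, which is the normative benchmark against which empirical
prioritization of the inferred outcome is judged.

`yoked_format_agents()` duplicates each fitted participant's S, PI, or RI
gains across all three formats (pure-MB agents, fitted $f_{MB}$, no
MF/perseveration) and plays all agents on the same fresh sessions, giving
session-level group means per format regime. `earnings_regression()`
regresses standardized earnings on overall MBCA level (mean of the six
gains) and position asymmetry (mean over formats of |first − second|),
using `MASS::rlm` M-estimation; p values use a $t$ reference with
$n - 3$ degrees of freedom.

## Numerical and design choices, in brief

* Choice log-probabilities use the log-sum-exp form; the likelihood core
  and its analytic gradient are compiled, and the multi-start box-
  constrained optimization runs entirely in compiled code.
* Trials with missing choices contribute no likelihood and trigger no
  update; loaders accept them, the simulator never produces them.
* Display sides are randomized uniformly (the side-assignment rule is not
  part of the task's stated design; side-coded regressors need one).
* The canonical MB-gain order in all serializations is S1, S2, PI1, PI2,
  RI1, RI2.
* Sessions serialize to tidy CSV (persons/outcomes as labels, 1-based
  trials) plus a JSON sidecar with map, configuration, reward
  probabilities, and seed; a session seed derives independent sub-streams
  for pair order, sides, formats, outcome order, and reward probabilities,
  so plan components can be regenerated independently.
* The grid simulation's RI constraint is read as $c^{MB}_{RI,1} = p\,t$,
  $c^{MB}_{RI,2} = (1-p)\,t$; the two RI entries are the only pair it makes
  sense to complement.

## Known limitations

* Group BGLRT calibration is demonstrated at the scaled-down design, not
  at the original 1001-bootstrap/38-participant scale; the pipeline runs
  at that scale but the packaged studies do not.
* Mixed-model denominator degrees of freedom follow the fitting backend;
  exact small-sample F reference distributions are out of scope.
* The two-stage fallback for degenerate mixed models is an approximation
  and is flagged in the result object (`$re`).
* Synthetic RTs are only as rich as the generator a test injects; the
  package makes no claim about RT distributions.
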