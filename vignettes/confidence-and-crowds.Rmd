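---
title: "Confidence, crowds, and held-out questions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence, crowds, and held-out questions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdwise)
```

## The problem

In a two-alternative forced-choice (2AFC) task, a "crowd" answers binary
questions by majority vote. A natural recruitment strategy is to rank
candidates by their subjective confidence on a few *training* questions
and staff the group from the top of the ranking. Whether that helps
depends on how far confidence travels: confidence reported *on* a
question reflects both stable competence and question-specific
knowledge, and only the former generalises to held-out *test*
questions. `crowdwise` packages the machinery to study this: a
generative model of 2AFC behaviour, confidence–accuracy regressions,
confidence-based group formation, three aggregation rules, and
train/test resampling simulations.

## The generative model

`generate_dataset()` draws a complete participants × questions table
from a latent-trait (item-response-style) model. For participant $p$
and question $q$:

$$
a_p \sim N(0, \sigma_a^2), \quad
e_q \sim N(0, \sigma_e^2), \quad
k_{pq} \sim N(0, \sigma_k^2), \quad
s_{pq} = a_p + e_q + k_{pq},
$$

$$
\text{correct}_{pq} \sim \text{Bernoulli}(\text{logit}^{-1}(s_{pq})), \qquad
\text{conf}_{pq} = 100\,\text{logit}^{-1}(\gamma_0 + \gamma_1 s_{pq} + \varepsilon_{pq}),
\quad \varepsilon_{pq} \sim N(0, \sigma_c^2).
$$

The decomposition is the point: $k_{pq}$ informs accuracy only on
question $q$, so confidence predicts accuracy more strongly within a
question than between questions — the empirical signature that makes
single-training-question selection fragile. The between-question
association is carried by ability $\sigma_a$ alone.

### Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| `n_participants`, `n_questions` | design size | 150 × 70 | mirrors a ~150-person, 70-question population-inference study; `task_shapes()` also records the companion 149 × 25 design |
| `ability_sd` ($\sigma_a$) | stable skill spread (logit units) | 0.3 | weak general competence: between-question predictability small but nonzero |
| `easiness_sd` ($\sigma_e$) | question difficulty spread | 0.7 | questions vary substantially; induces agreement between any two responders |
| `item_knowledge_sd` ($\sigma_k$) | cell-specific knowledge | 1.0 | dominates the evidence, making within-question coupling much stronger than between |
| `calib_intercept` ($\gamma_0$) | confidence bias | 0 | neutral calibration; positive values model overconfidence |
| `calib_slope` ($\gamma_1$) | confidence–evidence coupling | 1 | calibrated raters; 0 decouples confidence, negative values model "wicked" environments where confidence misleads |
| `confidence_noise_sd` ($\sigma_c$) | reporting noise | 0.5 | confidence is informative but imperfect |
| `seed` | RNG seed | 1 | identical configs are bit-identical |

Randomness uses deterministic substreams: one stream for abilities and
one per question index (easiness, knowledge, response and confidence
draws), so enlarging `n_questions` never perturbs earlier questions'
draws — convenient for nested designs and regression tests.

## Confidence–accuracy regressions

`fit_confidence_logistic()` fits
$P(\text{correct}) = \text{logit}^{-1}(\alpha + \beta\,\text{conf})$ by
maximum likelihood and reports the slope with a 95% Wald interval.
`within_question_analysis()` fits one model per question;
`between_question_analysis()` one per ordered pair $(i, j)$, $i \ne j$,
predicting accuracy on $j$ from confidence on $i$ (4,830 pairs for 70
questions, 600 for 25).

**Estimator choice.** The inferential target is whether the 95%
interval excludes zero. A Bayesian MCMC fit with flat priors targets
the same quantity through posterior credible intervals;
we use ML with Wald intervals because it is deterministic, fast enough
for thousands of pair fits, and has calibrated type-I error at these
sample sizes (the test suite verifies ~5% false-exclusion rate at
$\gamma_1 = 0$ over 250 questions of 150 responses). The ML point
estimate plays the role a posterior median would play.

**Degenerate fits.** A fit is flagged `converged = FALSE` — never an
error — when all responses are identical, IRLS fails, the standard
error is non-finite, the residual deviance is ~0 (perfect separation),
or $|\beta| > 50$ per unit confidence (quasi-separation; real
calibration slopes are two orders of magnitude smaller).
`apply_exclusions()` drops flagged fits plus any externally excluded
questions or ordered pairs — the same role that dropping non-converged
MCMC chains (e.g. by an $\hat{R} > 1.1$ rule) plays in a Bayesian
pipeline.

## Group formation and aggregation

`rank_by_confidence()` orders participants by mean confidence over the
training questions, descending. Exact ties are broken uniformly at
random under an explicit `tie_seed`: with continuous 0–100 confidence
ties are measure-zero, but a deterministic, unbiased rule keeps every
run reproducible.

`select_members()` supports the three categories — `highest` (top
$g$ ranks), `higher` (above-median ranks $1..\lceil N/2\rceil$),
`mixed` (all ranks) — in two modes. *Stride* mode takes deterministic
positions $r_i = 1 + \mathrm{round}\!\big((i-1)\,\text{pool}/g\big)$,
i.e. $g$ evenly spaced ranks starting at 1: with $N = 150$ and
$g = 15$, ranks 1, 6, …, 71 (`higher`, pool 75) and 1, 11, …, 141
(`mixed`, pool 150); for `highest` the stride degenerates to ranks
$1..g$. *Random* mode samples $g$ members uniformly without
replacement from the category pool. The accordance simulation uses
stride panels (a fixed cross-section of the ranking); the group
simulation uses random draws (a sampled group), which is the natural
reading of each design and deliberately not harmonised.

Three aggregation rules are provided. *Majority*: the alternative with
more votes; exact ties (possible only for even groups) are fair coin
flips under a seed, or an error when no seed is supplied. *Weighted
confidence*: the alternative with the larger sum of its supporters'
confidences — three members choosing A at 20/30/40 lose to two choosing
B at 80/90 (sums 90 vs 170). *Transmission chain*: members are polled
in order; the first member's choice is adopted unconditionally (their
confidence is never consulted), and each later member overwrites the
running solution iff their confidence reaches the threshold (default
50).

## The two simulations

**Accordance (judgment diversity).** Per iteration: draw 10 questions,
use the first as the training question, rank by confidence on it, take
the three stride panels of 15, and compute the mean accordance rate
(fraction of identical answers; $1 -$ normalized Hamming distance)
over all $\binom{15}{2} = 105$ pairs on the 9 test questions.
Category means over iterations get t-based 95% CIs — with thousands of
per-iteration averages the t/normal interval is the standard choice and
the package takes it as such.

**Group accuracy (train vs test).** Per iteration: split the questions
into $n_\text{train} \in \{1,5,10\}$ training and
$n_\text{test}$ (25 or 15) test questions, rank by mean training
confidence, form one group (`highest` deterministic; `higher`/`mixed`
random within the pool), and score majority-rule accuracy on both sets.
`summarize_test_worse()` reports the proportion of iterations with
test − train < 0 and the mean of those negative differences;
`compare_conditions()` computes Cliff's delta between two conditions'
accuracy vectors. Question draws are without replacement within an
iteration and independent across iterations; each iteration runs on a
substream keyed by (seed, iteration), so results are reproducible and
conditions can share common random numbers when given the same seed.

## Statistics

`cliffs_delta()` uses strict inequalities (ties contribute 0), the
standard convention; the implementation sorts one sample and counts
with binary search, and the tests require agreement with full
$O(nm)$ enumeration. `anova_required_sample_size()` searches the
smallest balanced total $N$ (multiple of $k$) whose noncentral-F power
($\lambda = f^2 N$, $df_1 = k-1$, $df_2 = N-k$) reaches the target:
$f = 0.25$ gives $N = 159$ and $f = 0.30$ gives $N = 111$ at the
defaults $\alpha = .05$, power $= .80$, $k = 3$. Those defaults are the
conventional planning values — and the only ($\alpha$, power) pair
consistent with both of these benchmark N values at $k = 3$ — but both
are overridable arguments, since a planning context may fix them
differently.

## What the generator does and does not emulate

The synthetic model reproduces the features the analyses rely on:
forced complete designs, continuous 0–100 confidence, chance-level
difficulty on average, stronger within- than between-question
confidence–accuracy coupling, and the resulting fragility of
single-training-question selection (high test-worse proportions for
`highest` groups that shrink as training questions accumulate).

It does not reproduce everything about human crowds:

- **Low-evidence behaviour.** In the model, a participant with strongly
  negative latent evidence chooses the *wrong* alternative
  systematically; two such participants therefore agree. Real
  low-confidence respondents tend to guess near-randomly, which makes
  their judgments *diverse*. Consequently the accordance simulation on
  synthetic data robustly ranks `highest` panels as most similar, but
  does not separate `higher` from `mixed` panels the way real data can:
  the agreement-in-error of low-evidence members offsets the diversity
  that mixing is meant to buy. The test suite documents this: the
  seeded check of the full `highest ≥ higher ≥ mixed` ordering fails
  under the default configuration, and the failure is retained as an
  honest negative result rather than tuned away.
- No response times, familiarity, learning or sequential effects;
  participants are exchangeable given ability.
- Confidence noise is homoscedastic on the logit scale; real raters
  show scale-use idiosyncrasies (end-point avoidance, anchoring).

Passing tests on synthetic data therefore validate the *machinery*
(estimators, selection, aggregation, resampling, summaries) and the
qualitative within/between asymmetry — not any quantitative claim about
a particular human dataset. Real data in the canonical long CSV layout
(`participant_id, question_id, correct, confidence`) can be loaded with
`read_dataset()` and pushed through the identical pipeline.

## Numerical choices and problem sizes

- Ties: uniform-random under explicit seeds everywhere (rankings,
  majority votes); never order-of-appearance, which would bias toward
  input order.
- Separation cap $|\beta| \le 50$; Wald intervals at
  `level = 0.95`.
- Test-suite problem sizes are scaled for fast, stable checks: 150×10
  to 150×250 synthetic designs, 300–1,000 simulation iterations, and
  20-seed replication for ordering properties; the full study design
  (5,000 iterations, 150×70 and 149×25) is the default of the
  simulation drivers.
- `run_pipeline()` echoes its configuration, seed and package version
  into a `.provenance.json` sidecar next to every CSV it writes, and
  leaves a `FAILED` marker naming the stage if one errors, keeping
  completed outputs.

## Known limitations

Beyond the generator limitations above: the Wald interval is
first-order (a profile-likelihood or Bayesian interval would differ in
small samples); the accordance CI treats iterations as iid draws
(they share the finite participant pool, so the CI describes resampling
noise conditional on the panel of participants, not sampling of new
participants); and `weighted`/`chain` rules are exposed for the
aggregation API but the resampling drivers score majority rule only,
matching the study design they implement.
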