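---
title: "Measurement models and simulation design in moralcan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and simulation design in moralcan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralcan)
```

## The measurement problem

Moral-dilemma research asks how people trade off *norms* (an action is
forbidden or favoured) against *consequences* (its benefits exceed or fall
short of its costs). The standard instrument is a battery of 24 scenarios
crossing two norm kinds with two consequence kinds — categories coded `PB`,
`PC`, `AB`, `AC` in this package (norm **P**rohibited / **A**llowed ×
**B**enefits / **C**osts dominant), six stories per cell — rated for
acceptability on a 1–6 scale or answered accept/reject. `moralcan`
implements four parameterizations of the resulting four response rates, the
covariate-adjusted association machinery used to relate them to a stressor
score such as the PSS-10, and a synthetic-cohort generator so the whole
pipeline (including its null behaviour) can be studied without access to any
particular dataset.

## The four frameworks

**Traditional score.** The acceptance proportion in the `PB` cell alone
(trolley-style dilemmas). Accepting is read as utilitarian, rejecting as
deontological. One number, and it confounds norm sensitivity, consequence
sensitivity, and response bias.

**Process dissociation (PD).** Uses the two proscriptive-norm cells. With
$p_c$ and $p_i$ the rejection rates in congruent (`PC`) and incongruent
(`PB`) dilemmas,
$$p_c = U + (1-U)\,D, \qquad p_i = (1-U)\,D,$$
so $U = p_c - p_i$ (utilitarian-driven) and $D = p_i/(1-U)$
(deontology-driven). Two parameters, two observations: the decomposition is
exact, which is why `pd_params()` followed by `pd_predict()` reproduces its
inputs to machine precision, and why the test suite checks exactly that. $D$
is undefined at $U = 1$; `pd_params()` flags this rather than dropping the
case.

**CNI processing tree.** A three-parameter multinomial processing tree over
all four cells: consequences drive the response with probability $C$,
otherwise norms with probability $N$, otherwise a generalized inaction
preference $I$ decides. `cni_fit()` maximizes the product-binomial
likelihood on $[0,1]^3$ (L-BFGS-B, multi-start: the algebraic initializer
from `cni_invert()` plus 20 seeded uniform restarts; likelihood probabilities
clipped to $[10^{-9}, 1-10^{-9}]$ so boundary values remain evaluable). Fit
is assessed by $G^2$ against the saturated model on 1 df (4 cells, 3
parameters). Participants with $G^2$ p-value below 0.05 are flagged for
exclusion — a *small* goodness-of-fit p-value indicates misfit; the source
convention this mirrors prints the inequality the other way round, which we
read as a typo and document here rather than silently adopt. Parameters
within $10^{-6}$ of 0 or 1 are flagged as boundary estimates instead of
being excluded; at $\hat C = 1$ the likelihood no longer depends on $N$ and
$I$, so they are explicitly reported as unidentified.

**CAN decomposition.** Three orthogonal contrasts of the four cell values
$v_t$, computable algebraically on either scale:
$$C = \tfrac{(v_{PB}+v_{AB}) - (v_{PC}+v_{AC})}{2},\quad
  N = \tfrac{(v_{AB}+v_{AC}) - (v_{PB}+v_{PC})}{2},\quad
  A = \tfrac{v_{PB}+v_{PC}+v_{AB}+v_{AC}}{4}.$$
On binary data $C, N \in [-1,1]$ and $A \in [0,1]$; on raw 1–6 ratings the
parameters stay in rating units ($C, N \in [-5,5]$, $A \in [1,6]$, neutral
at 3.5) — deliberately no renormalization, so a reported $A$ of, say, 3.7
reads directly as "slightly action-prone on the rating scale".

For noise-free profiles generated by the tree the two multi-parameter
frameworks are linked by exact identities,
$$C_{can} = C,\qquad N_{can} = (1-C)\,N,\qquad
  A_{can} = \tfrac{C}{2} + \tfrac{(1-C)N}{2} + (1-C)(1-N)(1-I),$$
which the test suite verifies on an $11^3$ parameter grid. These bridges are
also what the recovery study uses as the CAN truth values.

## Association statistics and power conventions

`partial_correlation()` residualizes both variables on an intercept plus the
covariates by least squares and correlates the residuals; the p-value uses
$t = r\sqrt{df}/\sqrt{1-r^2}$ with $df = n - 2 - k$. Effect sizes convert by
$d = 2r/\sqrt{1-r^2}$ and group contrasts by the pooled-SD Cohen's $d$.

Power conventions are explicit because published reports rarely state them:
t-test powers use the noncentral-t distribution and default to two tails
(one-sample $ncp = d\sqrt{n}$; two-sample $ncp = d\sqrt{n_1 n_2/(n_1+n_2)}$);
correlation powers use the Fisher-z approximation with $SE =
1/\sqrt{n-k-3}$ and default to one tail. These two defaults jointly
reproduce the published power values this package's acceptance checks
recompute (0.87 for the two-sample contrast at $d = 0.44$, $n = 92/105$;
1.00 for the one-sample test at $d = 0.52$, $n = 208$; 0.40 for $r = 0.10$,
$n = 197$ with one covariate). Both are flags (`tails=`), not assumptions
baked in. A related documented wrinkle: the pooled $d$ computed from the
printed two-decimal group summaries is 0.43, while 0.44 evidently comes from
unrounded inputs; both are noted in `pooled_d()`'s tests.

## Scale scoring and screening

PSS items are scored 0–4 and summed after reverse-scoring the positive
items; the reverse keys default to positions {4,5,7,8} (PSS-10) and
{4,5,6,7,9,10,13} (PSS-14) — the standard instrument keying — and are
configurable because deployments vary. The 13-item social-desirability scale
is scored as the count of key-matching responses with no default key claimed
to be the instrument's true key; the generator defines its own. Screening
excludes, in order: recent acute stress, an incomplete battery, a failed
attention check — one logged reason per participant, full-case exclusion, no
imputation. `median_split()` implements the high/low dichotomization with a
deterministic tie policy (ties to the low group by default) purely so the
practice it represents can be studied; the package's own analyses use
continuous scores.

One terminological choice: "norm-allowed" categories are treated as
*prescriptive* norms (the norm favours action), matching the standard
24-scenario battery design. If a battery with merely permissive norms is
analysed, the sign of norm-sensitivity contrasts retains its algebraic
meaning but the substantive reading changes.

## The synthetic cohort generator

`draw_participants()` ties everything to one latent standard-normal chronic
stress score per participant:

* PSS-10 total $= \mathrm{round}(\mathrm{clip}(\mu + \sigma z, 0, 40))$ with
  defaults $\mu = 12.15$, $\sigma = 6.84$, matching the descriptive
  statistics of the replication-scale cohort the generator emulates. Totals
  are decomposed into item scores by a greedy even spread (remainder on
  early items), then reverse-keyed items are flipped, so `score_pss()`
  recovers the total exactly.
* Decision parameters are drawn on the logit scale:
  $\mathrm{logit}(P) = b_P + c_P z + \epsilon_P$, $\epsilon_P \sim N(0,
  s_P)$, with base means $\mathrm{logit}(0.2), \mathrm{logit}(0.25),
  \mathrm{logit}(0.41)$ for $C, N, I$ (echoing typical published means) and
  SDs of 0.5 logits. The coupling slopes $c_P$ default to **zero**: stress
  and moral parameters independent, the null regime. Nonzero couplings turn
  the same machinery into a power study.
* Demographics (age mean 32.07, SD 12.35, range 17–89; 56.7% female) are
  realistic set dressing; nothing downstream depends on them.

Binary responses are Bernoulli draws from the participant's tree cell
probabilities. Likert responses use a probit latent-threshold model: latent
acceptability $\Phi^{-1}(p) + \epsilon$, $\epsilon \sim N(0, \sigma_L)$, cut
at five thresholds into ratings 1–6. The default thresholds
$(-1.8, -0.8, 0, 0.8, 1.8)$ put the 3/4 boundary at 0 and the default
$\sigma_L = 1$, which makes the recoded accept indicator *exactly*
Bernoulli($p$): dichotomized analyses of the simulated ratings see precisely
the binary tree, so the two arms of the dichotomization study differ only in
scoring, never in the underlying cohort. As $\sigma_L \to 0$ the rating
deterministically lands on the side of 0.5 on which $p$ falls.

What the generator does **not** emulate: story-level difficulty effects,
response times, order effects, acute-stress dynamics, or any dependence
between items beyond the shared person parameters. Passing tests therefore
demonstrate the estimators' and tests' behaviour under the model's own
assumptions — item-exchangeable tree responses — not robustness to the full
texture of real response data.

## The simulation studies and problem sizes

`run_dichotomization_study()` simulates Likert cohorts (208 participants by
default), analyses each cohort twice — CAN on recoded accept/reject values
vs. CAN on raw mean ratings — and tests the PSS correlation of each
parameter at $\alpha = 0.05$. Under null coupling both arms are calibrated
tests of a true null, so both rejection rates should sit near $\alpha$; the
acceptance suite runs 2,000 replicates and checks the continuous arm's rate
within two binomial Monte-Carlo standard errors, the uniformity of its
p-values (Kolmogorov–Smirnov at $\alpha = 0.01$), and that the dichotomized
arm does not reject *less* (the direction of the claim that dichotomization,
which discards information, cannot be the safer choice). Cohorts are shared
between arms by construction (same seeds), isolating the scoring effect.

`run_recovery_study()` draws per-category counts from known $(C, N, I) =
(0.2, 0.25, 0.4)$, refits both frameworks, and reports bias and RMSE at 6,
24, and 96 items per category (500 replicates in the acceptance suite).
Expected behaviour: cohort-mean CNI bias within $\pm 0.02$ at 96
items/category, and RMSE strictly decreasing in items per category for all
three tree parameters. The 24→96 comparison also shows concretely why
6-item-per-cell batteries produce noisy individual-level tree estimates.

These replicate counts and cohort sizes were chosen as the smallest sizes at
which the binomial/KS tolerances above are meaningful; they complete in a
few minutes on a single core.

## Numerical and design choices

* Tree cell probabilities are clamped to $[0,1]$ against floating-point
  overshoot at algebraic boundaries (e.g. $I = 0$ makes a cell sum exactly 1).
* `cni_invert()` marks a profile feasible only if the recovered parameters
  are in the cube *and* the forward model reproduces all four inputs
  (tolerance $10^{-8}$): with four observations and three parameters, some
  in-range contrast combinations lie off the model manifold. Division-by-zero
  branches return the infeasible marker instead of raising, so the
  initializer can always fall back to interior starting values.
* The optimizer's restart draws use a fixed internal seed, making every fit
  deterministic for given counts.
* Master seeds split into per-stage child seeds via a 31-bit polynomial hash
  of the stage label (`child_seed()`), so any pipeline stage can be re-run in
  isolation with the stream it originally saw.
* Participant-level CNI fits that fail outright (optimizer non-convergence)
  are tallied separately from poor-fit exclusions, mirroring the distinction
  between "error reports" and fit-based exclusion in published workflows.
* All analysis functions are deterministic given their inputs; randomness
  enters only through the generator and study drivers, each of which takes
  an explicit seed.

## Known limitations

* Only the three contrasts $C$, $A$, $N$ of the CAN family are implemented;
  published extensions with additional parameters are out of scope.
* No hierarchical or Bayesian tree estimation; individual-level maximum
  likelihood with 24 items is intentionally shown (by the recovery study) to
  be noisy.
* The PSS-14 generator scales the 10-item latent total rather than modelling
  four extra items; it exists so 14-item scoring paths can be exercised, not
  as a claim about the instrument.
* The dichotomization study speaks to Type I calibration and the information
  cost of median-splitting under this generator; it does not reproduce any
  specific published correlation, which would require the original raw data.
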