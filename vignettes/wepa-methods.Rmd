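---
title: "Measuring psychological constructs by semantic projection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring psychological constructs by semantic projection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wepa)
library(dplyr)
```

## The measurement model

`wepa` scores short user-generated texts on theory-defined psychological
constructs by projection in a static word-embedding space. A construct (say,
goal commitment) is represented as a *bipolar semantic axis*: two sets of
anchor words describe its opposing poles (determination, persistence,
follow-through versus delay, hesitation, disengagement). Each pole's
*prototype* is the centroid of its anchors' embedding vectors,

$$\mathrm{proto}_d = \frac{1}{|A_d|}\sum_{a \in A_d}\mathrm{Embed}(a),
\qquad d \in \{\mathrm{pos}, \mathrm{neg}\},$$

and the *axis* is the unit-normalised prototype difference,

$$\mathrm{axis} = \frac{\mathrm{proto}_{\mathrm{pos}} -
\mathrm{proto}_{\mathrm{neg}}}
{\lVert \mathrm{proto}_{\mathrm{pos}} - \mathrm{proto}_{\mathrm{neg}}\rVert}.$$

A text with cleaned token multiset $W$ is represented by the mean of *all*
its token vectors,

$$\mathrm{text} = \frac{1}{|W|}\sum_{w \in W}\mathrm{Embed}(w),$$

where out-of-vocabulary tokens contribute zero vectors but remain in the
denominator — low-coverage texts are deliberately pulled towards the neutral
point rather than dropped. The construct score is the scalar projection
$\mathrm{text} \cdot \mathrm{axis}$. Positive values indicate language closer
to the positive pole; magnitude indicates deviation from neutrality. The
score measures *expressed construct salience* in language, not the latent
psychological state itself.

The closed-vocabulary baseline is the damped dictionary ratio
$(h_+ - h_-)/(h_+ + h_- + 1)$, where $h_\pm$ count the distinct anchor
*types* the text shares with each pole. It is transparent but covers only
texts containing at least one anchor word; the projection score covers every
non-empty text. Both scorers use identical anchor sets, so comparisons
isolate the scoring rule.

## Why these choices

**Vectors are used as stored.** Normalisation happens only where the model
requires it (the axis): the text vector averages raw vectors, so token
vectors with larger norms legitimately carry more weight.

**Type counting in the baseline.** The dictionary ratio counts word types
(set intersection), not occurrences; occurrence counting is available via
`dictionary_score(count = "tokens")`. A text consisting of $k$ copies of one
positive anchor scores $1/2$ under the baseline regardless of $k$, while its
projection equals that anchor's own projection — a documented divergence
between the scorers.

**Missing versus zero.** A projection score is missing only for empty token
lists; a text of pure OOV tokens scores 0. An uncovered text's dictionary
score is treated as missing for coverage statistics; `benchmark_agreement()`
supports both dropping uncovered texts and scoring them 0, since either
convention is defensible when correlating with labels.

**Week bucketing.** User-weeks are 7-day windows anchored at each user's
registration date (`week_index = floor(days since registration / 7)`), not
ISO calendar weeks, so relative-week trajectories align users by tenure.

**Cleaning rules.** URLs are tokens containing `://` or starting `www.`; a
nonlinguistic token has no letter in any script (the Unicode letter class
covers CJK); one-character tokens are dropped. These are artifact
conventions — the categories are standard, the exact patterns are not
prescribed anywhere — and the segmenter is injected so Chinese text can use
a proper word segmenter while tests use the deterministic whitespace
tokenizer. An optional stop-word list is applied after the structural rules;
it defaults to empty because stop lists are language-specific.

## Cross-temporal stability

Scores are longitudinally comparable only if the measurement direction is
stable. Period-specific embedding spaces are aligned to a reference space by
orthogonal Procrustes — the orthogonal transform (rotations and reflections,
no scaling or translation) minimising the Frobenius mismatch over a shared
vocabulary, solved by SVD of the cross-covariance. Two indicators are then
reported per construct and period: the cosine between the period axis and
the reference axis (direction stability) and the Spearman correlation of
anchor projections in the two spaces (internal rank-order stability). The
default fitting vocabulary is the intersection of the two vocabularies
restricted to the first 5000 reference tokens, unweighted; the reference
vocabulary order is treated as the frequency order. Anchors are screened per
space, and anchors missing from a sparse period are dropped from that
period's rank test and reported.

## Criterion-validity panel

The behavioral criterion is log weekly exercise minutes, $\ln(x+1)$. The
estimating equation regresses next week's outcome on this week's construct
score with individual fixed effects,

$$\mathrm{ExDur}_{i,t+1} = \alpha + \beta\,\mathrm{Construct}_{i,t} +
\gamma\,\mathrm{Controls}_{i,t} + \mu_i + \epsilon_{i,t},$$

estimated by the within transformation (entity demeaning) with one-way
cluster-robust standard errors at the user level, small-sample correction
$\tfrac{G}{G-1}\cdot\tfrac{N-1}{N-K}$ with the absorbed user means counted
in $K$. The lead is strict: a row enters estimation only when the same user
is observed in the immediately following week — bridging gaps would change
the estimand. Continuous predictors are winsorized at the 1st/99th
percentiles (both tails) and z-standardized over the rows being prepared;
the outcome is never standardized, so with a log outcome a coefficient
$\beta$ on a standardized predictor translates to a semi-elasticity
$100(e^{\beta}-1)$ percent per SD, or $\bar m (e^{\beta}-1)$ minutes per
week against a raw reference mean $\bar m$. Standardization is computed
after winsorization on the sample being prepared, making coefficients
per-SD effects in the fitted sample. The self-efficacy composite is the sum
of its four source-dimension scores, formed on raw projections before any
scaling.

Supporting diagnostics: VIFs from auxiliary regressions and condition
indices of the standardized design; a normal z-test for subgroup coefficient
differences; relative-week trajectories (full-sample standardization, per
relative-week means, centered 3-week moving average whose window shrinks at
the series edges — endpoints are kept rather than dropped); textual-sparsity
strata on the count of valid tokens (at least 5; the short stratum
$(0, 20)$; the long stratum $[20, \infty)$, with the boundary in the long
stratum); and an anchor-perturbation sweep that removes 1–3 random
positive–negative anchor pairs, rebuilds the axis, rescores and refits,
reporting percent deviations from the unperturbed coefficient.

## Measurement-error correction

Projection scores are noisy proxies, so naive coefficients are attenuated.
`simex_fe()` implements simulation–extrapolation: for each multiplier
$\lambda \in \{0, 0.5, 1, 1.5, 2\}$ it adds $B = 30$ independent draws of
$N(0, \lambda\sigma^2_u)$ noise to the standardized focal score (controls
are treated as error-free), refits the fixed-effects model, averages the
focal coefficient per $\lambda$, fits an unweighted quadratic to the mean
path by ordinary least squares, and evaluates it at $\lambda = -1$. The
attenuation statistic is
$(|\beta_{\mathrm{naive}}| - |\beta_{\mathrm{simex}}|)/
|\beta_{\mathrm{simex}}| \times 100$.

The error variance $\sigma^2_u$ is an explicit input — supplied directly or
derived from a reliability ratio via
`error_variance_from_reliability()` — because no principled internal
estimate exists for projection scores; surfacing the assumption in the
interface seemed more honest than hiding a default. The whole procedure is
deterministic given the configuration seed. Jackknife or asymptotic SIMEX
standard errors are not provided.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a full scenario: for each construct a random
unit direction is planted in a $d$-dimensional space; positive and negative
anchors are drawn isotropically around $\pm\delta/2$ along it; the rest of
the vocabulary is isotropic around the origin. Per user-week a latent
intensity $z \sim N(0,1)$ tilts token draws towards the matching pole's
anchors, and — with weight `filler_alignment` — towards non-anchor tokens
whose own axis position matches $z$. That last feature emulates
construct-related vocabulary beyond the anchor lists, which is precisely
what projection scoring aggregates and exact matching misses; without it a
synthetic dictionary baseline is unrealistically strong. The outcome follows
$\mathrm{ExDur}_{i,t+1} = \alpha_i + \beta z_{i,t} + \epsilon$ on the log
scale, and the hidden truth ($z$, $\alpha$) is returned for recovery tests.
Token streams are emitted as raw posts and pushed through the corpus
cleaning path, so the cleaning rules are exercised end to end.

Reference conditions (the generator defaults): $d = 50$, vocabulary 500,
$\delta = 3$, within-pole sd 0.5, 8 + 8 anchors, 300 users, 8 weeks, 20–60
tokens per user-week, signal strength 0.35, filler alignment 1, true effect
0.5, unit fixed-effect and noise sds. All randomness flows from one
mandatory seed through fixed per-generator offsets, so adding a generator
never perturbs existing outputs.

What the fixtures do *not* emulate: real morphology and segmentation
(tokens are synthetic ASCII), polysemy and context dependence, topic
structure, user heterogeneity in vocabulary, attrition correlated with the
construct, and platform feedback loops. Passing the synthetic recovery
suite therefore shows the *machinery* is correct under the stated model; it
does not certify measurement validity on any real corpus, which requires
the anchor diagnostics, human-benchmark comparison and stability analysis
on that corpus.

## Numerical conventions

Axis construction rejects identical prototypes (zero-norm difference);
cosine similarity rejects zero-norm inputs and clamps rounding just past
$\pm 1$; neighbour ties are broken by vocabulary order; Procrustes warns
when the shared vocabulary is smaller than the dimension; the within
estimator drops users contributing a single estimation row, rejects
regressors constant within every user by name, and declares the demeaned
design singular below a reciprocal condition number of $10^{-12}$;
winsorization uses type-7 quantiles; quadratic SIMEX extrapolation requires
at least three grid points.

## Validation problem sizes

The test-suite's simulation checks use the reference scenario above for
end-to-end recovery (100 seeds; a significant positive focal coefficient is
expected in at least 95 of them), 50 classical errors-in-variables
replications at reliability 0.7 with 500 users over 8 weeks for the SIMEX
improvement check, 200 replications of a 120-user, 6-week panel for
clustered-CI coverage, and small (tens of tokens, dimensions 5–20) spaces
for the deterministic oracle equivalences. These sizes give stable Monte
Carlo rates while keeping the default test run quick.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 42)
fx <- make_space(spec)
pn <- make_panel(spec, fx$space, fx$anchors)

pole_diagnostics(fx$anchors, fx$space)

uw <- aggregate_weeks(pn$posts, pn$registrations) |>
  filter_panel(pn$registrations)
axes <- build_axes(fx$anchors, fx$space)
scores <- score_texts(uw, axes, fx$space)

merged <- pn$panel |>
  inner_join(select(scores, user_id, week_index, wepa_score),
             by = c("user_id", "week_index")) |>
  mutate(score_z = as.numeric(scale(wepa_score)))
rows <- lead_outcome(merged)
fit <- fe_regression(rows, "ExDur_lead", focal = "score_z")
tidy(fit)

cfg <- simex_config(sigma2_u = 0.2, seed = 1)
simex_fe(rows, "ExDur_lead", focal = "score_z", config = cfg)
```

## Known limitations

Scores are expressed-salience indicators, not latent-state measurements;
fixed-effects associations are predictive, not causal. The dictionary
baseline's uncovered-text convention materially affects its benchmark
correlation, and both conventions are provided because the right one is
context-dependent. SIMEX output is only as good as the assumed error
variance. The shipped anchor dictionary
(`inst/extdata/anchor_glosses_demo.csv`) contains English glosses intended
for demonstration; applying the method to a real corpus requires
theoretically grounded, expert-validated anchor lists in the corpus
language, and the anchor screening, pole diagnostics and stability reports
exist precisely to audit that step.
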