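---
title: "Measuring response styles with the multidimensional nominal response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring response styles with the multidimensional nominal response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnrm)
```

## The measurement problem

Likert-type items confound two things: the respondent's standing on the
substantive construct, and *how* the respondent uses the response scale.
Some people gravitate to the endpoints (extreme response style, ERS),
others to the midpoint (MRS).  The traditional remedy is a recoded sum
score — count the endpoint responses — but such counts are confounded
with content: a person genuinely extreme on the trait also produces many
endpoint responses, so trait and style mix.

This package implements a model-based alternative.  Each item response
is treated as a multinomial outcome whose category log-odds are linear
in several latent traits at once, with the analyst choosing, per
dimension, a *scoring function* — a fixed numeric code per category —
that plays exactly the role of the recode used for sum scores.

## The model

Person $i$ gives response $y_{ij} \in \{0, \dots, K_j - 1\}$ to item
$j$.  With latent traits $\mathbf{x} = (x_1, \dots, x_D)$, the category
response function is the multinomial logit

$$
T(k \mid \mathbf{x}) =
\frac{\exp\!\big(\textstyle\sum_d a_d\, s_{kd}\, x_d + c_k\big)}
     {\sum_m \exp\!\big(\textstyle\sum_d a_d\, s_{md}\, x_d + c_m\big)},
$$

where $a_d$ is the item's overall slope on dimension $d$, $c_k$ a
category intercept with $c_0 = 0$, and $s_{kd}$ the fixed scoring code
of category $k$ on dimension $d$.  The log-odds of category $k$ over
$k'$ is linear in every trait with coefficient $a_d (s_{kd} - s_{k'd})$,
so scoring functions control *which comparisons* each trait can move:
with ERS codes $[1,0,0,0,0,0,1]$ the style trait cancels entirely from
comparisons among non-endpoint categories and between the two endpoints.

Typical codes are $0..K-1$ for a substantive trait (the generalized
partial credit convention), endpoint indicators for ERS, and a midpoint
indicator for MRS.  Codes are unitless; rescaling a code vector rescales
the slope inversely (`reparameterize()` verifies the invariance), so
slopes are interpretable only jointly with their codes.  Latent traits
have fixed mean 0 and variance 1; their correlations are free
parameters.

**Identification.** Per item, the matrix $[\mathbf{1}, \mathbf{s}_1,
\dots, \mathbf{s}_D]$ must have full column rank, otherwise one
dimension is an affine recoding of the others (e.g. adding
$[0,1,1,1,1,1,0]$ next to ERS).  `scoring_set()` enforces this with a
relative singular-value tolerance of $10^{-8}$; the threshold is a
numerical-rank convention, chosen once, since the requirement itself is
qualitative.

## Estimation

`fit_mnrm()` maximizes the marginal likelihood by EM over a fixed
rectangular quadrature grid:

* **E-step.** Posterior weights of each person over the grid nodes, and
  expected category counts $r_{jk}(\mathbf{x})$ per item and node.
* **M-step (items).** Each item's expected multinomial log-likelihood
  is maximized over $(a_j, c_j)$ by Newton–Raphson with analytic
  gradient and Hessian, with step-halving whenever a step would decrease
  the expected log-likelihood.
* **M-step (correlations).** The latent correlation matrix is updated
  from posterior second moments across persons, renormalized to unit
  diagonal and projected to the nearest correlation matrix if
  indefinite; grid weights are rebuilt.  Because the unit-diagonal
  constraint makes this update approximate, the marginal log-likelihood
  is re-checked and the update reverted on the rare occasions it would
  decrease it — the reported trace is therefore nondecreasing.

Defaults, all overridable: 21 nodes per dimension on $[-5, 5]$ for
$D \le 2$ (15 for $D = 3$) during estimation; convergence when the
log-likelihood changes by less than $10^{-5}$, at most 500 cycles.
Scoring uses the finer convention of 49 equally spaced nodes on
$[-6, 6]$.  The coarser estimation grid is a deliberate accuracy/cost
trade-off: the test suite asserts that doubling the node count moves the
deviance by under 0.5%.  Starting values are slopes of 1.0 on the first
(substantive) dimension and 0.5 on style dimensions, intercepts from log
observed category proportions, identity correlations; a warning is
issued if a dimension's mean slope changes sign relative to its start
(factor reflection).  An `equal_slopes = TRUE` constraint fits the
partial-credit-style model in which every item shares one slope vector —
the unique case whose pattern EAPs are a monotone function of sum
scores.

Free-parameter counts are $\sum_j (D + K_j - 1)$ (or $D + \sum_j (K_j -
1)$ under equal slopes) plus $D(D-1)/2$ estimated correlations;
`fit_indices()` turns the deviance into AIC/BIC and `lr_test()` compares
nested fits.  Item-parameter standard errors are not computed — accurate
standard-error estimation for this model class is its own research topic
and no single default is safe; score standard errors *are* provided,
since they follow directly from the posterior.

## Scoring

Three routes, deliberately kept comparable:

1. **Sum scores** (`sum_scores()`): recode and add.  Persons with
   missing items receive the sum over observed items plus an explicit
   missing count — no imputation or proration, since any such rule would
   be a modeling decision in disguise.
2. **Pattern EAPs** (`pattern_eap()`): posterior mean and SD per
   dimension given the full response pattern, by quadrature.
3. **Sum-score EAPs** (`translation_table()`, `score_by_sum()`): the
   posterior mean given *only* the sum score.  The summed-score
   likelihood $L_d(v \mid \mathbf{x})$ is accumulated item by item with
   the polytomous Lord–Wingersky recursion over each item's *collapsed*
   response function (category probabilities summed within equal scoring
   codes); multiplying by the grid weights, summing out the nuisance
   dimensions, and taking node moments gives $p(v)$, $E(\eta \mid v)$
   and $V(\eta \mid v)$.

The recursion keys sums on their exact values (matched after rounding at
$10^{-9}$), so non-integer scoring codes work; it reduces to the
collapsed response function for a single item, and the tests verify it
against exhaustive enumeration of all $K^n$ patterns on three-item
models at $10^{-12}$.  Unattainable sum scores are reported with zero
probability and `NA` moments rather than divided by.  When dimensions
have different scoring functions, one translation run per target
dimension is performed; the model itself never changes between runs.
Reports round to 3 decimals; storage is full precision.

`compare_scores()` assembles all three scores per person with their
Pearson and Spearman correlations — the workflow that exposes the
U-shaped trait/ERS confounding of sum scores.

## The simulator

`make_style_study()` draws latent traits from a correlated multivariate
normal, then responses from the model's category probabilities.  Default
conditions describe a realistic single-construct battery: N = 1000
persons, 20 seven-category items, one substantive trait plus ERS,
uncorrelated by default; substantive slopes uniform on $[0.3, 1.0]$,
style slopes on $[0.5, 1.5]$, and unimodal intercept profiles with
additive noise, matching the magnitudes of published quality-of-life
calibrations.  Sub-seeds for items, traits, and responses derive
deterministically from the design seed, so every fixture is exactly
reproducible.

What the simulator does *not* emulate: multiprocess or unfolding
response mechanisms, person-specific scale drift, local dependence among
items, or content multidimensionality.  Passing recovery tests therefore
show that the estimator inverts its own generating law at realistic
sizes — not that real questionnaire data satisfy that law.

## Numerical choices

* Softmax probabilities use max-subtraction; logits up to $\pm 700$ are
  safe, covering slope–code–trait products far beyond the $[-6, 6]$
  grid.
* Categories are indexed $0..K-1$ throughout, with the category-0
  intercept fixed at 0.  Published parameter tables sometimes label the
  same intercepts $c_1..c_K$; the values are identical and one
  convention avoids off-by-one bugs.
* Scoring vectors are taken literally as given — no internal
  normalization — so slopes always refer to the user's codes.
* Collapsed response values are reported in ascending numeric order.
* The anchored-last-category convention of some programs is supported in
  `reparameterize(reference = "last")`; internally intercepts stay
  referenced to category 0, with the offset recorded, since the two
  parameterizations give identical probabilities.

## Problem sizes used in the test suite

Worked-example checks run on the built-in three-item fixture and its
$3 \times 3$ grid.  Recovery is demonstrated once at N = 2000 with 20
items and two dimensions (slope RMSE under 0.15, correlation error under
0.05), with smaller seeded fits (N = 250–700, 6–10 items) carrying the
monotonicity, multi-start, grid-refinement, and oracle-agreement
properties.  These sizes were chosen as the smallest designs at which
the respective properties are informative.

## Known limitations

* No item-parameter standard errors or limited-information fit
  statistics (C2/RMSEA/TLI); model comparison is by deviance, AIC/BIC,
  and likelihood-ratio tests of nested fits.
* Fixed rectangular quadrature limits practical dimensionality to about
  three; no adaptive quadrature or stochastic approximation.
* All items are assumed to load on every style dimension named in the
  scoring set; styles confined to item subsets require zero slopes
  rather than structural absence.
* Every published worked value this package reproduces was printed from
  parameters rounded to two decimals, so recomputed table cells can
  differ from print by up to ~0.005 (2-dp tables) or ~0.003 (3-dp
  tables); the tests assert at exactly these rounding-propagation
  bounds.
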