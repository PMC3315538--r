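---
title: "Interval coded scoring: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval coded scoring: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Clinical decision support lives in a tension between performance and
usability: flexible classifiers discriminate well but cannot be applied at
the bedside, while hand-made point charts are usable but lose information
through arbitrary binning.  `icscore` fits an additive classifier whose
per-variable effects are *step functions*, and where the number, position
and height of the steps are chosen by the optimizer rather than by the
analyst.  Because the fitted effects are constant on intervals, the model
converts losslessly into a questionnaire: each non-baseline interval is a
yes/no question worth an integer number of points, the points sum to a
score, and a monotone link maps the score to an event risk.

For patient $i$ with covariates $x_{i1},\dots,x_{iP}$ and outcome
$y_i \in \{-1,+1\}$, the decision function is

$$ f(x_i) = \sum_{p=1}^{P} \sum_{j} w_{pj}\, \mathbf 1[x_{ip} \in I_{pj}] + b, $$

where the intervals $I_{pj}$ of a continuous variable are the half-open
cells $(-\infty,\theta_1), [\theta_1,\theta_2), \dots, [\theta_K,\infty)$
of a dense candidate threshold grid (left-closed, so chart rows read
"between 40 (included) and 60").  Categorical variables get one indicator
per level and binary variables a two-level block.  Training minimizes

$$ \sum_i \max(0,\, 1 - y_i f(x_i))
   \;+\; \gamma \sum_{p,j} u_{pj}\, |w_{p,j+1} - w_{pj}|, $$

a hinge loss plus a total-variation (fused-lasso) penalty on adjacent
interval coefficients; for categorical blocks, where levels have no order,
each non-reference level is penalized against the reference instead of
against its neighbour.  The penalty fuses adjacent intervals (equal
coefficients merge into one chart row) and deletes variables (a block fused
to the reference contributes nothing), so interval selection and variable
selection happen inside one convex problem.

Two identifiability conventions are applied throughout.  First, because
each block's indicators sum to one, a constant can move between any block
and the intercept without changing predictions; the reference (first)
interval of every block is therefore pinned at weight zero ("gauge
fixing"), which also makes the chart's baseline answers worth 0 points.
Second, the quadratic term of the classical linear SVM is dropped: with
the total-variation penalty the problem is an exact linear program, and a
`ridge` argument (default 0) is available when a unique solution is wanted.

## Solving the linear program

With fixed penalty factors $u$ the training problem is an LP.  No
general-purpose LP solver is available to this package, so it ships its
own primal-dual interior-point method (Mehrotra predictor-corrector)
specialised to the problem's structure: eliminating the hinge slacks and
TV auxiliaries analytically reduces each Newton step to a
$(d{+}1)\times(d{+}1)$ normal-equation solve, where $d$ is the number of
non-reference columns — so the cost per iteration is $O(nd^2)$ regardless
of the $2n + 2m$ constraints, and a 2000-patient, 90-column fit takes a
fraction of a second.  The objective is internally rescaled so cost
coefficients are $O(1)$ even when reweighting drives penalty weights to
$10^2\gamma$.  Convergence is declared at a relative duality gap and
residual norms below $10^{-9}$ ($10^{-7}$ for cross-validation refits,
which only need to rank candidates).

Two forms of solver validation are built into the test suite.  The
objective attained by the interior-point method is compared, on dozens of
random small instances, against an independent dense simplex
(`boot::simplex`) run on the LP dual — equal optima by strong duality —
to $10^{-6}$.  A second user-selectable backend (`solver = "simplex"`)
solves an origin-feasible primal reformulation with the same simplex code
and must agree too; being a vertex method it is exact but only practical
for small instances.

One numerical property of interior-point methods matters downstream: when
the LP optimum is non-unique the iterates converge to the *analytic
centre* of the optimal face, which spreads a step over several adjacent
candidate cuts and leaves sub-tolerance residue on coefficients whose
optimal value is zero.  Coefficients at or below `zero_tol = 1e-3` (on the
margin scale, where retained effects are order 0.1–2) are therefore zeroed
before charts are built, margins are compared, or cross-validation ranks
candidates; without this an all-zero model can appear to discriminate
through $10^{-5}$-scale residue.

## Reweighting: sharpening the fusion

The plain TV penalty can retain small, clinically irrelevant intervals.
Following the reweighted-$\ell_1$ idea, the model is refit with factors

$$ u_{pj} = \frac{1}{|\Delta w_{pj}| + \varepsilon_c}, $$

so small differences are penalized harder on the next pass, iterating
until the coefficients move less than `tol` (default $10^{-4}$, cap
`max_iter = 50`).  $\varepsilon_c$ controls aggressiveness: large values
leave the fit essentially unweighted, small values drive hard fusion.

`select_eps_c()` implements the selection rule for $\varepsilon_c$: among
candidates whose 5-fold cross-validated AUC, Bernoulli likelihood and
Nagelkerke $R^2$ stay within slacks (defaults 0.01, 2% relative, 0.02) of
the unweighted model's, pick the one with fewest chart intervals; if none
qualifies, fall back to the best-AUC candidate with a warning.  The
candidates (default ladder 1, 0.3, 0.1, 0.03, 0.01) are visited from mild
to sharp, each level warm-started from the previous level's solution.
This continuation matters because of the analytic-centre behaviour above:
a cold start from a spread-out solution prices every position of a true
jump highly and tends to delete whole variables, whereas after a mild pass
the jump has concentrated onto one boundary, which then survives sharper
levels cheaply.  Within the selection path the inner loop is capped at 8
passes — warm starts converge in a few — which also bounds the cost of
oscillating reweighting fixed points (the iteration is not guaranteed to
converge; non-convergence is reported as a flag, not an error).

## From coefficients to the chart

The fitted weights are anchored (reference intervals exactly zero, the
shifts absorbed into the intercept — predictions unchanged), divided by
the smallest non-zero absolute weight so the weakest retained effect is
worth one point, and rounded to the nearest integer with exact halves
rounded away from zero.  The normalizer is computed on the raw anchored
weights, before any merging.  Adjacent intervals with equal rounded points
merge, so the rendered questionnaire is minimal.  The intercept never
appears in the chart; it is absorbed by the link function's domain.

The score-to-risk link is estimated by weighted pool-adjacent-violators
isotonic regression on the per-score event fractions (`stats::isoreg`
takes no weights, so the pooling loop is implemented here and tested
against a dynamic-programming oracle).  An optional `"smoothed"` variant
first applies a Gaussian kernel smoother whose bandwidth minimizes the
cross-validated Bernoulli deviance, then restores monotonicity.  Fitted
risks are clipped to [0.001, 0.999]: a paper chart should say "<0.001",
not promise certainty.  The lookup table evaluates the link at every
attainable integer score, rounds to 2 decimals and merges equal rows.

## Tuning $\gamma$

`cv_select_gamma()` chooses the fusion penalty from a default grid of 13
log-spaced values covering $10^{-3}$ to $10^{3}$ per patient, by 10-fold
stratified cross-validated AUC, ties to the larger (sparser) $\gamma$.
Held-out folds are scored with the *rounded chart*, not the real-valued
margin: the chart is what the model delivers, and margins of a degenerate
LP face can rank patients on numerically meaningless residue.  Folds are
a pure function of (outcome vector, k, seed); a draw that strands a class
in one fold is redrawn with a warning.  $\gamma$ is selected once, before
reweighting, and not re-tuned inside the $\varepsilon_c$ selection.

## Evaluation toolbox

Discrimination is the Mann–Whitney AUC (ties count ½), with a
bias-corrected (BC, no acceleration term) percentile bootstrap CI over
1000 patient resamples; single-class replicates are redrawn.  Explained
variance is Nagelkerke's likelihood-ratio $R^2$ against the prevalence
model, risks clipped to $[10^{-6}, 1-10^{-6}]$.  Calibration sorts
patients by predicted risk into contiguous equal-count groups of at least
10% of the data (remainder to the last group), reporting per-group mean
prediction, observed fraction and exact Clopper–Pearson 95% intervals,
plus the calibration-in-the-large ratio mean(predicted)/prevalence.  The
decision cutoff maximizes specificity subject to a sensitivity floor
(default 0.90), ties to the larger cutoff; the 2×2 block reports
sensitivity, specificity, LR±, and the diagnostic odds ratio with a
log-normal CI (0.5 continuity correction on empty cells).

For comparison, `build_classical_score_system()` builds the traditional
Sullivan-style chart: an ordinary logistic fit on the raw variables,
user-chosen fixed-width intervals, the effect at each interval midpoint
divided by the smallest effect and rounded.  Its interval placement is a
user guess — precisely the step the interval-coded approach automates.

## The synthetic cohort generator

`generate_cohort()` draws covariates from declared distributions, forms a
piecewise-constant additive log-odds surface, and draws Bernoulli
outcomes; `bayes_auc()` reports the cohort's discrimination ceiling (the
AUC of the true risks).  The default `staircase_spec()` has two
informative continuous variables with two breakpoints each (level effects
of magnitude 1–2 on the log-odds), one informative binary variable, three
irrelevant variables, and an intercept giving ≈0.30 prevalence — sized to
echo gynecological diagnosis cohorts at desk scale.  Declared pairwise
interactions are supported as derived variables (a column computed from
others, with its own step function), matching how the pregnancy
application includes a gestational-sac × heart-rate-seen interaction.

What the generator does *not* emulate: correlated covariates, measurement
error, informative missingness, site effects, or the very strong signal
(AUC ≈ 0.95) of the real adnexal cohort.  Passing recovery tests on this
generator therefore demonstrates the machinery, not clinical validity.

A known limitation surfaces exactly here.  The hinge loss saturates: once
a patient is beyond the margin, further log-odds information earns
nothing, so the marginal value of an entire *weak* variable (interval
effects ≈ 1 on the log-odds, cohort ceiling AUC ≈ 0.76) is only a few
hinge units.  Any difference-penalty strong enough to zero several
irrelevant variables then tends to delete weak true structure wholesale
rather than merely fusing within it, and fitted charts are either dense
(noise retained, true breakpoints present) or collapsed (noise gone,
weak breakpoints too).  In the strong-signal regime of the original
applications the two phenomena separate cleanly; at weak signal they do
not, and the comparable-performance selection rule deliberately resolves
the tension in favour of discrimination, at the cost of retaining some
irrelevant low-point questions.

## Problem sizes and seeds in the shipped tests

The test suite exercises: solver-oracle agreement on 50 random instances
(≤30 rows, ≤6 non-reference columns); sparsification on a one-variable,
two-breakpoint staircase of 600 patients; pipeline recovery on 20 cohorts
of 2000 patients with independent 5000-patient test draws; bootstrap
coverage over 200 simulations of 200 patients at a true binormal AUC of
0.80; and calibration on a 5000-patient cohort.  All randomness flows
through explicit seeds; identical seeds give identical results.

## Degenerate inputs and edge rules

Missing covariate values score 0 points (the reference answer) and are
excluded from grid construction.  Constant columns get an empty grid and
can never contribute.  An all-zero fit yields an empty chart, a document
stating that no variables were selected, and no risk spread.  Exact .5
point ratios round away from zero.  `interval_of` is monotone and
left-closed everywhere, including at the grid boundaries.
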