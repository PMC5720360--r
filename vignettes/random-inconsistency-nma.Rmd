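---
title: "Estimating heterogeneity and inconsistency variances in network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heterogeneity and inconsistency variances in network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmari)
```

## The model

A network meta-analysis compares more than two treatments by combining
studies that each compare a subset of them.  `nmari` works with
contrast-based data: study $i$ of design $d$ (a *design* is the set of
treatments the study includes) contributes a vector $Y_{di}$ of
estimated relative effects (log odds ratios, mean differences) of its
$c_d$ non-baseline arms against a design-specific baseline arm, with a
within-study covariance matrix $S_{di}$ that is treated as known.
Because all contrasts of a multi-arm study share the baseline arm, the
off-diagonal entries of $S_{di}$ equal the baseline arm's variance.

The model is

$$Y_{di} = \delta_d + B_{di} + \omega_d + \varepsilon_{di},$$

where $\delta_d$ expresses the design's average effects in terms of the
*basic parameters* $\delta^{AB}, \delta^{AC}, \dots$ (average effects of
each treatment relative to a network reference $A$), $B_{di} \sim
N(0, \tau_\beta^2 P_{c_d})$ is a study-level random effect capturing
between-study heterogeneity, $\omega_d \sim N(0, \tau_\omega^2 P_{c_d})$
is a design-level random effect capturing inconsistency (disagreement
between designs beyond heterogeneity), and $\varepsilon_{di} \sim
N(0, S_{di})$.  Here $P_k$ is the $k \times k$ matrix with unit diagonal
and off-diagonal entries $1/2$, the correlation structure forced by the
shared baseline arm.  Stacking all studies gives

$$Y \sim N(X\delta,\; \tau_\beta^2 M_1 + \tau_\omega^2 M_2 + S),$$

where $M_1$ has unit diagonal and entries $1/2$ between contrasts of the
same study, and $M_2$ has entries $1$ between same-design rows of the
same comparison and $1/2$ between same-design rows of different
comparisons.  Taking $\tau_\omega^2 = 0$ recovers the consistency model;
design-by-treatment interaction with *random* inconsistency effects
keeps the basic parameters interpretable as averages over the whole
evidence base while admitting inconsistency.

`assemble_network()` builds $(Y, X, S, M_1, M_2)$ from per-study
contrast blocks; `contrasts_from_binary()` and
`contrasts_from_continuous()` build the blocks from arm-level data.

## Estimating the variance components

The difficulty is estimating $(\tau_\beta^2, \tau_\omega^2)$; given
estimates, inference for $\delta$ is weighted least squares with the
weights treated as known.  Three classical estimators are provided.

**Iterative moment (Paule–Mandel type) estimation** is built on three
*Q pivots*, generalized residual sums of squares whose weight matrix is
the total (not just within-study) precision:

* the network pivot under consistency,
  $Q^{net}(\tau_\beta^2) = (Y-\hat Y)^T(\tau_\beta^2 M_1 + S)^{-1}(Y-\hat Y)
  \sim \chi^2_{n-c}$;
* the per-design heterogeneity pivot
  $Q_d^{het}(\tau_\beta^2) \sim \chi^2_{(n_d-1)c_d}$, computed from
  design $d$'s studies alone (inconsistency cancels within a design
  because all its studies estimate the same design mean);
* the full network pivot
  $Q^{net}(\tau_\beta^2, \tau_\omega^2) \sim \chi^2_{n-c}$ with weight
  $(\tau_\beta^2 M_1 + \tau_\omega^2 M_2 + S)^{-1}$.

In each case $\hat Y$ is the GLS fit under the same weight.  Matching
each pivot to its expectation gives estimating equations: under the full
model, $\sum_d Q_d^{het}(\hat\tau_\beta^2) = \sum_d (n_d-1)c_d$ is
solved first, then $\hat\tau_\beta^2$ is held fixed while
$Q^{net}(\hat\tau_\beta^2, \hat\tau_\omega^2) = n-c$ is solved for
$\hat\tau_\omega^2$.  Each pivot is continuous and strictly decreasing
in the variance being estimated.  The heterogeneity pivots decay to
zero (their structure matrices are positive definite), so the first
equation always has a unique root or truncates.  The inconsistency
pivot instead decays to the summed within-design heterogeneity pivot:
$M_2$ is singular whenever a design is replicated, and only
between-design contrasts lose precision as $\tau_\omega^2$ grows, so
$\lim_{\tau_\omega^2\to\infty} Q^{net}(\tau_\beta^2, \tau_\omega^2) =
\sum_d Q_d^{het}(\tau_\beta^2)$, which equals $\sum_d (n_d-1)c_d$ at
the first-stage solution.  The second equation therefore has a unique
root exactly when the network has between-design degrees of freedom
($\sum_d c_d > c$); when it has none, $\tau_\omega^2$ is not
identifiable and the package reports zero with a warning rather than
chasing a root at infinity.  In all cases, a pivot at zero that does
not exceed its degrees of freedom truncates the estimate to zero.
These estimators are semiparametric: expectations of quadratic forms
need no normality.

**Moment (DerSimonian–Laird type) estimation** uses the same quadratic
forms with weights fixed at the within-study precision $S^{-1}$, where
expectations are linear in the two variances:
$E[Q^{net}] = (n-c) + a_1\tau_\beta^2 + a_2\tau_\omega^2$ with
$a_j = \mathrm{tr}((W - WH)M_j)$, $W = S^{-1}$ and $H$ the GLS hat
matrix.  This gives closed-form estimates (`estimate_dl()`), again with
truncation at zero.

**Likelihood estimation** (`estimate_reml()`, `estimate_ml()`)
maximizes the restricted (or profile) log-likelihood
$-\tfrac12[\log\det V + \log\det X^TV^{-1}X + r^TV^{-1}r]$ over the
nonnegative quadrant.  REML is the recommended default; ML is biased
downwards in small samples.

## Numerical choices

* All weighted quadratic forms go through Cholesky factorizations;
  a covariance matrix that fails to factorize raises an error rather
  than being silently regularized, since hidden ridging would bias the
  variance estimates.
* Estimating equations are solved by bracket doubling (initial upper
  bound $1 + \max \mathrm{diag}(S)$) followed by bisection to an
  absolute tolerance of $10^{-12}$ on the variance, capped at 500
  iterations; a pivot value at zero less than or equal to the degrees
  of freedom counts as truncation.  For repeated evaluations each pivot
  is diagonalized once: writing the base covariance as $U^TU$ and
  eigendecomposing $U^{-T}MU^{-1}$ turns every evaluation into a
  diagonally weighted regression, so root finding and interval
  inversion are cheap and numerically stable.
* The REML/ML surface is maximized with bounded quasi-Newton search
  (analytic gradients) on $[0, B]^2$ with
  $B = 10(\max(\text{moment estimates}) + 1)$, started from the origin
  and from the two moment estimates; the best converged start wins and
  per-start convergence flags are reported.  An objective tolerance of
  $10^{-8}$ is used.  Boundary solutions below $10^{-10}$ are reported
  as exact zeros.
* Exact boundary cases (pivot at zero equal to the degrees of freedom)
  are truncated to zero.
* The reference treatment defaults to the lexicographically smallest
  label, and each design's baseline to its smallest treatment; variance
  estimates are invariant to these choices (tested), so the defaults
  only fix a reporting convention.
* For binary data, if any cell of any arm of a study is zero, 0.5 is
  added to every cell of every arm of that study before log odds are
  formed.  Published analyses of the same data may use other
  conventions, which can move third decimals.
* Rows are ordered by design, then study, then comparator, making the
  structure matrices and all outputs deterministic.
* Networks whose treatment graph is disconnected are rejected with an
  error naming the components; a pseudo-inverse fit would silently
  estimate unidentified contrasts.
* Under the full model, a network with a single design is rejected
  (the design mean and its inconsistency effect are aliased), and a
  network with no replicated design reports
  $\hat\tau_\beta^2 = 0$ with a prominent warning rather than an
  arbitrary number.

## Confidence intervals for the variances

Because the consistency-model pivot is monotone with a known
$\chi^2_{n-c}$ distribution, inverting it at the $\alpha/2$ and
$1-\alpha/2$ quantiles gives a Q-profile interval for $\tau_\beta^2$
under consistency (`q_profile_ci_consistency()`); crossings below zero
truncate and a pivot entirely below the lower quantile yields a flagged
degenerate interval.  For the full model, profile-likelihood intervals
(`profile_likelihood_ci()`) profile one variance over the other and
invert the $\chi^2_1$ likelihood-ratio drop.  Q-profile-type intervals
for one variance that also account for the uncertainty in the other are
an open problem and are deliberately not attempted.

## The synthetic-data generator

`synthetic_layout()` generates study conditions emulating a large
published mini-mental-state examination network in which heterogeneity
and inconsistency are both substantial: 41 studies of which 37 compare
two treatments, 3 compare three and one compares four; 9 treatments
with a dominant reference (each non-spanning two-arm study includes the
reference with probability 1/2); and highly dispersed within-study
variances.  Per-arm variances are log-normal with parameters
$(\mu, \sigma) = (-2.2712, 1.3735)$, calibrated once (by Monte Carlo,
inverting the mean and median of the sum of two independent log-normal
arm variances) so that the two-arm within-study variance has mean 0.53
and median 0.29 — the dispersion observed in that network, where the
mean and median differ by almost a factor of two.  Multi-arm
covariances follow the shared-baseline-arm rule.  `simulate_dataset()`
draws outcomes from the stacked model with all basic parameters zero
(estimation is location invariant, so this is without loss) by
simulating the three random components separately, which also makes the
latent draws available.

What the generator does *not* emulate: estimated (rather than known)
within-study covariances, non-normal random effects, binary outcomes
generated at the arm level, and any relationship between study size and
effect size.  Passing tests therefore demonstrate correct behaviour of
the estimators *under the model*, not robustness to its violation.

## The Monte-Carlo harness

`run_grid()` fits every requested method to the same simulated
datasets, using one master seed and per-(grid point, replicate)
substreams so that estimator correlations are meaningful and any subset
of the grid can be reproduced independently.  Coverage of the nominal
95% Wald intervals is pooled across all basic parameters.  Likelihood
fits that fail to converge are excluded from that method's summaries
and counted.  Correlations are computed on the raw (possibly truncated)
estimates.  The default grid crosses
$\tau_\beta^2 \in \{0, 0.25, 0.5, 0.75, 1\}$ with
$\tau_\omega^2 \in \{0, 0.25, 0.5\}$: a wide range of heterogeneity,
and inconsistency capped at moderate values since severe inconsistency
should discourage a network meta-analysis altogether.

The packaged test suite exercises this harness at 500 replicates per
grid point on the 41-study layout, and the distributional check of the
network pivot at 5000 replicates; these sizes give Monte-Carlo standard
errors small enough to detect estimator bias of a few hundredths on the
variance scale while keeping the default test run short.

## Known limitations

* Within-study covariances are treated as known, as is conventional;
  with very small arms the normal approximation and the known-variance
  assumption both degrade.
* Wald intervals for the treatment effects use normal quantiles with no
  small-sample adjustment, matching the weighted-regression framing;
  their actual coverage is slightly below nominal when the variance
  components are estimated imprecisely.
* The two-variance model assumes a common heterogeneity variance and a
  common inconsistency variance across all designs; richer structures
  would need more data to identify and break the monotone-pivot
  machinery that guarantees unique moment estimates.
* Loop-inconsistency variants of $M_2$, ranking probabilities,
  prediction intervals and meta-regression covariates are out of scope.

## A worked example

```{r example}
layout <- synthetic_layout(n_studies = 14, n_treatments = 5,
                           design_mix = c("2" = 12, "3" = 2), seed = 3)
sim <- simulate_dataset(layout, tau_beta_sq = 0.4,
                        tau_omega_sq = 0.2, seed = 99)
net <- set_outcome(layout, sim$Y)
fit <- fit_network(net, method = "pm", model = "full")
summary(fit)
```

```{r intervals}
q_profile_ci_consistency(net)
```
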