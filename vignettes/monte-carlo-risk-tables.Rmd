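---
title: "Monte Carlo joint-density estimation of suicide-ideation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo joint-density estimation of suicide-ideation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mcrisk)
```

## The problem

Screening batteries for adolescent suicide risk cross a suicidal-ideation
instrument (PANSI, with a negative-ideation sub-scale NSI and a positive,
protective sub-scale PI) with instruments measuring risk and protective
factors: family function (the five-item family APGAR), school adjustment
(BSSA-10, with sub-scales for school performance, academic expectations and
integration problems) and risky eating behaviors (BQREB, with binge-purge,
compensatory-measures and restriction factors).

The analytic question is joint: *what is the probability of an adverse
ideation score given a score band on a factor sub-scale?* Classical
parametric answers assume joint normality of the score pair, which these
instruments violate — bounded integer sums with strong ceiling effects are
visibly non-Gaussian. The approach implemented here makes no such
assumption:

1. **Score** item responses into sub-scale sums (reverse-keyed items
   recoded as `min + max − response`).
2. **Smooth** each (factor, ideation) score pair into a joint density
   $\hat f(x) = \frac{1}{n h_1 h_2} \sum_{i=1}^n
   \varphi\!\left(\frac{x_1 - p_{i1}}{h_1}\right)
   \varphi\!\left(\frac{x_2 - p_{i2}}{h_2}\right)$, a product-Gaussian
   kernel density estimate (KDE).
3. **Sample** the KDE with a random-walk Metropolis–Hastings (MH) chain:
   propose $x_c \sim N(x_k, \Sigma_p)$, accept with probability
   $\min\{1, \hat f(x_c) / \hat f(x_k)\}$, and discard an initial burn-in
   segment.
4. **Bin** the retained samples on a three-interval split of each
   sub-scale's score range, yielding a joint probability table and, row-wise
   renormalised, the conditional table
   $P(\text{ideation band} \mid \text{factor band})$.

`risk_model()` packages steps 2–4 for one pair; `run_full()` orchestrates
the fourteen pairs of the battery (seven factors × two PANSI sub-scales).

## Worked example

```{r example}
cohort <- generate_cohort(cohort_spec(n = 413, seed = 1))
scores <- score_cohort(cohort)
fit <- risk_model(scores, "BSSA_SP", "PANSI_NSI", seed = 1)
summary(fit)
```

The conditional table reads: given a school-performance score in the band
of its row, the probability of a negative-ideation score in each column
band. A single-number summary is available through `headline_risk()`, whose
convention is documented below.

## Model components and their parameters

### Kernel density estimate

* **Kernel.** Product of two univariate standard Gaussians (diagonal
  bandwidth matrix). This matches the default behaviour of the common
  multivariate kernel-smoothing routines and makes two useful quantities
  exact: the density itself is a double sum checkable by brute force, and
  the mass of any rectangle factorises into normal-CDF differences
  (`kde_cell_mass()`), giving an analytic reference table against which the
  chain's Monte-Carlo error can be measured.
* **Bandwidth.** Per-dimension normal-reference rule for a bivariate
  density, $h_d = \hat\sigma_d \, n^{-1/6}$ (the Silverman-type rule with
  exponent $-1/(d+4)$, $d = 2$), overridable via `bandwidth=`. For the
  default cohort ($n = 413$) this gives bandwidths of roughly a third of a
  score standard deviation. No claim is made that this reproduces any
  particular published figure: the smoothing choice there is unstated.
* **Integer scores are smoothed as-is** — no jitter. The KDE therefore puts
  some mass outside the valid score rectangle; binning handles this by
  extending the outermost intervals to infinity, so no sample is ever
  dropped.

### Metropolis–Hastings sampler

* **Proposal.** Gaussian random walk. `run_chain()` defaults to the unit
  identity covariance — the textbook form of the method. The fitted
  estimator `risk_model()`, however, defaults to the scale-matched proposal
  $\sigma_d = 2.38\,\hat\sigma_d/\sqrt{2}$ (the Roberts–Gelman–Gilks
  optimal random-walk scaling). The reason is practical: score pairs live
  on ranges as wide as 10–60, and a unit proposal on that scale accepts
  ~90% of moves but diffuses so slowly that a 20,000-iteration chain leaves
  a visible Monte-Carlo gap between the binned table and the analytic
  reference (total-variation distance ≈ 0.07 on the default cohort). The
  scale-matched proposal accepts ~40% of moves and reduces that gap to
  ≈ 0.02 at the same chain length. Pass `proposal_scale = 1` to recover
  the unit proposal exactly.
* **Iterations.** Default $N = 20{,}000$, read as total iterations (the
  distinction from "retained samples" is immaterial at the default 10%
  burn-in).
* **Burn-in.** Default $M = \lfloor N/10 \rfloor$; the method's
  description names $M$ without fixing it, and one tenth is a conventional
  choice for a chain started inside the support (the start is a randomly
  drawn respondent's score pair, so it is never in a density-zero region).
  Rejected proposals repeat the current state — textbook MH; burn-in
  removal is a separate, explicit step (`discard_burnin()`), and both are
  recorded in the chain CSV (`accepted`, `is_burnin` columns).
* **Reproducibility.** Each chain takes one integer seed; `run_full()`
  derives per-pair seeds as `master seed + pair index`, so restricting the
  pair list never changes another pair's chain, and a manifest re-run is
  bitwise identical.

### Binning and tables

Each axis is split into the three published closed integer intervals (e.g.
NSI (8,19), (20,29), (30,40)). Real-valued chain states are assigned by
midpoint cuts between adjacent intervals (8.5 between (3,8) and (9,13)),
outer bins unbounded. Joint cells are `count / m`; conditional rows are
renormalised joint rows, with empty rows flagged rather than silently
zeroed.

`headline_risk()` reduces a table to one number: the maximum, over a
designated set of adverse factor bands, of the conditional mass on the
adverse ideation bands. The defaults (`adverse_bins()`) read "adverse" as:
lowest band for the school sub-scales and family APGAR (low scores mean
poor adjustment/function — BSSA items 6–10 are reverse-keyed first, so low
always means worse), highest band for the eating-behavior factors, NSI ≥ 20
(upper two bands) on the negative-ideation axis and the lowest PI band on
the positive-ideation axis. This reduction is this package's own documented
convention: the published headline percentages use an unstated reduction
that cannot be reverse-engineered from the printed tables, so no numeric
comparison to them is attempted.

### Psychometric validation

The validation stage is computed from first principles on the item-level
correlation matrix $R$:

* **KMO** $= \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
  \sum_{i \ne j} q_{ij}^2)$ with $q_{ij} = -s_{ij}/\sqrt{s_{ii} s_{jj}}$,
  $S = R^{-1}$ (anti-image partial correlations). Singular $R$ is an error,
  not a silent regularisation.
* **Bartlett's sphericity** $\chi^2 = -(n - 1 - (2p+5)/6)\ln\det R$ with
  $p(p-1)/2$ degrees of freedom, asymptotic reference distribution, no
  small-sample correction.
* **Retention** by the Kaiser criterion (eigenvalues strictly above 1);
  **loadings** are principal components of $R$ (eigenvectors scaled by
  $\sqrt{\lambda}$) with varimax rotation. PCA-plus-varimax was chosen
  because only the retention criterion is pinned down by the source
  procedure; rotation is orthogonal, so communalities are preserved, which
  the tests check.

## The synthetic cohort generator

No raw respondent data is deposited anywhere, so the package carries its
own cohort generator (`generate_cohort()`), openly an artifact construct:

* One latent standard normal per sub-scale, drawn with a target 9 × 9
  correlation matrix (default: the study-shaped matrix in
  `default_scale_correlations()`, e.g. 0.558 between the two PANSI
  sub-scales) through the symmetric eigen square root.
* Each item's latent is `0.7 × sub-scale latent + √(1 − 0.7²) × noise`
  (a common middling loading); reverse-keyed items are generated against
  the latent's sign so that *scored* sub-scales always increase with their
  latent and score-level correlations track the latent targets in sign.
* Equal-mass standard-normal thresholds map item latents to each item's
  response range; `ceiling_skew` shifts all thresholds downward (in latent
  SD units) to pile responses on the top category, emulating the ceiling
  effect that motivates the non-Gaussian treatment in the first place.

What the generator does *not* emulate: item-specific loadings and
thresholds calibrated to the real instruments, nonresponse mechanisms,
demographic structure, and the exact marginal score distributions of the
study cohort. Passing tests therefore demonstrate that the machinery is
correct under a controlled, study-shaped data-generating process — not that
the package reproduces the original cohort's numbers, which would require
the undeposited raw responses. Score-level correlations are attenuated
relative to latent targets by discretization (0.558 latent ≈ 0.48 observed
at the default settings), which is expected and tested only as a
rank-order/sign property.

## Numerical choices and degenerate inputs

* A sub-scale with zero variance makes the KDE degenerate; `fit_kde()`
  refuses it with an explicit error instead of jittering silently, and
  `run_full()` records the failure for that pair and continues with the
  rest.
* A chain started at a zero-density state (impossible with the
  random-individual start, possible with a manual `init`) is an error, not
  a silent restart.
* Respondents missing any item of a sub-scale get no score on that
  sub-scale (listwise per sub-scale): a sum over a partial item set is not
  comparable to a complete one. Correlation and psychometric stages then
  use listwise-complete rows.
* The family-APGAR category list in circulation names a "functional" band
  although the three dysfunction bands already cover 0–10; scores 7–10 are
  mapped to mild dysfunction and the contradiction is documented at
  `classify_apgar()`.
* The BQREB factor→item assignment and the PANSI NSI/PI item split are not
  published at item-number level; defaults (BQREB 1–4/5–7/8–10; PI = items
  2, 6, 8, 12, 13, 14 per the original instrument keying) are explicit
  arguments of `builtin_instruments()`.

## Problem sizes used in the test suite

The shipped tests run the full study-scale conditions where they are cheap
(n = 413 cohorts, 20,000-iteration chains, a 50,000-iteration chain against
an analytic bivariate normal) and reduced sizes where only the contract is
at stake (e.g. 1,000–3,000-iteration chains for reproducibility and
pipeline-wiring checks, 10,000-draw cohorts for correlation-recovery
bounds). Monte-Carlo assertions state their tolerance as a multiple of the
relevant standard error or as the fixed bounds quoted above.

## Known limitations

* The KDE is not boundary-corrected; near score-range edges the density
  leaks outward and the outer bins absorb it. For three-interval grids the
  effect is minor but it biases edge cells slightly toward the interior
  reference value.
* Bandwidths use the normal-reference rule; heavily skewed (high
  `ceiling_skew`) cohorts would be better served by cross-validated
  bandwidths, which are out of scope.
* The headline reduction is a convention (documented above), not a
  reproduction of any published percentage.
* Only pairwise (2-D) joint densities are modelled; the method does not
  extend here to three or more simultaneous sub-scales.
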