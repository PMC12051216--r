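---
title: "Latent HbA1c trajectory classes and recurrent heart-failure risk: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent HbA1c trajectory classes and recurrent heart-failure risk: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajrecur)
```

# The problem

People with type 2 diabetes carry an elevated risk of heart failure, and
hospitalizations for heart failure (HHF) recur. Glycemia, tracked through
HbA1c (%), evolves over decades on a time axis anchored at the date of
diabetes diagnosis (DDD), with irregular measurement times and highly
unbalanced follow-up across patients. `trajrecur` implements a two-stage
analysis of this setting:

1. **Trajectory clustering.** A latent class growth model (LCGM) whose
   class mean trajectories are cubic B-splines partitions patients into
   groups with distinct long-term HbA1c profiles, without assuming a
   parametric shape.
2. **Recurrent-event modeling.** A nonhomogeneous Poisson process (NHPP)
   with power-law baseline intensity, observed only inside a per-subject
   window, links class membership and baseline risk factors to the
   intensity of recurrent HHF, and yields horizon predictions evaluated
   by ROC/AUC.

Registry data of this kind cannot be redistributed, so the package ships
a synthetic-cohort generator that emulates the statistical structure the
analysis assumes; every stage of the pipeline is exercised and tested
against that generator's known truth.

# The latent class growth model

Subject $i$ in class $k$ has, at measurement times $t_{ij}$,

$$y_{ij} = B(t_{ij})^\top \beta_k + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_{b,k}^2), \quad \varepsilon_{ij} \sim N(0, \sigma_e^2),$$

where $B(\cdot)$ is a cubic B-spline basis. Marginally the class density
of a series is multivariate normal with compound-symmetric covariance
$\sigma_{b,k}^2 J + \sigma_e^2 I$; the rank-1 structure gives an
$O(n_i)$ likelihood through the Woodbury identity, so series with
thousands of points cost the same per point as short ones. The mixture
over $K$ classes with proportions $\pi$ is fitted by EM
(`fit_lcgm()`); the log-likelihood is monotone across iterations and
the fitted classes are reported in descending-$\pi$ order so results are
reproducible across label permutations.

Design choices where the design was genuinely open:

* **Variance structure.** The random intercept SD is class-specific
  ("for each subgroup") while the residual SD is shared; a shared
  $\sigma_e$ keeps the M-step well-conditioned and avoids degenerate
  spikes. $\sigma_{b,k} \ge 0$ by construction and
  $\sigma_e \ge 10^{-4}$ as a floor.
* **Initialization.** Start 1 runs k-means on per-subject profile
  features: mean HbA1c within five time bins (empty bins imputed with
  the subject mean) plus the within-subject SD — the bins capture level
  *and* shape, the SD captures volatility. Subsequent starts use fresh
  single-run k-means local optima, and the last start uses random
  responsibilities. Random responsibilities alone average to
  near-uniform posteriors and, at larger $K$, reliably merge adjacent
  classes (we observed the two ascending classes collapsing into one);
  diverse k-means starts reach the global basin. All starts run a short
  exploratory EM (60 iterations) and only the best continues to
  convergence (`|Δloglik| < 10^{-6} n` or 500 iterations).
* **Split-merge refinement.** Even with many starts, EM at larger $K$
  can settle into optima that merge two true classes while leaving a
  near-empty class elsewhere. After convergence, `fit_lcgm()` proposes
  merging the cheapest class pair — curve distance weighted by the
  harmonic mass $\pi_a\pi_b/(\pi_a+\pi_b)$, so near-empty classes merge
  for free — while re-splitting the worst-fitting (or
  largest-$\sigma_b$) class by 2-means on the profile features, and
  accepts the move only when the likelihood improves. Moves are
  monotone in the likelihood, so refinement can only sharpen the
  optimum; disable with `refine = FALSE`.
* **Mixing proportions** are constant (no covariates in the membership
  submodel), and there are no random slopes — the spline mean plus an
  intercept is the model.

# Spline bases and knot placement

The basis is determined by the degree (3), the number of interior knots
and their placement (`basis_spec()`):

* **equidistant** — equal-width inter-knot intervals;
* **equipotent** — knots at the $j/(n_{\text{int}}+1)$ empirical
  quantiles of the pooled measurement times, so each interval holds the
  same number of data points.

Boundary knots are clamped (repeated degree + 1 times) at
$(0, t_{\max})$, giving a non-negative partition of unity. Evaluation
times beyond the boundary are clamped to it: data beyond roughly 1,300
weeks are sparse and spline extrapolation is unstable. Tied equipotent
quantiles are collapsed to unique values with a warning.

# Selecting knots and the number of classes

`iterate_selection()` implements the alternating search: starting from
$K_0 = 3$ (the coarse low/moderate/high reading of HbA1c levels),
(a) choose the knot count (grid 5, 10, ..., 40) and placement strategy
by BIC at fixed $K$; (b) choose $K \in \{1, \dots, 10\}$ by 10-fold
cross-validated BIC at fixed knots; repeat until the triple is stable.
BIC is $-2\ell + p\log n$ with
$p = Km + K + 1 + (K-1)$ ($m$ spline coefficients per class, $K$
intercept SDs, one residual SD, $K-1$ free proportions).

A "BIC" under cross-validation has no single canonical definition, so the
package uses held-out marginal log-likelihood with the penalty computed
on the held-out subject count; since the penalty is constant across
folds and candidates differ only through $p$, rankings are driven by the
held-out log-likelihood (a pure-loglik score is available via
`cv_score = "loglik"`). Training-fold fits are warm-started from a
full-data fit, which changes cost, not semantics. Ties break toward the
smaller model everywhere.

# The window-observed NHPP

With $T$ the weeks since DDD, the recurrent-event intensity is the
power-law (Weibull-type) form

$$\lambda(t \mid x) = \frac{\beta}{\eta}\Big(\frac{t}{\eta}\Big)^{\beta-1}
  e^{x^\top\gamma}, \qquad
  \Lambda(t \mid x) = \Big(\frac{t}{\eta}\Big)^{\beta} e^{x^\top\gamma},$$

with scale $\eta$ (weeks), shape $\beta$, and log hazard ratios
$\gamma$ for class indicators and baseline risk factors. Events are
recorded only inside a per-subject window $[L, R]$ — complication
records begin at a truncation date, so $L$ is the DDD-to-truncation gap
(0 if diagnosis came later) — and each subject contributes

$$\sum_{i} \log\lambda(T_i \mid x) \;-\; \big[\Lambda(R \mid x) - \Lambda(L \mid x)\big]$$

to the log-likelihood (`window_loglik()`). `fit_nhpp()` maximizes it
over $(\log\eta, \log\beta, \gamma)$ — unconstrained, which stabilizes
quasi-Newton steps — by BFGS with analytic gradients; the covariance of
the estimates is the inverse observed information, and `hazard_ratios()`
reports $e^{\hat\gamma}$ with Wald 95% intervals and two-sided Wald
p-values (the conventional choice for this model class). No intercept is included
in $\gamma$: the scale $\eta$ absorbs the baseline level and an
intercept would be unidentified against it. Covariates are time-fixed
within a window.

Simulation (`simulate_events()`) inverts the exponential time-transform:
cumulative Exp(1) draws mapped through
$\Lambda^{-1}(u \mid x) = \eta (u e^{-x^\top\gamma})^{1/\beta}$ from
$\Lambda(L \mid x)$, truncated at $R$.

## Residual diagnostics and window truncation

Under the true model, cumulative-intensity increments between successive
events of the *full* process are iid Exp(1). For window-observed data
the residual origin is taken at $L$, not 0, because pre-window events
are unobserved. A subtlety matters for calibration checks: pooling the
within-window gaps naively biases them short, because a gap is observed
only if it fits inside the remaining window — for a window of
transformed length $c$ the pooled mean is $1 - (1 - e^{-c})/c$, not 1
(about 0.63 at the default simulation scale). `residual_gaps()` therefore
concatenates subjects' transformed timelines end to end: each window's
transformed event sequence is a unit-rate Poisson process restricted to
an interval of length $c_i$, so the concatenation is again a unit-rate
Poisson process and its inter-event gaps are *exactly* iid Exp(1) under
the true parameters. The naive pooling remains available
(`splice = FALSE`) for comparison.

## Survival and horizon prediction

The first-event survival after window entry is
$S(t) = \exp\{-[\Lambda(L+t \mid x) - \Lambda(L \mid x)]\}$
(`survival_first_event()`, averaged over subjects by
`mean_survival_curve()`), and the probability of an event within a
horizon $h$ of a prediction start $s$ is
$1 - \exp\{-[\Lambda(s{+}h \mid x) - \Lambda(s \mid x)]\}$
(`event_probability()`). Horizons default to 26, 52 and 104 weeks (six
months, one year, two years). The evaluation protocol
(`downsample_balance()`, `stratified_split()`, `roc_auc()`) keeps every
case, samples an equal number of controls without replacement, splits
80/20 per group with floor arithmetic, and computes AUC by the
Mann-Whitney rank statistic with ties counted half — identical to the
trapezoidal area under the swept ROC curve. Subjects whose window closes
before $s + h$ are labeled by the events observed up to window end by
default; exclusion is available (`censoring = "exclude"`) as the natural
alternative convention.

# The synthetic-cohort generator

`default_paper_config()` encodes the published study conditions: eight
classes at the published proportions (renormalized to sum to 1 — the
printed percentages sum to 102), mean trajectories that start at the
published per-class baseline HbA1c means and follow the described
qualitative shapes, class-conditional covariate prevalences from the
published baseline table, and an NHPP truth whose $\gamma$ encodes the
published class hazard ratios against the low stable class with
$\eta = 400$ weeks and $\beta = 1.3$.

Quantities with no published value were fixed once, as follows:

* **Visit process.** A baseline measurement at $t = 0$ plus
  truncated-exponential gaps (mean 26, range 4-104 weeks; inverse-CDF
  truncation), matching the published order of magnitude of 11-31
  measurements over 220-550-week observation periods. Follow-up is
  Uniform(150, 2,500) weeks; windows are
  $[\max(0, \text{follow-up} - 416), \text{follow-up}]$, mimicking the
  truncated covariate-availability period.
* **Shape primitives.** Stable level; linear ramp over 1,300 weeks
  (25 years); exponential approach for the sharp-decline class (rate
  0.025/week, i.e. an e-fold every 40 weeks); lightly damped sinusoid
  for the volatility classes. The volatility amplitude (1.5% HbA1c) and
  periods (800 and 1,000 weeks, two-to-three gentle cycles over the
  48-year axis) are free choices. The periods were chosen so that class
  means stay smooth at the resolution of the fitted spline trajectories:
  projection analysis shows an RMS representation error of at most 0.03%
  HbA1c in a 10-interior-knot basis, versus ~0.45% for fast (sub-decade)
  oscillations. The distinction matters: if the generative means sit
  outside the spline family being fitted, information criteria correctly
  keep adding classes to absorb the bias, and no class count is "true".
* **Noise scales.** Residual SD 0.3% and random-intercept SD 0.2% —
  within-class dispersions consistent with the published within-class
  baseline SDs once between-class separation is removed.
* **Covariates** are drawn independently given class (only marginal
  class-conditional rates are published).

What passing the recovery tests shows — and what it does not. The
generator produces well-separated smooth classes, Gaussian noise,
missing-at-random visit times and a correctly specified intensity; real
registries have none of these guarantees (unit errors, informative visit
timing, within-class covariate correlation, medication feedback on both
HbA1c and risk). Recovery of the configured proportions, baselines,
hazard ratios and class count therefore validates the estimation
machinery, not the clinical conclusions.

# Numerical choices and degenerate inputs

* Marginal likelihoods and posteriors use log-sum-exp stabilization;
  EM empties a class (max responsibility < 1e-12) → that start is
  abandoned and another used; all-degenerate fits raise an error.
* Weighted least-squares M-steps add a relative ridge of 1e-8 so a
  class briefly starved of data in some knot span stays solvable.
* $\beta < 1$ with an event at $t = 0$ makes the intensity diverge;
  this is a domain error reported per subject.
* Duplicate measurement times keep the first value (a warning reports
  the count); duplicate-free, strictly increasing times are enforced
  otherwise.
* DDD imputation draws uniformly over the actual number of days in the
  diagnosis year (365 or 366); weeks are day differences / 7 with
  fractions kept, avoiding rounding bias at window bounds.

# Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the pipeline at desk
scale, chosen to keep each stage's sampling error well inside its
stated tolerance: 2,000 subjects for residual calibration, 5,000 for
hazard-ratio recovery, 4,000 (full grid) for the 8-class LCGM recovery,
and 2,000 with a single-fit BIC over $K \in \{6,\dots,10\}$ for the
scaled-down class-number selection. The full published grid (8 knot
counts x 2 strategies, $K = 1..10$, 10-fold CV) is supported through
`iterate_selection()` and is a configuration choice.

# Known limitations

* The NHPP has no frailty term: within-subject event clustering beyond
  what class membership and covariates explain is not modeled.
* Covariates (including class) are fixed within a window; dynamically
  updated covariates enter only by restarting prediction at a new $s$.
* Medication effects are descriptive only — deliberately excluded from
  the intensity model because prescription responds to risk (reverse
  causation).
* Spline extrapolation beyond the last knot is clamped, so long-horizon
  trajectory predictions flatten at the boundary value.
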