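# trajrecur

Flexible long-term HbA1c trajectory classes and recurrent heart-failure
risk in type 2 diabetes.

People with type 2 diabetes accumulate decades of irregularly timed
HbA1c measurements after their date of diabetes diagnosis (DDD), and
hospitalizations for heart failure (HHF) recur over the same axis with
records available only inside a per-subject observation window.
`trajrecur` is an R implementation of a two-stage analysis of that
setting, for biostatisticians and epidemiologists working with
longitudinal diabetes registries:

1. **Latent class growth model (LCGM) with B-spline means.** Subject
   $i$ in class $k$ follows
   $y_{ij} = B(t_{ij})^\top\beta_k + b_i + \varepsilon_{ij}$ with
   $b_i \sim N(0,\sigma_{b,k}^2)$, $\varepsilon_{ij}\sim N(0,\sigma_e^2)$,
   fitted by EM with an $O(n_i)$ compound-symmetry likelihood. Knot
   count, knot placement (equidistant vs quantile/equipotent) and the
   number of classes $K$ are chosen by an alternating BIC /
   cross-validated-BIC procedure.
2. **Window-observed nonhomogeneous Poisson process (NHPP).** Recurrent
   HHF has power-law intensity
   $\lambda(t\mid x) = (\beta/\eta)(t/\eta)^{\beta-1}e^{x^\top\gamma}$,
   observed on $[L, R]$; maximum likelihood gives hazard ratios
   $e^{\gamma}$ for trajectory classes and baseline risk factors,
   first-event survival curves, Exp(1) time-transform residual
   diagnostics, and horizon event probabilities
   $1-\exp\{-[\Lambda(s{+}h\mid x)-\Lambda(s\mid x)]\}$ evaluated with a
   down-sampled, stratified ROC/AUC protocol.

Registry data of this kind are not redistributable, so the package
includes a synthetic-cohort generator (`default_paper_config()`,
`generate_cohort()`) that emulates the published cohort's structure —
eight trajectory classes at the published proportions and baseline
levels, class-conditional covariate prevalences, and an NHPP truth
encoding the published class hazard ratios — making the entire pipeline
testable end to end.

## Worked example

```r
library(trajrecur)

cfg <- default_paper_config()          # published proportions, baselines, HRs
g   <- generate_cohort(cfg, n = 1000, seed = 42)
g$cohort
#> cohort: 1000 subjects, 47996 HbA1c measurements, 2341 events in 1000 windows

# cluster trajectories: 8 classes, cubic splines, 10 quantile-placed knots
sp  <- basis_spec(g$cohort$measurements$t_weeks, 10, "equipotent")
fit <- fit_lcgm(g$cohort, K = 8, sp, n_starts = 5, seed = 1)
round(fit$pi, 3)
#> [1] 0.236 0.164 0.134 0.109 0.096 0.096 0.087 0.079
round(predict_trajectory(fit, 1, c(0, 520, 1300)), 2)
#> [1] 6.24 6.23 6.25

# link classes to recurrent events: class-indicator hazard ratios
w    <- as_event_windows(g$cohort, X = class_indicators(g$labels, 8))
nh   <- fit_nhpp(w, seed = 1)
head(hazard_ratios(nh), 3)
#>     name        HR    CI_low   CI_high            p
#> 1 class2 0.7294618 0.6099426 0.8724009 0.0005500387
#> 2 class3 1.3094460 1.1177925 1.5339597 0.0008403635
#> 3 class4 1.2051977 1.0443528 1.3908150 0.0106570567

# horizon prediction, one year ahead of window entry
p52 <- vapply(seq_along(w$subject_id), function(i)
  event_probability(nh, w$X[i, ], s = w$L[i], h = 52), numeric(1))
obs <- horizon_labels(w, s = w$L, h = 52)
round(roc_auc(obs, p52)$auc, 3)
#> [1] 0.683
```

The first block prints the fitted mixing proportions (largest class
~24%, the low stable group) and its flat mean trajectory near 6.3%
HbA1c. The hazard-ratio table reads as multiplicative effects on the
HHF intensity against the reference (low stable) class — at n = 1,000
the recovered effects (0.73, 1.31, 1.21, ...) sit near the generator's
configured truths (0.79, 1.30, 1.17, ...). The final number is the
one-year AUC of the NHPP horizon predictor on this synthetic cohort.

## Package layout

| file | contents |
| --- | --- |
| `R/cohort.R` | cohort container, CSV I/O, DDD imputation, observation windows |
| `R/synthetic.R` | trajectory primitives, synthetic-cohort generator, published-config defaults |
| `R/basis.R` | B-spline bases, equidistant/equipotent knot placement |
| `R/lcgm.R` | LCGM likelihood, EM fitting, posteriors, BIC, trajectory prediction |
| `R/selection.R` | knot/class-count selection, cross-validated BIC, iterative procedure |
| `R/nhpp.R` | window-observed NHPP: likelihood, MLE, HRs, survival, residuals, simulation |
| `R/prediction.R` | down-sampling, stratified split, horizon probabilities, ROC/AUC |
| `R/reporting.R` | baseline tables, coincidence matrices, curve exports |

A thin CLI over these functions is in `inst/cli/trajrecur.R`; the
methods vignette (`vignettes/trajectory-recurrence-methods.Rmd`)
documents the models, the generator's assumptions and the design
decisions.
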