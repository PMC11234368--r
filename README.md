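# clonebd

Birth–death modeling of clonal lineage-tracing data in renewing epithelia.

## The problem

In pulse-chase lineage tracing, a CreER driver sparsely marks single basal
cells of the epidermis; animals are sacrificed at a series of chase times
and, for every labeled clone, the numbers of basal (BL) and suprabasal (sBL)
cells are counted in whole mounts.  Self-renewing stem cells produce the
classical *neutral-drift* signature — a constant labeled BL cell fraction,
linear growth of the mean surviving clone size, and inversely decaying clone
survival.  A *transit-amplifying* (TA) progenitor behaves differently: it is
biphasic, first amplifying its basal descendants and later, past a
transition in clonal age, declining to extinction, while the tissue is
replenished by rare *nascent* TA cells.  Cross-sectional clone counts from
such a population mix clones of many clonal ages, so extracting the
underlying rates requires an explicit demographic model.

`clonebd` implements that model end to end:

* **Clone data** — validated CSV I/O for per-clone basal/suprabasal counts
  (`load_clone_table()`), summary observables with Poisson-bootstrap
  standard errors (`summarize_clones()`), empirical clone-size CDFs, an
  even-size bias test, and a scale-vs-interscale permutation comparison.
* **Analytic engine** — the linear birth–death process with
  piecewise-constant rates in clonal age.  For a clone founded by one basal
  cell, with ρ(t) = ∫(λ−μ) and I(t) = ∫ μ e^{−ρ}, the mean clone size is
  M = e^{ρ}, the extinction probability α = I/(1+I), and the mean surviving
  size n̄ = M(1+I) (`bd_propagate()`).  Surviving clone sizes are geometric
  — the neutral-competition law C(n) = 1 − (1 − 1/n̄)ⁿ, with the
  neutral-drift limit C(n) = 1 − e^{−n/n̄} (`clone_size_cdf()`).  The
  homeostatic steady state of a non-self-renewing population gives the
  nascent influx ν, the pre-transition amplification fold, and the fraction
  of cells in the extinction phase (`steady_state()`), and cohort-level
  predictions under three CreER labeling-bias models — equal,
  pre-transition-only, post-transition-only (`predict_observables()`).
* **Simulator** — an exact Gillespie simulator of clones (births, basal
  delamination, neutral divisions, suprabasal shedding) and a
  cross-sectional experiment generator emulating the tail-skin study
  design: chase days {3.5, 7, 14, 30, 60, 90, 180, 365}, Poisson cohorts
  of sparsely labeled single basal cells, founder ages drawn from the
  steady-state age density (`generate_experiment()`).
* **Estimation** — division-interval and exponential half-life estimators,
  the critical birth–death (neutral drift) fit, maximum-likelihood fits of
  the biphasic model under each labeling variant with a fixed 45-day
  transition (`fit_gbdm()`), profile-likelihood confidence intervals for
  the net rates, likelihood-ratio rejection of the monophasic model
  (`compare_models()`), and a parametric-bootstrap goodness-of-fit test of
  the geometric clone-size law (`neutrality_gof()`).

## Worked example

Simulate a biphasic TA experiment at the study scale (~2500 clones), then
run the estimation pipeline:

```r
library(clonebd)

cfg <- ta_biphasic_config(clones_per_day = 300)
tab <- generate_experiment(cfg, seed = 12)
su  <- summarize_clones(tab, n_boot = 400, seed = 13)

division_interval(su, shed_rate = cfg$shed_rate)
#> Division interval: 3.84 +/- 0.27 days (window 3.5-30 d, 4 points)

half_life(su, t_start = 60)
#> Exponential half-life of f_basal: 59.0 +/- 19.7 days (t >= 60 d)

set.seed(14)
fe <- fit_gbdm(su, "equal")
fo <- fit_gbdm(su, "post_transition")
fp <- fit_gbdm(su, "pre_transition")
compare_models(list(fe, fo, fp))
#> Likelihood-ratio tests vs the monophasic (post-transition) model:
#>        model      null   stat dof        p confidence
#> 1 gbdm_equal gbdm_post 16.780   2 0.000227     0.9998
#> 2   gbdm_pre gbdm_post  9.054   2 0.010800     0.9892
#> AIC table:
#>        model n_free  loglik      aic
#> 1 gbdm_equal      5 3446.12 -6882.24
#> 2   gbdm_pre      5 3442.26 -6874.51
#> 3  gbdm_post      3 3437.73 -6869.46

fe
#> Birth-death model fit: gbdm_equal
#>         estimate       se
#> lambda1  0.05754 0.012630
#> mu1      0.02972 0.027300
#> lambda2  0.02058 0.001973
#> mu2      0.03220 0.002319
#>   log-likelihood: 3446.119
#>   amplification fold 3.50; 77.0% of cells past transition; nu = 0.002558/day
```

The labeled basal cells divide about every 4 days (truth: one division per
4 days); the labeled basal fraction halves every ~57 days in the
extinction phase; the monophasic (post-transition-labeling) model is
rejected with confidence > 0.99; and the fitted biphasic model implies a
several-fold basal amplification of a nascent clone before its transition,
with ~77 % of homeostatic cells already past the transition and a nascent
influx well below 0.5 %/day.

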