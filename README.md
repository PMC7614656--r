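# compositemi

Missing-data methods for **binary composite endpoints with partially
observed components** in randomized trials.

Many trials define their primary outcome as a composite: a participant
meets the endpoint if an event occurs in any of several binary components
(or some monotone AND/OR combination of them). When components are missing
non-simultaneously, a popular strategy is to *derive* the composite from
the observed components where possible — an OR-composite is 1 as soon as
any observed component is 1 — and exclude the rest. This package
implements the analysis showing why that strategy is biased, and the
alternatives that are not:

* **Closed-form bias engine** (two components, one MCAR): the derived
  endpoint's missingness distribution, the odds ratios
  $OR_{full}$ and $OR_{deriv}$, and the bias ratio
  $$\frac{OR_{deriv}}{OR_{full}} =
    \frac{1-(1-\alpha)\sigma}{1-(1-\alpha)\tau},$$
  where $\alpha$ is the component observation probability and
  $\sigma, \tau$ are the per-arm fractions of composite events carried only
  by the partially observed component. The ratio is bounded in
  $[\alpha, 1/\alpha]$; the derived endpoint is MNAR even though the
  component is MCAR, while the complete-record outcome distribution is
  unaffected.
* **Saturated log-linear simulator** for three correlated binary
  components per arm, calibrated by root finding so the composite's
  marginal logistic model on treatment has intercept 0.3 and slope 1.35
  (arm event rates 0.57 / 0.84), with MCAR/MAR missingness mechanisms.
* **Multiple imputation**: composite-level univariate logistic MI
  (`mi_cra`, `mi_deriv`) and component-level chained equations with
  stratified conditional models (`mic_main`, `mic_x`, `mic_x_z1`), passive
  composite imputation, pseudo-observation augmentation against perfect
  prediction, and Rubin's-rules pooling.
* **Simulation harness** computing bias, empirical/model SE and coverage
  with Monte Carlo errors over the factorial scenario grid.
* **Block pipeline** for composites built from 30 daily assessments
  (six five-day blocks, two completeness rules, adjacent-block MICE,
  identity-link binomial risk differences) with a synthetic daily-data
  generator.

## Worked example

The canonical two-component illustration — independent components at
probability 0.7 (one arm) and 0.2 (the other), with 70% of the second
component MCAR ($\alpha = 0.3$):

```r
library(compositemi)
bias_ratio(independent_joint(0.7), independent_joint(0.2), alpha = 0.3)
#> Derived-endpoint bias decomposition
#>   OR_full  = 17.9753
#>   OR_deriv = 21.8781
#>   ratio    = 1.2171  (= [1-(1-a)sigma]/[1-(1-a)tau])
#>   sigma = 0.2308, tau = 0.4444, alpha = 0.30
```

The event fractions are 0.23 and 0.44, and the derived-endpoint odds ratio
overstates the full-data odds ratio by 22%.

The same phenomenon end to end in simulation — generate a trial from the
calibrated three-component model, mask components under a MAR mechanism,
and compare handling methods (true $\beta_x = 1.35$):

```r
params <- case_params("I", "simple")
trial  <- simulate_trial(2000, params$treatment, params$control,
                         "simple", seed = 7)
masked <- apply_missingness(trial, mechanism_preset("MAR1"), seed = 8)
def <- composite_simple()
for (m in c("full", "cra", "deriv", "mic_x")) {
  print(analyze_with_method(if (m == "full") trial else masked, def, m,
                            M = 25, burnin = 10, seed = 9))
}
#> full estimate (log OR): 1.3762 (SE 0.1054)
#>   95% CI [1.1695, 1.5828], n analyzed = 2000
#> cra estimate (log OR): 1.3012 (SE 0.1637)
#>   95% CI [0.9804, 1.6220], n analyzed = 964
#> deriv estimate (log OR): 1.7150 (SE 0.1550)
#>   95% CI [1.4112, 2.0188], n analyzed = 1505
#> mic_x estimate (log OR): 1.3043 (SE 0.1352)
#>   95% CI [1.0372, 1.5715], n analyzed = 2000
```

The derived endpoint uses more rows than the complete-record analysis
(1505 vs 964) yet lands far from the truth; chained-equations MI of the
components uses everyone and stays close, with a smaller standard error
than the complete-record analysis. `run_scenario()` / `performance()`
repeat this over hundreds of replicates to quantify bias and coverage per
method, and `topps_demo()` runs the block-based pipeline on a synthetic
daily-assessment cohort.

A thin command-line front end over the same functions lives at
`inst/cli/compositemi.R` (subcommands `simulate`, `mask`, `impute`,
`analyze`, `bias-surface`, `simstudy`, `topps-demo`).

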