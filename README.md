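# dualfrailty

Event-history analysis of ownership durations in which every transaction
has a dual reading: a *sale* by the current owner and a *purchase* by
another company. The motivating application is the trading of ocean-going
vessels among shipping companies, but the machinery applies to any asset
class with long-lived items changing hands inside a finite population of
owners.

## The model

A vessel `v` of age `a` (calendar time `t`) owned by company `s` is sold to
an active company `b != s` with transition intensity

```
alpha_v(a, b) = Z_s Z_b^{-1} alpha0(a)
                exp(beta_V' x_v(a) + beta_S' x_s + beta_B' x_b + beta_E' x_E(t))
```

and scrapped with cause-specific hazard

```
lambda_v(a) = Z_s lambda0(a) exp(theta_V' x_v(a) + theta_S' x_s + theta_E' x_E(t))
```

Each company's frailty `Z_c = exp(S_c)` is an unobserved
`Gamma(1/xi, 1/xi)` random effect (mean 1, variance `xi`): the *same*
`Z_c` scales up all of `c`'s sales and scraps and scales down, through
`1/Z_c`, all of its purchases — a **dual frailty**. The log-frailty `S_c`
is the company's *sentiment*: positive leans toward selling, negative
toward buying.

Estimation is Bayesian MH-within-Gibbs: the nonparametric baselines are
profiled each iteration by Breslow estimators; `beta`, `theta` and
`log(xi)` move by random-walk Metropolis against profiled
(partial-likelihood) targets; and each `Z_c` is drawn exactly from its
generalised inverse Gaussian full conditional
(`order M + 1/xi, chi = 2 D2, psi = 2 (D1 + 1/xi)`), with an `O(N)`
incremental sweep implemented in compiled code. A partial-likelihood
fitter with frailty ignored (`fit_no_frailty()`) provides starting values
and quantifies the attenuation that ignoring heterogeneity induces in
vessel- and seller-side coefficients.

The package also ships a discrete-time simulator of dual-frailty
transaction histories and a replication harness for parameter-recovery
experiments. See the methods vignette
(`vignettes/dual-frailty-model.Rmd`) for the full account.

## Worked example

Simulate a small homogeneous fleet (frailty off), summarise it, and fit
the no-frailty sales model:

```r
library(dualfrailty)

cfg <- sim_config(n_companies = 30, n_vessels = 60, horizon = 200,
                  baseline = 2e-4, xi = 0, seed = 42)
h <- simulate_fleet(cfg)
sim_summary(h)
#> # A tibble: 11 x 2
#>    measure     value
#>    <chr>       <int>
#>  1 n_companies    30
#>  2 n_vessels      60
#>  3 n_censored     60
#>  4 n_scrapped      0
#>  5 n_sales        97
#>  6 owners_1       15
#>  7 owners_2       16
#>  8 owners_3       14
#>  9 owners_4        8
#> 10 owners_5        6
#> 11 owners_6        1

fit <- fit_no_frailty(h, "sale")
tidy(fit)
#> # A tibble: 6 x 7
#>   model block  covariate term         estimate std.error statistic
#>   <chr> <chr>  <chr>     <chr>           <dbl>     <dbl>     <dbl>
#> 1 sale  beta_V x_V_1     beta_V:x_V_1  0.490     0.217       2.26
#> 2 sale  beta_V x_V_2     beta_V:x_V_2 -0.00441   0.00959    -0.460
#> 3 sale  beta_S x_C_1     beta_S:x_C_1  0.726     0.249       2.91
#> 4 sale  beta_S x_C_2     beta_S:x_C_2 -0.728     0.232      -3.14
#> 5 sale  beta_B x_C_1     beta_B:x_C_1 -0.292     0.213      -1.37
#> 6 sale  beta_B x_C_2     beta_B:x_C_2  0.257     0.213       1.21
```

The 97 sales were generated with `beta_V = (0.3, -0.01)`,
`beta_S = (0.4, -0.2)`, `beta_B = (-0.2, 0.1)`; the estimates agree with
the generating values up to sampling noise (the largest deviation, for
`beta_S:x_C_2`, is about 2.3 standard errors on only 97 events). The full model adds the
company frailties:

```r
mc <- run_mcmc(h, mcmc_config(n_iter = 400, burn_in = 100, seed = 7,
                              init_params = coef_hazard_params(fit)))
tidy(mc)      # posterior means and SDs per parameter, including xi
autoplot(mc)  # trace plots
mc$frailty    # per-company posterior mean and SD of Z_c
```

With `xi = 0` in the generator the posterior for `xi` concentrates near
zero; on heterogeneous data (`xi > 0`) the sampler recovers both the
regression parameters and the frailty variance while the no-frailty fit
attenuates the vessel and seller coefficients — run
`replication_study(xi = 0.2, n_reps = 5, seed = 1)` and
`attenuation_report()` on its result to see the contrast.

A thin command-line interface wraps the same functions
(`inst/cli/dualfrailty.R`): subcommands `simulate`, `fit-nofrailty`,
`fit-mcmc`, `replicate` and `summarise`, each taking flags and/or a
YAML/JSON `--config`.

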