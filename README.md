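# stoptrace

Simulation and estimation tools for the tracking **stop signal task
(SST)**, centred on a **time-series state-space estimator** of the stop
signal reaction time (SSRT).

## The problem

In the SST a participant responds to go stimuli but withholds the response
when a stop signal sounds after a stop-signal delay (SSD). The stopping
latency — the SSRT — is latent. Under the independent horse-race model the
go and stop processes race and inhibition succeeds exactly when

```
GORT > SSRT + SSD
```

Classical estimators such as the Logan integration method,

```
SSRT = Q_GORT(1 − P(SI)) − T̄_d
```

(`Q_GORT` the go-RT empirical quantile function, `P(SI)` the
successful-inhibition fraction, `T̄_d` the mean delay), treat trials as
exchangeable. They are not: behaviour differs on trials preceded by a stop
trial (type B) versus a go trial (type A), and the staircase tracking the
SSD induces serial dependence by design. `stoptrace` provides:

- a race-model **simulator** for tracking SST sessions and a standard
  44-participant synthetic cohort with controlled type-A/type-B structure
  (`sst_design()`, `simulate_session()`, `build_cohort()`);
- the **classical indices**: pooled integration (`estimate_logan1994()`),
  cluster-weighted (`estimate_weighted()`), and mixture-distribution
  (`estimate_mixture()`) estimators, plus trial-history internal indices
  (`internal_indices()`);
- a **3-channel missing-data linear-Gaussian state-space model**
  (GORT, signal-respond RT, SSD) fitted by EM with exact Kalman
  filtering/RTS smoothing (`em_fit()`, compiled core), and the SSRT read
  off the smoothed go-RT channel (`estimate_ss_ssrt()`);
- **inference helpers** for cohort comparisons (`run_comparison_sweep()`,
  `paired_t()`, `regress_b_on_a()`), tidyverse-style `tidy()`/`glance()`
  and `autoplot()` methods, CSV session/cohort I/O, and a small CLI
  (`inst/cli/stoptrace`).

## Worked example

```r
library(stoptrace)

s <- simulate_session(sst_design(960), seed = 1)
partition_clusters(s)$weights$w_a
#> [1] 0.724

round(c(logan    = estimate_logan1994(s),
        weighted = estimate_weighted(s),
        mixture  = estimate_mixture(s)), 1)
#>    logan weighted  mixture
#>    173.7    195.3    178.2

est <- estimate_ss_ssrt(s)   # lognormal state-space pipeline
round(est$ssrt, 1)
#> [1] 186.4
est$converged; est$em_iterations
#> [1] TRUE
#> [1] 135
```

Cohort-level comparison by session length:

```r
cohort <- build_cohort(trial_counts = c(96, 960), base_seed = 1)
sweep <- run_comparison_sweep(cohort)   # paired t-tests per index pair
autoplot(sweep)
```

See `vignette("time-series-ssrt")` for the model, the estimation steps,
and the rationale behind the numerical choices (diagonal observation
noise, zero-delay masking, fit scope, iteration cap).

## License

MIT
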