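# rtmbias

Monte Carlo machinery for a question every longitudinal observational study
faces: when a baseline **predictor** is used to predict **change** in a
health measure between two waves, how badly do (a) **selective attrition**
and (b) **inappropriate modeling of regression toward the mean (RTM)** bias
the estimate — and in which direction?

The package simulates standardized linear-Gaussian populations in which the
baseline predictor–health association is driven by a latent cause with
either *transient* effects (the cause moves baseline health and the
predictor but not follow-up health — it generates predictor-correlated RTM,
so baseline-adjusted multiple regression is the appropriate analysis) or
*enduring* effects (its total effect on follow-up health equals its effect
on baseline health — no RTM, so change-score analysis is appropriate).
A latent **liability of dropping out**,

    L = g_P * P + g_1 * H1 + g_2 * H2 + e_L,

drives attrition: the subjects with the highest liability are deleted
listwise. Both analyses are then fitted to the retained subjects:

* **MR**: `H2 ~ P + H1`, the predictor coefficient estimating the effect of
  `P` on change under an RTM assumption;
* **change score**: `(H2 - H1) ~ P`, assuming no RTM.

Replicates aggregate into per-cell mean coefficients, mean SEs, 95% CI
coverage of the true effect `b_pred = .10`, and mean change scores. A
closed-form truncated-Gaussian oracle (inverse-Mills-ratio selection
moments composed with the regression estimands) gives the asymptotic value
of every cell without touching the simulator.

## Worked example

```r
library(rtmbias)

# appropriate use of each method: unbiased without attrition
mr_estimand(population_spec("transient"))   # [1] 0.1
cs_estimand(population_spec("enduring"))    # [1] 0.1

# inappropriate use: RTM bias with no attrition at all
mr_estimand(population_spec("enduring"))    # [1] 0.1689655
cs_estimand(population_spec("transient"))   # [1] 0.02

# one Monte Carlo cell: appropriate MR, strongest dropout dependency,
# 50% attrition
cfg  <- study_config(master_seed = 1)       # 500 replicates of n = 1000
spec <- population_spec("transient", "mnar-strong")
run_cell(spec, "mr", 0.5, cfg)
#>      scenario cause_type method appropriate     sign rate reps    n
#> 1 mnar-strong  transient     mr        TRUE positive  0.5  500 1000
#>       mean_b    mean_se coverage_pct mean_diff     mc_se_b master_seed
#> 1 0.03876475 0.03916995           66        NA 0.001680337           1
```

The cell mean `0.039` against the true `0.10` shows strong downward bias —
with only 66% of the 500 replicate CIs covering the truth — once dropout
depends substantially on baseline *and* follow-up variables; the analytic
oracle `attrition_estimand(spec, "mr", 0.5)` gives the matching asymptote
`0.041`. `run_study(cfg)` runs all 40 cells of the factorial design
(4 dropout scenarios × populations × methods × rates × sign variants,
about 45 s) and `render_study_table(results, 1:6)` formats them as the six
published-style tables.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/rtmbias.R run-study --seed 1 --out study-out
Rscript inst/cli/rtmbias.R run-cell --scenario transient-mcar --method mr --rate 0.5
Rscript inst/cli/rtmbias.R estimands --rates 0,0.3,0.5,0.7
```

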