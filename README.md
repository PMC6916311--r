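# biasmeta

Bias-adjusted Bayesian meta-analysis of binary-outcome randomized trials.

Meta-analyses routinely pool trials whose design flaws — inadequate sequence
generation, inadequate allocation concealment, lack of blinding — are known
to exaggerate intervention effects by roughly 10% on average. `biasmeta`
adjusts for this instead of ignoring it or excluding the trials: every trial
at high or unclear risk of bias keeps its likelihood contribution but
receives an additive bias term with an informative prior, which both shifts
and down-weights its evidence. The package is aimed at systematic reviewers
and biostatisticians who have Cochrane-style risk-of-bias judgements for
their trials and want bias-adjusted pooled estimates.

## The model

For trial *i* with binomial counts per arm:

    events_ctrl_i ~ Bin(n_ctrl_i, expit(alpha_i))
    events_trt_i  ~ Bin(n_trt_i,  expit(alpha_i + delta_i + s·x_i·beta_i))
    delta_i ~ N(d, tau^2)              random true effects (log OR)
    beta_i  ~ N(mu_i, sigma_i^2)       bias term, flagged trials only
    d ~ N(0, 1e5);  tau ~ U(0, 2);  alpha_i ~ N(0, 1e5)

`x_i` flags trials with at least one high-or-unclear risk-of-bias domain;
`s` orients the bias for whether benefit means OR < 1 or OR > 1. The
trial-specific prior `N(mu_i, sigma_i^2)` on the log ratio-of-odds-ratios
scale comes from one of five methods:

1. **data-based** — predictive distributions per bias profile from a
   hierarchical model over a meta-epidemiological collection
   (`fit_meta_epi()`, `predictive_bias()`), or from a published table
   (`load_bias_table()`);
2. **opinion-based** — expert interquartile ranges mapped to normals
   (0.02-grid rounding on the log scale, the `±0.67·sd` quartile rule) and
   pooled across assessors by medians (`iqr_to_normal()`,
   `pool_assessors()`);
3. **combined** — conjugate normal-normal fusion of 1 and 2
   (`combine_normals()`);
4. **data-informed numeric opinions** — as 2, elicited against the
   empirical distribution;
5. **data-informed area selections** — assessors pick quartile regions of
   the empirical distribution, mapped through truncated-normal quartiles
   (`area_to_iqr()`).

Posterior sampling runs in JAGS; results report posterior medians and 95%
credible intervals for the pooled odds ratio `exp(d)` and the heterogeneity
variance `tau^2`, plus the maximum Gelman-Rubin statistic. Assessor
consistency is quantified by intraclass correlations with
parametric-bootstrap intervals (`icc_with_ci()`). Synthetic generators with
known ground truth cover every input kind (`simulate_meta_analysis()`,
`simulate_meta_epi()`, `simulate_elicitations()`).

## Worked example

```r
library(biasmeta)

# a synthetic 10-trial meta-analysis: true OR = exp(-0.55) ~ 0.58, with
# flagged trials biased toward the intervention by ~15% on the OR scale
sim <- simulate_meta_analysis(n_trials = 10, d = -0.55, tau = 0.2,
                              bias_spec = c(mean = -0.15, sd = 0.1),
                              seed = 101)
trials <- sim$trials
head(trials[, c("trial_id", "events_ctrl", "n_ctrl", "events_trt", "n_trt",
                "profile_key")], 4)
#>   trial_id events_ctrl n_ctrl events_trt n_trt profile_key
#> 1      t01          91    186         27    77         LLL
#> 2      t02          50    145         66   199         LLX
#> 3      t03          18     86         27   129         LLX
#> 4      t04          30    130         20   174         XXL

cfg <- mcmc_config(n_chains = 3, n_iter = 20000, n_burnin = 4000, seed = 1)

unadj <- fit_bias_adjusted(trials, priors = NULL, config = cfg)
unadj$summary
#> OR    0.573 (95% CrI 0.415-0.772)
#> tau^2 0.097 (95% CrI 0.0014-0.575)
#> max Rhat 1.002

# method 2: four assessors give IQRs for the bias in each flagged trial
flagged <- trials$trial_id[trials$profile_key != "LLL"]
elic <- simulate_elicitations(
  setNames(sim$truth$beta, trials$trial_id)[flagged],
  n_assessors = 4, assessor_shift_sd = 0.05, within_sd = 0.15,
  strategy = "a", seed = 2)$elicitations
priors <- process_elicitations(elic, "a")
head(priors, 3)
#>   trial_id mean_logror sd_logror  source
#> 1      t02      -0.130 0.1492537 opinion
#> 2      t03      -0.195 0.1492537 opinion
#> 3      t04      -0.210 0.1492537 opinion

adj <- fit_bias_adjusted(trials, priors, config = cfg)
adj$summary
#> OR    0.639 (95% CrI 0.474-0.842)
#> tau^2 0.053 (95% CrI 0.0002-0.460)
#> max Rhat 1.007
```

Adjustment moves the pooled odds ratio from 0.57 toward the null (0.64),
because the priors say flagged trials likely exaggerated the benefit, and
shrinks the heterogeneity variance (0.097 to 0.053) — part of the
between-trial spread was bias, not real effect variation. The pooled prior
means above sit near the biases the generator actually drew, and the prior
sd 0.149 is the elicited IQR half-width 0.67·0.15 mapped back through the
quartile rule.

## Command line

`exec/biasmeta` exposes the pipeline as subcommands:

```sh
biasmeta simulate --n-trials 10 --seed 5 --out data/
biasmeta elicit-process --elicitations elic.csv --strategy a --out priors.csv
biasmeta adjust --trials data/trials.csv --method 2 \
    --elicitations elic.csv --seed 3 --out results/
biasmeta icc --elicitations elic.csv --boot 1000 --out icc.json
```

`adjust --method` accepts `1`–`5` or `unadjusted`; each method validates its
required inputs (for example, method 3 needs both `--elicitations` and
`--bias-table`) before any sampling starts. Results are written as JSON
(`results.json`), retained draws of `d` and `tau` as CSV.

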