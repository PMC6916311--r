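---
title: "Bias-adjusted Bayesian meta-analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-adjusted Bayesian meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasmeta)
```

## The problem

Meta-analyses of randomized trials routinely include trials whose design is
flawed: inadequate randomization sequence generation, inadequate allocation
concealment, or lack of blinding. Meta-epidemiological studies show that
trials at high or unclear risk of bias in these domains exaggerate
intervention effects by roughly 10% on average (on the odds-ratio scale, for
subjectively assessed binary outcomes). Taking such trials at face value
biases the pooled estimate; excluding them wastes evidence. `biasmeta`
implements the middle road: each flawed trial keeps its likelihood
contribution but receives an additive *bias term* with an informative prior,
so that its evidence is both shifted and down-weighted according to how much
bias is expected.

Trials are classified per domain as low vs high-or-unclear risk ("flagged");
high and unclear are grouped because trials judged outright high-risk are
typically too sparse to model separately. The three domain flags define a
**bias profile** — one of 8 combinations, written e.g. `XLL` (flagged for
sequence generation only). All-low (`LLL`) trials carry no bias term.

## The bias-adjustment model

For trial $i$ with binomial arm counts,

$$
\begin{aligned}
r^c_i &\sim \mathrm{Bin}(n^c_i,\ \mathrm{expit}(\alpha_i)) \\
r^t_i &\sim \mathrm{Bin}(n^t_i,\ \mathrm{expit}(\alpha_i + \delta_i + s\, x_i \beta_i)) \\
\delta_i &\sim N(d, \tau^2), \qquad \beta_i \sim N(\mu_i, \sigma_i^2),
\end{aligned}
$$

where $x_i$ indicates a flagged trial, $\delta_i$ is the trial's true
log odds ratio, and $\beta_i$ is its bias on the log ratio-of-odds-ratios
(log-ROR) scale with *fixed, trial-specific* prior parameters
$(\mu_i, \sigma_i)$ supplied by one of the five methods below. Priors:
$d \sim N(0, 10^5)$, $\tau \sim U(0, 2)$ (sensible on the log-OR scale),
$\alpha_i \sim N(0, 10^5)$. The vague normal prior on the control-arm
log-odds $\alpha_i$ is this package's choice; it mirrors the convention used
for $d$.

The sign $s$ encodes the benefit direction. Bias priors are always expressed
on the orientation where *negative* log-ROR means exaggeration of benefit.
When benefit corresponds to OR > 1 (`benefit_direction = "or_gt_1"`), the
model applies the bias with $s = -1$, so that adjusted estimates shrink
toward the null from above — without the user re-orienting their prior
tables.

Posterior sampling is delegated to JAGS (via rjags), with the model code
above authored in this package; convergence is assessed by the
Gelman–Rubin potential scale reduction factor over $d$, $\tau$ and all
$\delta_i$, computed on the second halves of (by default 3) chains started
from widely dispersed initial values. Fits with $\max \hat R > 1.05$ carry a
non-convergence flag and raise a warning — never a silent result. Reported
defaults mirror a production analysis (3 chains, 500,000 retained
iterations after 25,000 burn-in); all examples and tests in this package use
far shorter chains (typically 3 × 4,000–20,000), which the Rhat gate
verifies are adequate at these problem sizes.

Unexplained heterogeneity remains in $\tau^2$; when the between-trial spread
is partly generated by biases, adjustment absorbs part of it, so adjusted
$\tau^2$ estimates are typically smaller.

### Numerical choices

* **Quantile rule.** Posterior summaries are medians and central 95%
  intervals using type-7 (linear order-statistic interpolation) quantiles —
  stated because interval endpoints depend on the rule.
* **Zero cells.** Arms with 0 or all events enter the exact binomial
  likelihood with no continuity correction; all priors are proper, so the
  posterior is too.
* **$\tau$ fixed at 0.** `tau_max = 0` switches structurally to the
  common-effect model $\delta_i \equiv d$. Pinning $\tau$ near-but-not-at
  zero makes single-site Gibbs sampling degenerate (the $(d, \delta)$ block
  becomes perfectly coupled and effectively stops mixing), so the point mass
  is handled in the model structure instead.
* **$\hat R$ conventions.** Constant, identical chains give $\hat R = 1$;
  constant chains at different levels give $\infty$; finite-sample noise
  that would push the raw ratio below 1 is reported as 1.
* **Determinism.** Chain RNGs and initial values are derived from the
  config seed, so identical seed + config reproduce samples bit-for-bit.

## Quantifying the expected bias

All five methods produce the same currency: a normal distribution for total
bias per trial on the log-ROR scale.

### Method 1 — empirical evidence

A hierarchical model is fitted to a *meta-epidemiological collection*: many
meta-analyses containing both all-low and flagged trials. Per domain $c$,

$$
\beta_{tc} \sim N(b_{mc}, \kappa_c^2), \qquad
b_{mc} \sim N(b_{0c}, \phi_c^2),
$$

giving a mean bias $b_{0c}$, between-meta-analysis variation $\phi_c$ and
within-meta-analysis variation $\kappa_c$ for each of the three domains,
alongside per-meta-analysis effects $d_m \sim N(0, 10^5)$ and
heterogeneity $\tau_m \sim U(0,2)$. Hyperpriors are $b_{0c} \sim N(0, 10^3)$
and $\phi_c, \kappa_c \sim U(0, 2)$.

The model is *additive across domains with a priori independent
components*, so the predictive distribution for total bias in a new trial
with a given profile is the sum of its flagged domain predictives, each
$N(b_{0c}, \phi_c^2 + \kappa_c^2)$ given the hyperparameters. This additive
independent-domain structure is a design choice of this package: published
per-profile bias distributions are the only external constraint available,
and any alternative fit can be substituted through `load_bias_table()`
without touching the rest of the pipeline. `predictive_bias()` integrates
over hyperparameter uncertainty using exact mixture moments across posterior
draws (Monte-Carlo draws are retained for diagnostics only), and floors the
predictive sd at $10^{-6}$ so degenerate tables cannot crash downstream
samplers.

Identification requires meta-analyses containing *both* all-low and flagged
trials; with fewer than two such meta-analyses the variance components
largely follow their priors and the fit carries an `identified = FALSE`
flag.

### Methods 2 and 4 — elicited interquartile ranges

Assessors state an interquartile range for the bias ratio (ROR scale) in
each flagged trial — from trial information alone (strategy a, method 2) or
with the empirical distribution as a reference (strategy b, method 4). Both
are processed identically:

1. log-transform the bounds and snap them to a 0.02 grid
   (`round_log_ror()`; midpoint ties resolve away from zero — the package's
   choice, centralized in one function);
2. map the IQR $(L, U)$ to $N\left(\frac{L+U}{2},
   \left(\frac{U-L}{2 \times 0.67}\right)^2\right)$. The constant 0.67 is
   the 75th standard-normal percentile *rounded to two decimals* and is
   deliberately stored as such, not recomputed as $\Phi^{-1}(0.75) = 0.6745$;
3. pool across assessors by the *median* of means and the *median* of sds —
   a "typical assessor" summary, robust to extreme opinions, in contrast to
   linear or logarithmic opinion pools which weaken or sharpen knowledge.
   Even panels use the midpoint-of-central-pair median.

A range whose ends coincide after rounding is rejected as a zero-width
opinion.

### Method 5 — selected areas

Assessors pick a contiguous union of the reference distribution's quartile
regions A–D. A selected area is a truncated normal; its 25% and 75%
quantiles are, with cumulative bounds $(p_{lo}, p_{hi})$,

$$
\mu_d + \sigma_d\, \Phi^{-1}\!\big(p_{lo} + q\,(p_{hi} - p_{lo})\big),
\quad q = 0.25, 0.75,
$$

exact in probability space (areas A and D extend to probability bounds 0
and 1, not to any plotted axis limit). The resulting IQR then flows through
the same grid rounding and normal mapping as methods 2 and 4 — applying the
0.02 grid here too is a uniform-processing choice this package makes
explicitly. Narrower selections give narrower opinions, monotonically.

### Method 3 — statistical combination

The pooled opinion distribution is combined with the data-based distribution
by a conjugate normal–normal update,

$$
\mu = \frac{w_d \mu_d + w_o \mu_o}{w_d + w_o}, \qquad
\sigma = (w_d + w_o)^{-1/2}, \qquad w = 1/\sigma^2,
$$

implemented in closed form rather than inside the MCMC: the combination *is*
this posterior, and the closed form is deterministic and fast. A test
verifies equivalence against an MCMC fit of the two-level formulation. The
form is symmetric, so "opinion as data, empirical evidence as prior" and
the reverse coincide. Both sources carry equal weight; an `opinion_power`
argument is reserved for sensitivity analyses (default 1, not a tuning
knob).

## Assessor consistency

Consistency of elicited opinions is quantified by the intraclass
correlation of the per-assessor opinion *means*: a linear mixed model with
fixed assessor effects and random trial effects, estimated by maximum
likelihood (lme4, `REML = FALSE`; exactly saturated layouts with zero
residual variance are detected directly and returned as boundary
estimates). Then

$$
\mathrm{ICC} = \frac{\sigma^2_{\text{trial}}}
  {\sigma^2_{\text{trial}} + \sigma^2_{\text{resid}}},
$$

with a 95% percentile interval from a parametric bootstrap that simulates
from the fitted variance components *conditioning on the estimated fixed
effects* (the package's choice of bootstrap scheme) and refits. ICCs are
reported separately per elicitation strategy (and can be computed per
meta-analysis), matching how consistency differs across strategies.

## What the synthetic generators emulate — and what they do not

The three generators (`simulate_meta_analysis()`, `simulate_meta_epi()`,
`simulate_elicitations()`) draw from exactly the models above, with the
truth returned beside the records. Defaults are fixed once as the package's
study conditions:

* single meta-analyses of 10 trials (a typical small review; one all-low
  trial, the rest spread over the seven flagged profiles), per-arm sizes
  50–200, control risks $U(0.2, 0.5)$;
* flagged-trial bias around $-0.15$ (sd 0.1) on the log-ROR scale,
  i.e. ROR $\approx 0.86$ — the ~10–15% exaggeration reported in
  meta-epidemiological work;
* meta-epidemiological collections of 40 meta-analyses × 10 trials, domain
  means $-0.2, -0.15, -0.1$ with $\phi = \kappa = 0.1$, meta-analysis
  effects $d_m \sim N(0, 0.7^2)$, within-meta heterogeneity 0.1;
* four assessors per strategy, with per-assessment disagreement shifts, so
  the implied ICC of processed means is
  $\mathrm{var(biases)}/(\mathrm{var(biases)} + \text{shift}^2)$ up to
  grid-rounding noise.

Because generator and fitted model coincide, recovery and coverage tests
demonstrate *internal correctness* (the sampler targets the stated
posterior; intervals are calibrated under the stated model), not robustness
of the model to real data: real trials have correlated bias domains,
non-exchangeable biases, outcome-dependent reporting, and risk-of-bias
misclassification — none of which the generators produce. Passing tests
should be read accordingly.

## Problem sizes used in the checks

The automated checks run, among others: a 50-case truncated-normal
quartile grid against a bisection oracle (agreement $10^{-8}$); a 10-case
fusion grid against an MCMC oracle (agreement 0.005); a large-count
common-effect fixture against the precision-weighted closed form (agreement
0.02, with bias-inflated weights $1/(v_i + x_i\sigma_i^2)$); coverage of
the 95% credible interval for $d$ over 200 simulated meta-analyses of 10
trials at 3 × 10,000 iterations; hyperparameter recovery on a 40 × 10
meta-epidemiological collection within 3 posterior sds; and ICC recovery of
0.5 ± 0.05 on a 200-trial equal-variance design. These sizes are the
package's chosen verification conditions.

## Known limitations

* Binary outcomes only: there is little empirical evidence on bias for
  continuous or time-to-event outcomes, and the model is binomial-logistic
  throughout.
* Three bias domains; incomplete-outcome-data bias is not modelled
  (meta-epidemiological evidence shows no effect-estimate shift for it).
* Domain biases are additive and independent across domains; the
  meta-epidemiological model here is a transparent approximation, not a
  reconstruction of any particular published fit — substitute your own
  per-profile table via `load_bias_table()` if you have a better one.
* No network meta-analysis, no threshold analysis, and no two-stage
  normal-approximation variant.
* Variance components ($\phi_c$, $\kappa_c$, $\tau$) mix slowly in MCMC;
  the Rhat flag should be respected and chains lengthened when it trips.
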