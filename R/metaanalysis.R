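# Bias-adjusted Bayesian random-effects meta-analysis.
#
# Model, per trial i with arm counts (events, n):
#   events_ctrl_i ~ Binomial(n_ctrl_i, expit(alpha_i))
#   events_trt_i  ~ Binomial(n_trt_i,  expit(alpha_i + delta_i + s x_i beta_i))
#   delta_i ~ N(d, tau^2)         random true effects (log odds ratio)
#   beta_i  ~ N(mu_i, sigma_i^2)  bias term, only for flagged trials (x_i=1),
#                                 with trial-specific fixed mu_i, sigma_i
#   d ~ N(0, 1e5); tau ~ Uniform(0, 2); alpha_i ~ N(0, 1e5)
# s is +1 when intervention benefit corresponds to OR < 1 and -1 otherwise:
# bias priors are always expressed on the orientation where negative log-ROR
# means exaggeration of benefit.

.BIAS_ADJUST_MODEL <- "
model {
  for (i in 1:N) {
    rc[i] ~ dbin(pc[i], nc[i])
    rt[i] ~ dbin(pt[i], nt[i])
    logit(pc[i]) <- alpha[i]
    logit(pt[i]) <- alpha[i] + delta[i] + s * x[i] * beta[i]
    alpha[i] ~ dnorm(0, 1.0E-5)
    delta[i] ~ dnorm(d, prec.tau)
    beta[i] ~ dnorm(mu[i], prec.beta[i])
  }
  d ~ dnorm(0, 1.0E-5)
  tau ~ dunif(0, tau.max)
  prec.tau <- pow(tau, -2)
}
"

# tau fixed at zero: the random-effects distribution degenerates to a point
# mass and every trial shares the common effect d.
.BIAS_ADJUST_MODEL_COMMON <- "
model {
  for (i in 1:N) {
    rc[i] ~ dbin(pc[i], nc[i])
    rt[i] ~ dbin(pt[i], nt[i])
    logit(pc[i]) <- alpha[i]
    logit(pt[i]) <- alpha[i] + d + s * x[i] * beta[i]
    alpha[i] ~ dnorm(0, 1.0E-5)
    beta[i] ~ dnorm(mu[i], prec.beta[i])
  }
  d ~ dnorm(0, 1.0E-5)
}
"

# Shared JAGS runner: deterministic per-chain RNG seeds and dispersed
# initial values come in through `inits`.
run_jags <- function(model_string, data, inits, monitors, n_burnin, n_iter,
                     thin = 1L, quiet = TRUE) {
  con <- textConnection(model_string)
  on.exit(close(con))
  jm <- rjags::jags.model(con, data = data, inits = inits,
                          n.chains = length(inits), quiet = quiet)
  if (n_burnin > 0L) {
    stats::update(jm, n_burnin, progress.bar = "none")
  }
  rjags::coda.samples(jm, monitors, n.iter = n_iter, thin = thin,
                      progress.bar = "none")
}

chain_inits <- function(config, extra = NULL) {
  k <- config$n_chains
  lapply(seq_len(k), function(ch) {
    ini <- list(.RNG.name = "base::Wichmann-Hill",
                .RNG.seed = (abs(config$seed) %% 1000000L) * 1000L + ch)
    if (!is.null(extra)) ini <- c(ini, extra(ch, k))
    ini
  })
}

#' Fit the bias-adjusted meta-analysis model
#'
#' Runs MCMC for the random-effects logistic meta-analysis with additive
#' per-trial bias terms. Trials flagged (high-or-unclear risk of bias in at
#' least one domain) receive a bias term with a fixed normal prior taken
#' from `priors`; all-low trials have no bias term. With `priors = NULL` the
#' unadjusted model is fitted (no bias terms for any trial).
#'
#' @param trials a `bias_trials` data frame (see [as_bias_trials()]), at
#'   least two trials.
#' @param priors a `bias_priors` table with one row per flagged trial
#'   (columns `trial_id`, `mean_logror`, `sd_logror`), or `NULL` for an
#'   unadjusted fit. Supplying a prior for an all-low trial, or omitting one
#'   for a flagged trial, is an error.
#' @param config an [mcmc_config()]; `benefit_direction` controls the
#'   internal sign of the bias term (see [mcmc_config()]).
#' @param tau_max upper bound of the uniform prior on the between-trial
#'   standard deviation tau (default 2, sensible on the log-OR scale).
#'   `tau_max = 0` fixes tau at zero exactly, i.e. fits the common-effect
#'   model `delta_i = d` (single-site Gibbs is degenerate for tau pinned
#'   near but not at zero, so the point mass is handled structurally).
#' @param rhat_threshold convergence is flagged when the largest
#'   Gelman-Rubin statistic over `d`, `tau` and all `delta_i` exceeds this
#'   (default 1.05).
#' @param thin thinning interval for retained draws.
#' @param quiet suppress sampler progress output.
#' @return an object of class `bias_adjusted_fit`: a list with elements
#'   `summary` (a [posterior_summary()]), `samples` (a [coda::mcmc.list] of
#'   the monitored parameters), `draws` (matrix of pooled `d` and `tau`
#'   draws), `rhat` (named vector), `converged` (logical), `config`,
#'   `tau_max` and `priors`.
#' @export
fit_bias_adjusted <- function(trials, priors = NULL, config = mcmc_config(),
                              tau_max = 2, rhat_threshold = 1.05,
                              thin = 1L, quiet = TRUE) {
  trials <- as_bias_trials(trials)
  if (!inherits(config, "mcmc_config")) {
    stopf("config must be an 'mcmc_config' object")
  }
  n <- nrow(trials)
  if (n < 2L) stopf("need at least two trials")
  flagged <- trials$profile_key != "LLL"

  x <- rep(0L, n)
  mu <- rep(0, n)
  prec <- rep(1, n)
  if (!is.null(priors)) {
    priors <- as_bias_priors(priors)
    extra <- setdiff(priors$trial_id, trials$trial_id[flagged])
    if (length(extra)) {
      stopf("bias prior supplied for non-flagged or unknown trial(s): %s",
            paste(extra, collapse = ", "))
    }
    missing <- setdiff(trials$trial_id[flagged], priors$trial_id)
    if (length(missing)) {
      stopf("missing bias prior for flagged trial(s): %s",
            paste(missing, collapse = ", "))
    }
    idx <- match(priors$trial_id, trials$trial_id)
    x[idx] <- 1L
    mu[idx] <- priors$mean_logror
    prec[idx] <- 1 / priors$sd_logror^2
  }

  s <- if (config$benefit_direction == "or_lt_1") 1 else -1
  common_effect <- tau_max == 0
  dat <- list(N = n, rc = trials$events_ctrl, nc = trials$n_ctrl,
              rt = trials$events_trt, nt = trials$n_trt,
              x = x, mu = mu, prec.beta = prec, s = s)
  if (!common_effect) dat$tau.max <- tau_max

  # Widely dispersed initial values across chains for d and tau.
  alpha0 <- stats::qlogis((trials$events_ctrl + 0.5) / (trials$n_ctrl + 1))
  inits <- chain_inits(config, extra = function(ch, k) {
    ini <- list(d = seq(-2, 2, length.out = k)[ch],
                alpha = alpha0,
                beta = mu)
    if (!common_effect) {
      ini$tau <- tau_max * seq(0.05, 0.95, length.out = k)[ch]
      ini$delta <- rep(0, n)
    }
    ini
  })

  model_str <- if (common_effect) .BIAS_ADJUST_MODEL_COMMON else
    .BIAS_ADJUST_MODEL
  monitors <- if (common_effect) "d" else c("d", "tau", "delta")
  sam <- run_jags(model_str, dat, inits, monitors = monitors,
                  n_burnin = config$n_burnin, n_iter = config$n_iter,
                  thin = thin, quiet = quiet)

  rhat <- gelman_rubin(sam)
  track <- grepl("^(d$|tau$|delta)", names(rhat))
  rhat_max <- max(rhat[track])
  converged <- is.finite(rhat_max) && rhat_max <= rhat_threshold
  if (!converged) {
    warnf("convergence not reached: max Rhat = %.3f (threshold %.2f)",
          rhat_max, rhat_threshold)
  }

  mat <- as.matrix(sam)
  d_draws <- mat[, "d"]
  tau_draws <- if (common_effect) rep(0, length(d_draws)) else mat[, "tau"]
  or_q <- summarize_draws(d_draws, "exp")
  tau2_q <- summarize_draws(tau_draws, "square")
  summ <- posterior_summary(or_q[["median"]], or_q[["lo"]], or_q[["hi"]],
                            tau2_q[["median"]], tau2_q[["lo"]],
                            tau2_q[["hi"]], rhat_max)

  structure(list(summary = summ,
                 samples = sam,
                 draws = cbind(d = d_draws, tau = tau_draws),
                 rhat = rhat,
                 converged = converged,
                 config = config,
                 tau_max = tau_max,
                 priors = priors),
            class = "bias_adjusted_fit")
}

#' @export
print.bias_adjusted_fit <- function(x, ...) {
  cat(sprintf("Bias-adjusted Bayesian meta-analysis (%s)\n",
              if (is.null(x$priors)) "unadjusted" else
                sprintf("%d bias prior(s)", nrow(x$priors))))
  print(x$summary)
  if (!x$converged) cat("WARNING: convergence flag raised\n")
  invisible(x)
}

#' Write retained draws of d and tau to CSV
#'
#' Plain-text draws file (columns `d`, `tau`) for external diagnostics.
#'
#' @param fit a `bias_adjusted_fit`.
#' @param path output path.
#' @export
write_draws <- function(fit, path) {
  if (!inherits(fit, "bias_adjusted_fit")) {
    stopf("write_draws() expects a 'bias_adjusted_fit'")
  }
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed on the second halves of the chains from the between- and
#' within-chain variances:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n\, W + B/n}{W}}.}
#' When every chain is constant, the statistic is 1 by convention if the
#' chains agree and `Inf` (non-mixing) if they sit at different levels.
#'
#' @param x either a [coda::mcmc.list] (returns a named vector, one value
#'   per monitored parameter) or a numeric matrix with one column per chain
#'   (returns a scalar).
#' @return potential scale reduction factor(s).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "mcmc.list")) {
    if (length(x) < 2L) stopf("gelman_rubin: need at least two chains")
    params <- colnames(x[[1]])
    out <- vapply(params, function(p) {
      gelman_rubin(sapply(x, function(ch) as.numeric(ch[, p])))
    }, numeric(1))
    names(out) <- params
    return(out)
  }
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2L) stopf("gelman_rubin: need at least two chains")
  if (nrow(x) < 10L) stopf("gelman_rubin: chains too short")
  # second halves only
  x <- x[(floor(nrow(x) / 2) + 1L):nrow(x), , drop = FALSE]
  n <- nrow(x)
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(means)  # = B/n
  if (W == 0) {
    return(if (B_over_n == 0) 1 else Inf)
  }
  # finite-sample noise can push the raw ratio slightly below 1; report 1
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

#' Posterior median and central 95% interval of transformed draws
#'
#' Empirical quantiles (type-7 interpolation of order statistics) after an
#' optional transform: `exp` for odds ratios from log-OR draws, `square`
#' for tau-squared from tau draws.
#'
#' @param draws numeric vector of at least 100 retained draws.
#' @param transform one of `"identity"`, `"exp"`, `"square"`.
#' @return named numeric `c(median, lo, hi)` (2.5 and 97.5 percentiles).
#' @export
summarize_draws <- function(draws, transform = c("identity", "exp",
                                                 "square")) {
  transform <- match.arg(transform)
  draws <- as.numeric(draws)
  if (length(draws) < 100L) {
    stopf("summarize_draws: need at least 100 draws (got %d)", length(draws))
  }
  y <- switch(transform, identity = draws, exp = exp(draws),
              square = draws^2)
  q <- stats::quantile(y, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], lo = q[2], hi = q[3])
}
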