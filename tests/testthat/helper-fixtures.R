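# Shared fixtures, built in code.

# fast MCMC profile for tests
test_config <- function(seed = 1L, benefit_direction = "or_lt_1",
                        n_iter = 4000L, n_burnin = 1000L) {
  mcmc_config(n_chains = 3L, n_iter = n_iter, n_burnin = n_burnin,
              seed = seed, benefit_direction = benefit_direction)
}

# three hand-written trials covering all-low, mixed and all-flagged profiles
example_trials <- function() {
  as_bias_trials(data.frame(
    trial_id = c("t1", "t2", "t3"),
    meta_id = "MA1",
    events_ctrl = c(12L, 30L, 7L),
    n_ctrl = c(60L, 120L, 45L),
    events_trt = c(8L, 22L, 4L),
    n_trt = c(58L, 115L, 44L),
    rob_seq = c("low", "Unclear", "high"),
    rob_conc = c("low", "low", "U"),
    rob_blind = c("low", "high", "H"),
    stringsAsFactors = FALSE
  ))
}

example_prior_table <- function(trials) {
  fl <- trials$trial_id[trials$profile_key != "LLL"]
  as_bias_priors(data.frame(trial_id = fl, mean_logror = -0.15,
                            sd_logror = 0.1, source = "data",
                            stringsAsFactors = FALSE))
}

# bias table covering the seven flagged profiles
example_bias_table <- function(path = NULL) {
  keys <- flagged_profile_keys()
  tab <- data.frame(profile_key = keys,
                    mean_logror = seq(-0.05, -0.25,
                                      length.out = length(keys)),
                    sd_logror = seq(0.08, 0.14, length.out = length(keys)))
  if (is.null(path)) return(tab)
  write_bias_table(tab, path)
  path
}

# quartile bounds of a truncated normal by bisection on its normalized CDF;
# independent oracle for area_to_iqr()
truncnorm_quartiles_bisect <- function(mu, sd, p_lo, p_hi, tol = 1e-12) {
  lo_z <- if (p_lo <= 0) -Inf else qnorm(p_lo)
  hi_z <- if (p_hi >= 1) Inf else qnorm(p_hi)
  mass <- p_hi - p_lo
  cdf_trunc <- function(z) (pnorm(pmin(pmax(z, lo_z), hi_z)) - p_lo) / mass
  invert <- function(target) {
    a <- if (is.finite(lo_z)) lo_z else -40
    b <- if (is.finite(hi_z)) hi_z else 40
    for (i in 1:200) {
      mid <- (a + b) / 2
      if (cdf_trunc(mid) < target) a <- mid else b <- mid
      if (b - a < tol) break
    }
    (a + b) / 2
  }
  mu + sd * c(invert(0.25), invert(0.75))
}
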