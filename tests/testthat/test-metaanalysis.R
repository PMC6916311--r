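test_that("gelman_rubin detects mixing and handles degenerate chains", {
  # identical constant chains: Rhat = 1 by convention
  const <- matrix(1.5, nrow = 100, ncol = 3)
  expect_identical(gelman_rubin(const), 1)
  # chains stuck at disjoint levels never mix
  disjoint <- cbind(rep(0, 100), rep(5, 100))
  expect_gt(gelman_rubin(disjoint), 1.1)
  # iid chains from one distribution converge to 1
  set.seed(5)
  iid <- matrix(rnorm(3e4), ncol = 3)
  r <- gelman_rubin(iid)
  expect_gte(r, 1.0)
  expect_lt(r, 1.01)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "two chains")

  # agrees with the coda reference implementation on well-mixed chains
  ml <- coda::mcmc.list(lapply(1:3, function(i) {
    coda::mcmc(cbind(p1 = rnorm(5000), p2 = rnorm(5000, 2, 3)))
  }))
  mine <- gelman_rubin(ml)
  ref <- coda::gelman.diag(ml, autoburnin = TRUE)$psrf[, 1]
  expect_equal(unname(mine), unname(ref), tolerance = 0.02)
})

test_that("summarize_draws computes type-7 quantiles after transforms", {
  # oracle: direct type-7 order-statistic computation on 1..1000/1000;
  # h = (n-1)p + 1 gives 500.5, 25.975 and 975.025
  draws <- (1:1000) / 1000
  s <- summarize_draws(draws, "identity")
  expect_equal(unname(s), c(0.5005, 0.025975, 0.975025), tolerance = 1e-12)
  # constant draws, exp transform
  cexp <- summarize_draws(rep(0.3, 200), "exp")
  expect_equal(unname(cexp), rep(exp(0.3), 3), tolerance = 1e-12)
  # monotone transforms commute with quantiles when the quantile positions
  # fall on order statistics (1001 draws: h = 26, 501, 976 exactly)
  set.seed(2)
  x <- rnorm(1001)
  expect_equal(summarize_draws(x, "exp"),
               exp(summarize_draws(x, "identity")), tolerance = 1e-12)
  expect_error(summarize_draws(rnorm(50)), "at least 100")
})

test_that("prior bookkeeping is validated before sampling", {
  trials <- example_trials()
  priors <- example_prior_table(trials)
  cfg <- test_config()
  # prior for an all-low trial is refused
  bad <- rbind(as.data.frame(priors),
               data.frame(trial_id = "t1", mean_logror = -0.1,
                          sd_logror = 0.1, source = "data"))
  expect_error(fit_bias_adjusted(trials, bad, cfg), "non-flagged")
  # flagged trial without a prior is refused
  expect_error(fit_bias_adjusted(trials, priors[1, ], cfg),
               "missing bias prior")
  expect_error(fit_bias_adjusted(trials[1, ], NULL, cfg), "two trials")
})

test_that("identical seed and config give identical samples", {
  sim <- simulate_meta_analysis(n_trials = 6, seed = 9)
  priors <- priors_from_bias_table(
    sim$trials,
    setNames(lapply(flagged_profile_keys(),
                    function(k) bias_dist(-0.15, 0.1, profile_key = k)),
             flagged_profile_keys()))
  cfg <- test_config(seed = 4, n_iter = 1500, n_burnin = 500)
  f1 <- fit_bias_adjusted(sim$trials, priors, cfg)
  f2 <- fit_bias_adjusted(sim$trials, priors, cfg)
  expect_identical(f1$draws, f2$draws)
  # a different seed moves the draws
  f3 <- fit_bias_adjusted(sim$trials, priors, test_config(seed = 5,
                                                          n_iter = 1500,
                                                          n_burnin = 500))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("null data recover an odds ratio near 1", {
  sim <- simulate_meta_analysis(n_trials = 8, d = 0, tau = 0,
                                bias_spec = NULL,
                                profiles = "LLL",
                                arm_size_range = c(800L, 1200L), seed = 3)
  fit <- fit_bias_adjusted(sim$trials, NULL, test_config(seed = 3))
  expect_lt(abs(log(fit$summary$or_median)), 0.07)
  expect_gt(fit$summary$or_hi, 1)
  expect_lt(fit$summary$or_lo, 1)
})

test_that("inflating prior sds never narrows the interval for d", {
  sim <- simulate_meta_analysis(n_trials = 8, d = -0.4, tau = 0.1, seed = 12)
  base <- example_bias_table()
  map1 <- load_bias_table(write_bias_table(
    base, withr::local_tempfile(fileext = ".csv")))
  wide <- base
  wide$sd_logror <- wide$sd_logror * 2
  map2 <- load_bias_table(write_bias_table(
    wide, withr::local_tempfile(fileext = ".csv")))
  cfg <- test_config(seed = 8, n_iter = 8000, n_burnin = 2000)
  f1 <- fit_bias_adjusted(sim$trials, priors_from_bias_table(sim$trials,
                                                             map1), cfg)
  f2 <- fit_bias_adjusted(sim$trials, priors_from_bias_table(sim$trials,
                                                             map2), cfg)
  w1 <- log(f1$summary$or_hi) - log(f1$summary$or_lo)
  w2 <- log(f2$summary$or_hi) - log(f2$summary$or_lo)
  expect_gte(w2, w1 - 0.02)  # MC slack documented: medians carry MC error
})

test_that("bias adjustment absorbs heterogeneity generated by biases", {
  # spread between trials comes from strongly varying biases
  sim <- simulate_meta_analysis(
    n_trials = 12, d = -0.3, tau = 0.05,
    bias_spec = c(mean = -0.4, sd = 0.3),
    profiles = c("LLL", "LLL", rep(c("XLL", "XXL", "XXX", "LXX", "LXL"), 2)),
    arm_size_range = c(150L, 300L), seed = 21)
  priors <- as_bias_priors(data.frame(
    trial_id = sim$trials$trial_id[sim$trials$profile_key != "LLL"],
    mean_logror = -0.4, sd_logror = 0.3))
  cfg <- test_config(seed = 2, n_iter = 8000, n_burnin = 2000)
  unadj <- fit_bias_adjusted(sim$trials, NULL, cfg)
  adj <- fit_bias_adjusted(sim$trials, priors, cfg)
  expect_lte(adj$summary$tau2_median, unadj$summary$tau2_median)
})

test_that("draws file and summary JSON are written for a fit", {
  sim <- simulate_meta_analysis(n_trials = 5, seed = 2)
  fit <- fit_bias_adjusted(sim$trials, NULL,
                           test_config(n_iter = 1500, n_burnin = 500))
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, dpath)
  dd <- read.csv(dpath)
  expect_identical(names(dd), c("d", "tau"))
  expect_identical(nrow(dd), nrow(fit$draws))
  spath <- withr::local_tempfile(fileext = ".json")
  write_summary(fit$summary, spath, fit$config)
  expect_s3_class(read_summary(spath), "posterior_summary")
})
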