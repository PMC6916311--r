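test_that("generators are deterministic under a seed and round-trip CSVs", {
  s1 <- simulate_meta_analysis(n_trials = 8, seed = 42)
  s2 <- simulate_meta_analysis(n_trials = 8, seed = 42)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_meta_analysis(n_trials = 8, seed = 43)
  expect_false(identical(s1$trials, s3$trials))

  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(s1$trials, path)
  expect_identical(as.data.frame(read_trials(path)),
                   as.data.frame(s1$trials))

  m1 <- simulate_meta_epi(n_meta = 4, trials_per_meta = 4, seed = 7)
  m2 <- simulate_meta_epi(n_meta = 4, trials_per_meta = 4, seed = 7)
  expect_identical(m1$trials, m2$trials)

  e1 <- simulate_elicitations(c(t1 = -0.2, t2 = 0.1), seed = 3)
  e2 <- simulate_elicitations(c(t1 = -0.2, t2 = 0.1), seed = 3)
  expect_identical(e1$elicitations, e2$elicitations)
  ep <- withr::local_tempfile(fileext = ".csv")
  write_elicitations(e1$elicitations, ep)
  expect_equal(as.data.frame(read_elicitations(ep)),
               as.data.frame(e1$elicitations), tolerance = 1e-12)

  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_meta_analysis(seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noise-free limit reproduces the true effect in every trial", {
  sim <- simulate_meta_analysis(n_trials = 6, d = -0.5, tau = 0,
                                bias_spec = NULL, profiles = "LLL",
                                arm_size_range = c(2e5, 2e5), seed = 1)
  tr <- sim$trials
  logor <- log(tr$events_trt / (tr$n_trt - tr$events_trt)) -
    log(tr$events_ctrl / (tr$n_ctrl - tr$events_ctrl))
  expect_true(all(abs(logor - (-0.5)) < 0.03))
})

test_that("sample log odds ratios average to d plus the mean bias", {
  n <- 10000
  sim <- simulate_meta_analysis(n_trials = n, d = -0.3, tau = 0.1,
                                bias_spec = c(mean = -0.2, sd = 0.05),
                                profiles = rep(c("LLL", "XXL"), n / 2),
                                arm_size_range = c(400L, 600L), seed = 8)
  tr <- sim$trials
  logor <- log((tr$events_trt + 0.5) / (tr$n_trt - tr$events_trt + 0.5)) -
    log((tr$events_ctrl + 0.5) / (tr$n_ctrl - tr$events_ctrl + 0.5))
  expected <- -0.3 + mean(sim$truth$beta)
  mc_sd <- sd(logor) / sqrt(n)
  expect_lt(abs(mean(logor) - expected), 3 * mc_sd + 0.005)
})

test_that("meta-epi generator honours its hierarchy and profile guarantees", {
  # degenerate variances: every flagged trial carries exactly b0
  zero_var <- rbind(seq = c(-0.3, 0, 0), conc = c(-0.2, 0, 0),
                    blind = c(-0.1, 0, 0))
  sim <- simulate_meta_epi(n_meta = 5, trials_per_meta = 4,
                           domain_params = zero_var, seed = 4)
  expect_true(all(abs(sim$truth$b_mc[, 1] - (-0.3)) < 1e-12))

  # every meta-analysis holds at least one all-low and one flagged trial
  big <- simulate_meta_epi(n_meta = 30, trials_per_meta = 3, seed = 5)
  per_meta <- split(big$trials$profile_key, big$trials$meta_id)
  expect_true(all(vapply(per_meta, function(k) {
    any(k == "LLL") && any(k != "LLL")
  }, logical(1))))

  expect_error(simulate_meta_epi(n_meta = 1), "at least 2")
  expect_error(simulate_meta_epi(trials_per_meta = 1), "profile mix")
})

test_that("flagged-vs-unflagged contrast matches the analytic expectation", {
  dp <- rbind(seq = c(b0 = -0.25, phi = 0.05, kappa = 0.05),
              conc = c(b0 = 0, phi = 0, kappa = 0),
              blind = c(b0 = 0, phi = 0, kappa = 0))
  sim <- simulate_meta_epi(n_meta = 300, trials_per_meta = 6,
                           domain_params = dp, p_flag = 1, tau_m = 0.05,
                           arm_size_range = c(300L, 500L), seed = 13)
  tr <- sim$trials
  logor <- log((tr$events_trt + 0.5) / (tr$n_trt - tr$events_trt + 0.5)) -
    log((tr$events_ctrl + 0.5) / (tr$n_ctrl - tr$events_ctrl + 0.5))
  flagged <- tr$flag_seq == 1L
  contrasts <- vapply(split(seq_len(nrow(tr)), tr$meta_id), function(i) {
    mean(logor[i][flagged[i]]) - mean(logor[i][!flagged[i]])
  }, numeric(1))
  mc_sd <- sd(contrasts) / sqrt(length(contrasts))
  expect_lt(abs(mean(contrasts) - (-0.25)), 3 * mc_sd)
})

test_that("elicitation generator recovers true biases when assessors agree", {
  biases <- c(t1 = -0.24, t2 = -0.1, t3 = 0.06)
  sim <- simulate_elicitations(biases, n_assessors = 4,
                               assessor_shift_sd = 0, within_sd = 0.2,
                               strategy = "a", seed = 6)
  priors <- process_elicitations(sim$elicitations, "a")
  expect_true(all(abs(priors$mean_logror[match(names(biases),
                                               priors$trial_id)] -
                        biases) <= 0.01 + 1e-12))

  # strategy c with the centre at the reference mean picks a central area
  map <- list(XLL = bias_dist(-0.15, 0.1, profile_key = "XLL"))
  keys <- c(tc = "XLL")
  simc <- simulate_elicitations(c(tc = -0.15), n_assessors = 3,
                                assessor_shift_sd = 0, within_sd = 0.1,
                                strategy = "c", reference_map = map,
                                trial_keys = keys, seed = 2)
  expect_true(all(simc$elicitations$areas %in% c("B", "C", "B+C")))

  expect_error(simulate_elicitations(biases, within_sd = 0), "positive")
  expect_error(simulate_elicitations(unname(biases)), "named")
})

test_that("high assessor disagreement drives the downstream ICC toward 0", {
  set.seed(14)
  biases <- rnorm(30, -0.15, 0.02)   # tiny trial spread
  names(biases) <- sprintf("t%02d", 1:30)
  sim <- simulate_elicitations(biases, n_assessors = 4,
                               assessor_shift_sd = 0.5, within_sd = 0.2,
                               strategy = "a", seed = 15)
  normals <- elicitation_normals(sim$elicitations)
  r <- icc_with_ci(normals, n_boot = 100, seed = 3)
  expect_lt(r$icc, 0.15)
})
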