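test_that("log-ROR rounding snaps to the 0.02 grid, ties away from zero", {
  expect_equal(round_log_ror(-0.1985), -0.20)
  expect_equal(round_log_ror(0), 0)
  # exact midpoints: |0.03 - 0.02| == |0.03 - 0.04|, resolved away from zero
  expect_equal(round_log_ror(0.03), 0.04)
  expect_equal(round_log_ror(-0.03), -0.04)
  expect_error(round_log_ror(Inf), "finite")

  # never moves a value by more than half the grid
  set.seed(11)
  x <- runif(500, -1.5, 1.5)
  expect_true(all(abs(round_log_ror(x) - x) <= 0.01 + 1e-12))
  expect_true(all(abs(round_log_ror(x) / 0.02 -
                        round(round_log_ror(x) / 0.02)) < 1e-9))
})

test_that("IQR opinions map to normals whose quartiles recover the IQR", {
  x <- iqr_to_normal(0.82, 1.00, "ass1", "t1")
  expect_equal(x$mean, -0.10, tolerance = 1e-12)
  expect_equal(x$sd, 0.10 / 0.67, tolerance = 1e-12)
  # oracle: the 25/75 percentiles of N(mean, sd) sit within 0.01 of the
  # rounded elicitation bounds (0.67 is the 2-dp quartile constant)
  expect_lt(abs(qnorm(0.25, x$mean, x$sd) - (-0.20)), 0.01)
  expect_lt(abs(qnorm(0.75, x$mean, x$sd) - 0.00), 0.01)

  # symmetric intervals centre at zero
  for (cc in c(1.1, 1.5, 2.4)) {
    expect_equal(iqr_to_normal(1 / cc, cc)$mean, 0, tolerance = 1e-12)
  }
  # degenerate width after rounding is refused: both bounds of
  # (0.995, 1.005) snap to 0.00 on the 0.02 log grid
  expect_error(iqr_to_normal(0.995, 1.005, trial_id = "t9"), "zero-width")
})

test_that("area selections give truncated-normal quartiles", {
  full <- area_to_iqr(bias_dist(0, 1), "A+B+C+D")
  expect_equal(unname(full), c(qnorm(0.25), qnorm(0.75)), tolerance = 1e-12)

  bc <- area_to_iqr(bias_dist(0, 1), "B+C")
  expect_equal(unname(bc), c(qnorm(0.375), qnorm(0.625)), tolerance = 1e-12)

  # symmetric selections centre on the reference mean
  ref <- bias_dist(-0.17, 0.23)
  for (sel in c("B+C", "A+B+C+D")) {
    iqr <- area_to_iqr(ref, sel)
    expect_equal(mean(iqr), ref$mean, tolerance = 1e-12)
  }
  expect_error(area_to_iqr(bias_dist(0, 1), c("A", "C")), "contiguous")
  expect_error(area_to_iqr(bias_dist(0, 1), character(0)), "empty")
})

test_that("narrower selected areas give narrower mapped opinions", {
  ref <- bias_dist(-0.2, 0.3)
  sd_of <- function(areas) {
    iqr <- area_to_iqr(ref, areas)
    iqr_to_normal(exp(iqr[["lower"]]), exp(iqr[["upper"]]))$sd
  }
  expect_lt(sd_of("B"), sd_of("B+C"))
  expect_lt(sd_of("B+C"), sd_of("A+B+C+D"))
})

test_that("pooling across assessors takes medians and resists outliers", {
  ops <- data.frame(trial_id = "t1", assessor_id = paste0("A", 1:4),
                    mean = c(-0.1, -0.2, -0.3, 0.0),
                    sd = c(0.1, 0.2, 0.3, 0.4))
  pooled <- pool_assessors(ops)
  expect_equal(pooled$mean, -0.15, tolerance = 1e-12)
  expect_equal(pooled$sd, 0.25, tolerance = 1e-12)
  expect_identical(pooled$source, "opinion")

  # single assessor passes through unchanged
  one <- pool_assessors(ops[2, ])
  expect_equal(one$mean, -0.2)
  expect_equal(one$sd, 0.2)

  # one extreme opinion moves the pooled mean at most to the adjacent
  # order statistic
  extreme <- ops
  extreme$mean[4] <- -50
  pooled_ex <- pool_assessors(extreme)
  expect_gte(pooled_ex$mean, -0.3)
  expect_lte(pooled_ex$mean, -0.1)

  expect_error(pool_assessors(ops[0, ]), "non-empty")
  ops$trial_id[2] <- "t2"
  expect_error(pool_assessors(ops), "mix")
})

test_that("numeric strategies a and b share one processing path", {
  df <- data.frame(assessor_id = rep(paste0("A", 1:4), 2),
                   trial_id = "t1",
                   strategy = rep(c("a", "b"), each = 4),
                   lower_ror = rep(c(0.7, 0.8, 0.75, 0.85), 2),
                   upper_ror = rep(c(1.0, 1.1, 0.95, 1.2), 2),
                   areas = "", stringsAsFactors = FALSE)
  pa <- process_elicitations(as_elicitations(df), "a")
  pb <- process_elicitations(as_elicitations(df), "b")
  expect_equal(pa$mean_logror, pb$mean_logror, tolerance = 1e-12)
  expect_equal(pa$sd_logror, pb$sd_logror, tolerance = 1e-12)
})

test_that("area-selection records are processed against the reference", {
  tab <- example_bias_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_bias_table(tab, path)
  map <- load_bias_table(path)
  trials <- example_trials()
  keys <- setNames(trials$profile_key, trials$trial_id)
  df <- data.frame(assessor_id = paste0("A", 1:2), trial_id = "t2",
                   strategy = "c", lower_ror = NA_real_,
                   upper_ror = NA_real_, areas = c("B+C", "B"),
                   stringsAsFactors = FALSE)
  priors <- process_elicitations(as_elicitations(df), "c",
                                 reference_map = map, trial_keys = keys)
  expect_identical(priors$source, "area")
  expect_identical(priors$trial_id, "t2")
  # pooled mean sits near the reference mean for near-central selections
  ref <- map[["XLX"]]
  expect_lt(abs(priors$mean_logror - ref$mean), ref$sd)
  # missing reference inputs are an error
  expect_error(process_elicitations(as_elicitations(df), "c"),
               "reference_map")
})
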