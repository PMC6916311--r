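# Synthetic-data generators with known ground truth for every input kind:
# single meta-analyses of 2x2 trials, meta-epidemiological collections, and
# elicitation records. Each generator seeds a local RNG (no hidden global
# state) and returns the simulation truth alongside the records, so
# round-trip and recovery tests need no external data.

default_bias_spec <- function() c(mean = -0.15, sd = 0.1)

resolve_bias_spec <- function(bias_spec, key) {
  if (is.null(bias_spec)) return(c(mean = 0, sd = 0))
  if (is.numeric(bias_spec) && length(bias_spec) == 2L) {
    return(c(mean = unname(bias_spec[1]), sd = unname(bias_spec[2])))
  }
  if (is.data.frame(bias_spec)) {
    require_columns(bias_spec, c("profile_key", "mean_logror", "sd_logror"),
                    "bias_spec")
    i <- match(key, bias_spec$profile_key)
    if (is.na(i)) stopf("bias_spec has no row for profile key '%s'", key)
    return(c(mean = bias_spec$mean_logror[i], sd = bias_spec$sd_logror[i]))
  }
  stopf("bias_spec must be NULL, c(mean, sd), or a profile-keyed data frame")
}

random_judgements <- function(flags, p_high = 0.3) {
  vapply(flags, function(f) {
    if (f == 0L) "low" else sample(c("high", "unclear"), 1L,
                                   prob = c(p_high, 1 - p_high))
  }, character(1))
}

#' Simulate one meta-analysis of binary-outcome trials
#'
#' Generates trials from the same model the bias-adjusted analysis fits:
#' true effects `delta_i ~ N(d, tau^2)` on the log-OR scale, a bias term
#' `beta_i` for each flagged trial drawn from its profile's bias
#' distribution, control-arm log odds from uniform control risks, and
#' binomial arm counts.
#'
#' @param n_trials number of trials (at least 2); default mirrors a typical
#'   small meta-analysis.
#' @param d true mean intervention effect (log OR).
#' @param tau true between-trial heterogeneity sd (log OR).
#' @param bias_spec bias distribution for flagged trials: `NULL` (no bias),
#'   a numeric `c(mean, sd)` applied to every flagged profile, or a data
#'   frame with columns `profile_key`, `mean_logror`, `sd_logror`.
#' @param profiles character vector of profile keys per trial (recycled).
#'   Default: one all-low trial, the rest drawn from the seven flagged keys.
#' @param arm_size_range integer range for per-arm sizes.
#' @param ctrl_rate_range range of control-arm event risks, inside (0, 1).
#' @param benefit_direction orientation in which the bias acts (see
#'   [mcmc_config()]); the treated-arm linear predictor is
#'   `alpha + delta + s * beta` with `s = +1` for `"or_lt_1"`.
#' @param meta_id meta-analysis identifier written into the records.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list with `trials` (a `bias_trials` data frame) and `truth`
#'   (list: `d`, `tau`, `delta`, `beta`, `alpha`, `profiles`, `seed`).
#' @export
simulate_meta_analysis <- function(n_trials = 10L, d = -0.4, tau = 0.2,
                                   bias_spec = default_bias_spec(),
                                   profiles = NULL,
                                   arm_size_range = c(50L, 200L),
                                   ctrl_rate_range = c(0.2, 0.5),
                                   benefit_direction = c("or_lt_1",
                                                         "or_gt_1"),
                                   meta_id = "MA1", seed = 1L) {
  benefit_direction <- match.arg(benefit_direction)
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L) stopf("need at least 2 trials")
  if (tau < 0) stopf("tau must be >= 0")
  if (diff(arm_size_range) < 0 || arm_size_range[1] < 1) {
    stopf("degenerate arm_size_range")
  }
  if (any(ctrl_rate_range <= 0) || any(ctrl_rate_range >= 1) ||
      diff(ctrl_rate_range) < 0) {
    stopf("degenerate ctrl_rate_range: rates must lie in (0, 1)")
  }
  with_seed(seed, {
    if (is.null(profiles)) {
      profiles <- c("LLL", sample(flagged_profile_keys(), n_trials - 1L,
                                  replace = TRUE))
    } else {
      profiles <- rep_len(as.character(profiles), n_trials)
    }
    s <- if (benefit_direction == "or_lt_1") 1 else -1
    delta <- stats::rnorm(n_trials, d, tau)
    beta <- vapply(profiles, function(k) {
      if (k == "LLL") return(0)
      bs <- resolve_bias_spec(bias_spec, k)
      if (bs[["sd"]] == 0) bs[["mean"]] else
        stats::rnorm(1L, bs[["mean"]], bs[["sd"]])
    }, numeric(1))
    alpha <- stats::qlogis(stats::runif(n_trials, ctrl_rate_range[1],
                                        ctrl_rate_range[2]))
    n_ctrl <- sample(arm_size_range[1]:arm_size_range[2], n_trials,
                     replace = TRUE)
    n_trt <- sample(arm_size_range[1]:arm_size_range[2], n_trials,
                    replace = TRUE)
    flags <- t(vapply(profiles, function(k) {
      as.integer(strsplit(k, "")[[1]] == "X")
    }, integer(3)))
    rob <- matrix("low", n_trials, 3L)
    for (i in seq_len(n_trials)) rob[i, ] <- random_judgements(flags[i, ])
    trials <- data.frame(
      trial_id = sprintf("t%02d", seq_len(n_trials)),
      meta_id = meta_id,
      events_ctrl = stats::rbinom(n_trials, n_ctrl, stats::plogis(alpha)),
      n_ctrl = n_ctrl,
      events_trt = stats::rbinom(n_trials, n_trt,
                                 stats::plogis(alpha + delta + s * beta)),
      n_trt = n_trt,
      rob_seq = rob[, 1], rob_conc = rob[, 2], rob_blind = rob[, 3],
      stringsAsFactors = FALSE
    )
    list(trials = as_bias_trials(trials),
         truth = list(d = d, tau = tau, delta = delta, beta = beta,
                      alpha = alpha, profiles = profiles,
                      benefit_direction = benefit_direction, seed = seed))
  })
}

#' Simulate a meta-epidemiological collection
#'
#' Generates trials across many meta-analyses under the two-level additive
#' domain-bias model fitted by [fit_meta_epi()]: domain c has mean bias
#' `b0_c`, between-meta-analysis sd `phi_c` and within-meta-analysis sd
#' `kappa_c`. Each meta-analysis is guaranteed at least one all-low and one
#' flagged trial.
#'
#' @param n_meta number of meta-analyses (at least 2).
#' @param trials_per_meta trials in each meta-analysis (at least 2).
#' @param domain_params 3x3 matrix-like: rows `seq`, `conc`, `blind`,
#'   columns `b0`, `phi`, `kappa` (or a list of named length-3 vectors).
#' @param d_sd sd of meta-analysis mean effects `d_m ~ N(0, d_sd^2)`.
#' @param tau_m within-meta-analysis heterogeneity sd (shared).
#' @param p_flag probability that a domain is flagged in a non-all-low
#'   trial.
#' @inheritParams simulate_meta_analysis
#' @return list with `trials` (a `bias_trials` data frame spanning
#'   `n_meta` meta-analyses) and `truth` (list incl. the domain parameter
#'   matrix, meta effects `d_m` and per-meta domain biases `b_mc`).
#' @export
simulate_meta_epi <- function(n_meta = 40L, trials_per_meta = 10L,
                              domain_params = rbind(
                                seq = c(b0 = -0.2, phi = 0.1, kappa = 0.1),
                                conc = c(b0 = -0.15, phi = 0.1, kappa = 0.1),
                                blind = c(b0 = -0.1, phi = 0.1, kappa = 0.1)),
                              d_sd = 0.7, tau_m = 0.1, p_flag = 0.6,
                              arm_size_range = c(50L, 200L),
                              ctrl_rate_range = c(0.2, 0.5), seed = 1L) {
  n_meta <- as.integer(n_meta)
  trials_per_meta <- as.integer(trials_per_meta)
  if (n_meta < 2L) stopf("need at least 2 meta-analyses")
  if (trials_per_meta < 2L) {
    stopf(paste("impossible profile mix: need >= 2 trials per meta-analysis",
                "to hold an all-low and a flagged trial"))
  }
  dp <- if (is.list(domain_params) && !is.data.frame(domain_params)) {
    do.call(rbind, domain_params)
  } else {
    as.matrix(domain_params)
  }
  if (!all(dim(dp) == c(3L, 3L))) {
    stopf("domain_params must give b0, phi, kappa for the 3 domains")
  }
  rownames(dp) <- .DOMAIN_KEYS
  colnames(dp) <- c("b0", "phi", "kappa")
  if (any(dp[, c("phi", "kappa")] < 0)) stopf("phi and kappa must be >= 0")

  with_seed(seed, {
    d_m <- stats::rnorm(n_meta, 0, d_sd)
    b_mc <- sapply(1:3, function(c) stats::rnorm(n_meta, dp[c, "b0"],
                                                 dp[c, "phi"]))
    all_rows <- vector("list", n_meta)
    for (m in seq_len(n_meta)) {
      nt <- trials_per_meta
      flags <- matrix(0L, nt, 3L)
      # trial 1 all-low; remaining trials flagged with Bernoulli domains,
      # forcing at least one flagged trial
      for (i in 2:nt) flags[i, ] <- stats::rbinom(3L, 1L, p_flag)
      if (all(rowSums(flags) == 0L)) flags[nt, sample(3L, 1L)] <- 1L
      beta <- sapply(1:3, function(c) {
        stats::rnorm(nt, b_mc[m, c], dp[c, "kappa"])
      })
      delta <- stats::rnorm(nt, d_m[m], tau_m)
      alpha <- stats::qlogis(stats::runif(nt, ctrl_rate_range[1],
                                          ctrl_rate_range[2]))
      n_ctrl <- sample(arm_size_range[1]:arm_size_range[2], nt, TRUE)
      n_trt <- sample(arm_size_range[1]:arm_size_range[2], nt, TRUE)
      lp <- alpha + delta + rowSums(flags * beta)
      rob <- matrix("low", nt, 3L)
      for (i in seq_len(nt)) rob[i, ] <- random_judgements(flags[i, ])
      all_rows[[m]] <- data.frame(
        trial_id = sprintf("m%03d_t%02d", m, seq_len(nt)),
        meta_id = sprintf("m%03d", m),
        events_ctrl = stats::rbinom(nt, n_ctrl, stats::plogis(alpha)),
        n_ctrl = n_ctrl,
        events_trt = stats::rbinom(nt, n_trt, stats::plogis(lp)),
        n_trt = n_trt,
        rob_seq = rob[, 1], rob_conc = rob[, 2], rob_blind = rob[, 3],
        stringsAsFactors = FALSE
      )
    }
    list(trials = as_bias_trials(do.call(rbind, all_rows)),
         truth = list(domain_params = dp, d_m = d_m, b_mc = b_mc,
                      d_sd = d_sd, tau_m = tau_m, seed = seed))
  })
}

#' Simulate elicitation records with known ground truth
#'
#' Emulates an elicitation exercise: each assessor's centre of opinion on a
#' trial's bias is the true bias plus an assessment-level disagreement shift
#' drawn independently per (assessor, trial) pair, and the stated IQR has
#' half-width `0.67 * within_sd` on the log-ROR scale (strategies `a` and
#' `b`). For strategy `c` the assessor selects the quartile region of the
#' reference distribution containing their centre (the central pair `B+C`
#' when the centre falls exactly on the reference median). The intraclass
#' correlation implied for the processed opinion means is therefore
#' `var(true_biases) / (var(true_biases) + assessor_shift_sd^2)`, up to
#' grid-rounding noise.
#'
#' @param true_biases named numeric vector of true log-ROR biases by
#'   trial_id.
#' @param n_assessors number of assessors (at least 2); default 4 matches a
#'   group of assessors sharing one strategy.
#' @param assessor_shift_sd sd of the per-assessment disagreement shifts
#'   (log-ROR); 0 makes every assessor's centre equal the true bias.
#' @param within_sd each assessor's opinion sd (log-ROR), must be positive.
#' @param strategy elicitation strategy for all records (`"a"`, `"b"`,
#'   `"c"`).
#' @param reference_map,trial_keys required for strategy `c`: the
#'   profile-keyed reference distributions and the trial-to-profile map.
#' @param assessor_prefix prefix for generated assessor ids.
#' @param seed integer seed.
#' @return list with `elicitations` (an `elicitations` data frame) and
#'   `truth` (list: `true_biases`, `assessor_shifts`, `within_sd`).
#' @export
simulate_elicitations <- function(true_biases, n_assessors = 4L,
                                  assessor_shift_sd = 0.05,
                                  within_sd = 0.15,
                                  strategy = c("a", "b", "c"),
                                  reference_map = NULL, trial_keys = NULL,
                                  assessor_prefix = "A", seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(names(true_biases)) || any(!nzchar(names(true_biases)))) {
    stopf("true_biases must be a named vector (names = trial ids)")
  }
  if (n_assessors < 2L) stopf("need at least 2 assessors")
  if (!is.finite(within_sd) || within_sd <= 0) {
    stopf("within_sd must be positive")
  }
  if (strategy == "c" && (is.null(reference_map) || is.null(trial_keys))) {
    stopf("strategy c needs reference_map and trial_keys")
  }
  with_seed(seed, {
    shifts <- matrix(stats::rnorm(n_assessors * length(true_biases), 0,
                                  assessor_shift_sd),
                     nrow = n_assessors,
                     dimnames = list(NULL, names(true_biases)))
    rows <- list()
    for (j in seq_len(n_assessors)) {
      for (t in names(true_biases)) {
        centre <- true_biases[[t]] + shifts[j, t]
        if (strategy %in% c("a", "b")) {
          rows[[length(rows) + 1L]] <- data.frame(
            assessor_id = paste0(assessor_prefix, j), trial_id = t,
            strategy = strategy,
            lower_ror = exp(centre - .IQR_NORMAL_CONST * within_sd),
            upper_ror = exp(centre + .IQR_NORMAL_CONST * within_sd),
            areas = "", stringsAsFactors = FALSE)
        } else {
          key <- unname(trial_keys[t])
          if (is.na(key)) stopf("no profile key for trial %s", t)
          ref <- lookup_bias(reference_map, key)
          z <- stats::pnorm((centre - ref$mean) / ref$sd)
          area <- if (abs(z - 0.5) < 1e-9) "B+C" else
            .AREAS[findInterval(z, c(0, 0.25, 0.5, 0.75, 1),
                                rightmost.closed = TRUE)]
          rows[[length(rows) + 1L]] <- data.frame(
            assessor_id = paste0(assessor_prefix, j), trial_id = t,
            strategy = "c", lower_ror = NA_real_, upper_ror = NA_real_,
            areas = area, stringsAsFactors = FALSE)
        }
      }
    }
    list(elicitations = as_elicitations(do.call(rbind, rows)),
         truth = list(true_biases = true_biases, assessor_shifts = shifts,
                      within_sd = within_sd, strategy = strategy,
                      seed = seed))
  })
}
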