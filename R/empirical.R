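# Data-based bias evidence (method 1): hierarchical model over a
# meta-epidemiological collection, and predictive bias distributions per
# bias profile.
#
# Model, for trial t in meta-analysis m with domain flags x[t,c]:
#   events ~ Binomial as in the meta-analysis module
#   logit(p_trt) = alpha_t + delta_t + sum_c x[t,c] beta[t,c]
#   delta_t   ~ N(d_m, tau_m^2)
#   beta[t,c] ~ N(b_mc, kappa_c^2)     within-meta-analysis bias variation
#   b_mc      ~ N(b0_c, phi_c^2)       between-meta-analysis variation
#   d_m ~ N(0, 1e5); tau_m ~ U(0,2); b0_c ~ N(0, 1e3); phi_c, kappa_c ~ U(0,2)
# Domain components are additive and a priori independent, so the predictive
# bias for a profile is the sum of its flagged domain predictives, each
# N(b0_c, phi_c^2 + kappa_c^2) given the hyperparameters.

.META_EPI_MODEL <- "
model {
  for (t in 1:N) {
    rc[t] ~ dbin(pc[t], nc[t])
    rt[t] ~ dbin(pt[t], nt[t])
    logit(pc[t]) <- alpha[t]
    logit(pt[t]) <- alpha[t] + delta[t] +
      x[t,1] * beta[t,1] + x[t,2] * beta[t,2] + x[t,3] * beta[t,3]
    alpha[t] ~ dnorm(0, 1.0E-5)
    delta[t] ~ dnorm(d[meta[t]], prec.tau[meta[t]])
    for (c in 1:3) {
      beta[t,c] ~ dnorm(b[meta[t],c], prec.kappa[c])
    }
  }
  for (m in 1:M) {
    d[m] ~ dnorm(0, 1.0E-5)
    tau[m] ~ dunif(0, 2)
    prec.tau[m] <- pow(tau[m], -2)
    for (c in 1:3) {
      b[m,c] ~ dnorm(b0[c], prec.phi[c])
    }
  }
  for (c in 1:3) {
    b0[c] ~ dnorm(0, 1.0E-3)
    phi[c] ~ dunif(0, 2)
    kappa[c] ~ dunif(0, 2)
    prec.phi[c] <- pow(phi[c], -2)
    prec.kappa[c] <- pow(kappa[c], -2)
  }
}
"

.DOMAIN_KEYS <- c("seq", "conc", "blind")
.HYPER_COLS <- c(paste0("b0_", .DOMAIN_KEYS), paste0("phi_", .DOMAIN_KEYS),
                 paste0("kappa_", .DOMAIN_KEYS))

# Lower bound on predictive sd, protecting downstream samplers from
# degenerate priors.
.PREDICTIVE_SD_FLOOR <- 1e-6

#' Fit the hierarchical bias model to a meta-epidemiological collection
#'
#' Estimates, for each risk-of-bias domain (sequence generation, allocation
#' concealment, blinding), the mean bias `b0_c` on the log-ROR scale and its
#' between- (`phi_c`) and within-meta-analysis (`kappa_c`) standard
#' deviations, from a collection of meta-analyses containing both all-low
#' and flagged trials.
#'
#' @param records a `bias_trials` data frame spanning several meta-analyses
#'   (`meta_id` column distinguishes them). A meta-analysis contributes to
#'   bias identification only if it contains at least one all-low and one
#'   flagged trial; fewer than two such meta-analyses raises a diagnostic
#'   warning (variance components then largely follow their priors).
#' @param config an [mcmc_config()].
#' @param rhat_threshold convergence flag threshold on the hyperparameters.
#' @param thin thinning interval.
#' @param quiet suppress sampler progress output.
#' @return an object of class `meta_epi_fit`: list with `draws` (matrix of
#'   pooled posterior draws, columns `b0_seq`, ..., `kappa_blind`),
#'   `samples` (a [coda::mcmc.list]), `rhat`, `converged`, `identified`,
#'   `config`.
#' @export
fit_meta_epi <- function(records, config = mcmc_config(),
                         rhat_threshold = 1.05, thin = 1L, quiet = TRUE) {
  records <- as_bias_trials(records)
  if (!inherits(config, "mcmc_config")) {
    stopf("config must be an 'mcmc_config' object")
  }
  metas <- unique(records$meta_id)
  flagged <- records$profile_key != "LLL"
  if (!any(flagged)) {
    stopf("identification error: collection contains no flagged trials")
  }
  has_both <- vapply(metas, function(m) {
    f <- flagged[records$meta_id == m]
    any(f) && any(!f)
  }, logical(1))
  identified <- sum(has_both) >= 2L
  if (!identified) {
    warnf(paste("fewer than two meta-analyses contain both all-low and",
                "flagged trials; bias variance components are weakly",
                "identified"))
  }

  meta_idx <- match(records$meta_id, metas)
  x <- cbind(records$flag_seq, records$flag_conc, records$flag_blind)
  dat <- list(N = nrow(records), M = length(metas),
              rc = records$events_ctrl, nc = records$n_ctrl,
              rt = records$events_trt, nt = records$n_trt,
              x = x, meta = meta_idx)

  alpha0 <- stats::qlogis((records$events_ctrl + 0.5) / (records$n_ctrl + 1))
  inits <- chain_inits(config, extra = function(ch, k) {
    spread <- seq(-0.5, 0.5, length.out = k)[ch]
    list(b0 = rep(spread, 3),
         phi = rep(seq(0.05, 0.5, length.out = k)[ch], 3),
         kappa = rep(seq(0.05, 0.5, length.out = k)[ch], 3),
         d = rep(0, length(metas)),
         tau = rep(0.1, length(metas)),
         alpha = alpha0)
  })

  sam <- run_jags(.META_EPI_MODEL, dat, inits,
                  monitors = c("b0", "phi", "kappa"),
                  n_burnin = config$n_burnin, n_iter = config$n_iter,
                  thin = thin, quiet = quiet)

  rhat <- gelman_rubin(sam)
  rhat_max <- max(rhat)
  converged <- is.finite(rhat_max) && rhat_max <= rhat_threshold
  if (!converged) {
    warnf(paste("meta-epi fit: max Rhat = %.3f exceeds %.2f; treat",
                "variance components with caution"),
          rhat_max, rhat_threshold)
  }

  draws <- as.matrix(sam)
  # coda names: b0[1].. -> b0_seq ..
  rename <- function(nm) {
    dom <- .DOMAIN_KEYS[as.integer(sub(".*\\[(\\d)\\]", "\\1", nm))]
    paste0(sub("\\[.*", "", nm), "_", dom)
  }
  colnames(draws) <- rename(colnames(draws))
  draws <- draws[, .HYPER_COLS, drop = FALSE]
  names(rhat) <- rename(names(rhat))

  structure(list(draws = draws, samples = sam, rhat = rhat,
                 converged = converged, identified = identified,
                 config = config),
            class = "meta_epi_fit")
}

#' @export
print.meta_epi_fit <- function(x, ...) {
  cat("Meta-epidemiological bias model fit\n")
  est <- colMeans(x$draws)
  sds <- apply(x$draws, 2, stats::sd)
  for (p in .HYPER_COLS) {
    cat(sprintf("  %-12s %7.3f (sd %.3f)\n", p, est[[p]], sds[[p]]))
  }
  cat(sprintf("  max Rhat %.3f%s\n", max(x$rhat),
              if (!x$converged) "  [convergence flag raised]" else ""))
  invisible(x)
}

as_hyper_draws <- function(posterior) {
  if (inherits(posterior, "meta_epi_fit")) return(posterior$draws)
  m <- as.matrix(posterior)
  require_columns(as.data.frame(m), .HYPER_COLS, "hyperparameter draws")
  m[, .HYPER_COLS, drop = FALSE]
}

#' Predictive distribution for total bias in a new trial
#'
#' For a trial with a given bias profile, the predictive bias is the sum of
#' its flagged domain components, each distributed `N(b0_c, phi_c^2 +
#' kappa_c^2)` given the hyperparameters; hyperparameter uncertainty is
#' integrated over the posterior draws. The returned normal summary uses the
#' exact mixture moments across draws: mean = average of the conditional
#' means, variance = variance of conditional means + average conditional
#' variance (the limit of summarizing Monte-Carlo predictive draws). A set
#' of Monte-Carlo predictive draws (one per posterior draw) is attached as
#' attribute `"draws"` for diagnostics.
#'
#' @param posterior a [fit_meta_epi()] result, or any matrix/data frame of
#'   hyperparameter draws with columns `b0_seq`, `b0_conc`, `b0_blind`,
#'   `phi_*`, `kappa_*` (a single row represents fixed parameters).
#' @param profile a [bias_profile()] or a three-character profile key; must
#'   not be all-low (`"LLL"` has no bias term).
#' @param seed seed for the attached diagnostic draws.
#' @return a [bias_dist()] with `source = "data"` and the profile key. The
#'   sd is floored at 1e-6 (with a warning) to protect downstream samplers.
#' @export
predictive_bias <- function(posterior, profile, seed = 1L) {
  draws <- as_hyper_draws(posterior)
  key <- if (inherits(profile, "bias_profile")) profile$key
         else as.character(profile)
  if (!grepl("^[LX]{3}$", key)) {
    stopf("invalid profile key '%s'", key)
  }
  if (key == "LLL") {
    stopf("no bias term for all-low trials (profile LLL)")
  }
  flags <- as.integer(strsplit(key, "")[[1]] == "X")
  b0 <- draws[, paste0("b0_", .DOMAIN_KEYS), drop = FALSE]
  v <- draws[, paste0("phi_", .DOMAIN_KEYS), drop = FALSE]^2 +
       draws[, paste0("kappa_", .DOMAIN_KEYS), drop = FALSE]^2
  cond_mean <- as.numeric(b0 %*% flags)
  cond_var <- as.numeric(v %*% flags)
  # exact mixture moments over posterior draws (population variance)
  mean_out <- mean(cond_mean)
  n <- length(cond_mean)
  var_out <- mean(cond_var) + sum((cond_mean - mean_out)^2) / n
  sd_out <- sqrt(var_out)
  if (sd_out < .PREDICTIVE_SD_FLOOR) {
    warnf("predictive bias sd is degenerate (%.2e); floored at %.0e",
          sd_out, .PREDICTIVE_SD_FLOOR)
    sd_out <- .PREDICTIVE_SD_FLOOR
  }
  out <- bias_dist(mean_out, sd_out, source = "data", profile_key = key)
  attr(out, "draws") <- with_seed(seed, {
    stats::rnorm(n, cond_mean, sqrt(cond_var))
  })
  out
}

#' Predictive bias table for all flagged profiles
#'
#' @inheritParams predictive_bias
#' @param keys profile keys to tabulate (default: all seven flagged keys).
#' @return a data frame with columns `profile_key`, `mean_logror`,
#'   `sd_logror`, suitable for [write_bias_table()].
#' @export
predictive_bias_table <- function(posterior, keys = flagged_profile_keys(),
                                  seed = 1L) {
  rows <- lapply(keys, function(k) {
    b <- predictive_bias(posterior, k, seed = seed)
    data.frame(profile_key = k, mean_logror = b$mean, sd_logror = b$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a profile-keyed bias table to CSV
#' @param table data frame with columns `profile_key`, `mean_logror`,
#'   `sd_logror` (e.g. from [predictive_bias_table()]).
#' @param path output path.
#' @export
write_bias_table <- function(table, path) {
  require_columns(table, c("profile_key", "mean_logror", "sd_logror"),
                  "bias table")
  utils::write.csv(table[, c("profile_key", "mean_logror", "sd_logror")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a profile-keyed bias table from CSV
#'
#' Reads published (or previously fitted) per-profile bias distributions, so
#' the data-based and data-informed methods can run without refitting the
#' hierarchical model.
#'
#' @param path CSV with columns `profile_key`, `mean_logror`, `sd_logror`.
#' @return a named list mapping profile key to [bias_dist()]
#'   (`source = "data"`).
#' @examples
#' # a synthetic example table shipped with the package
#' tab <- system.file("extdata", "synthetic_bias_table.csv",
#'                    package = "biasmeta")
#' map <- load_bias_table(tab)
#' map[["XXX"]]
#' @export
load_bias_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("profile_key", "mean_logror", "sd_logror"),
                  "bias table")
  if (anyDuplicated(df$profile_key)) {
    stopf("bias table: duplicate profile key(s): %s",
          paste(unique(df$profile_key[duplicated(df$profile_key)]),
                collapse = ", "))
  }
  if (any(!is.finite(df$sd_logror) | df$sd_logror <= 0)) {
    stopf("bias table: sd_logror must be positive")
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    bias_dist(df$mean_logror[i], df$sd_logror[i], source = "data",
              profile_key = df$profile_key[i])
  })
  names(out) <- df$profile_key
  out
}

#' Look up a profile key in a bias-table map
#'
#' @param map named list from [load_bias_table()].
#' @param key profile key string.
#' @return the [bias_dist()]; errors naming the key when absent.
#' @export
lookup_bias <- function(map, key) {
  b <- map[[key]]
  if (is.null(b)) stopf("bias table has no entry for profile key '%s'", key)
  b
}

#' Trial-keyed priors from a profile-keyed bias table
#'
#' Builds the method-1 prior table for a meta-analysis: each flagged trial
#' receives the data-based distribution of its bias profile.
#'
#' @param trials a `bias_trials` data frame.
#' @param map named list from [load_bias_table()] (or built from
#'   [predictive_bias_table()] output).
#' @return a `bias_priors` data frame covering the flagged trials.
#' @export
priors_from_bias_table <- function(trials, map) {
  trials <- as_bias_trials(trials)
  fl <- trials[trials$profile_key != "LLL", , drop = FALSE]
  if (nrow(fl) == 0L) stopf("no flagged trials in this meta-analysis")
  rows <- lapply(seq_len(nrow(fl)), function(i) {
    b <- lookup_bias(map, fl$profile_key[i])
    data.frame(trial_id = fl$trial_id[i], mean_logror = b$mean,
               sd_logror = b$sd, source = "data", stringsAsFactors = FALSE)
  })
  as_bias_priors(do.call(rbind, rows))
}
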