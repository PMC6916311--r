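# Inter-assessor consistency: intraclass correlation of elicited bias means.
#
# Mixed model on the means of the assessors' bias distributions:
#   mean_ij = a_j + u_i + e_ij,  u_i ~ N(0, sigma_trial^2),
#                                e_ij ~ N(0, sigma_resid^2)
# with trials i random and assessors j fixed. The ICC is the proportion of
# total variation explained by between-trial variation,
# sigma_trial^2 / (sigma_trial^2 + sigma_resid^2); confidence intervals come
# from a parametric bootstrap conditioning on the estimated fixed effects.

validate_opinion_means <- function(table) {
  require_columns(table, c("trial_id", "assessor_id", "mean"),
                  "opinion means table")
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  table$trial_id <- as.character(table$trial_id)
  table$assessor_id <- as.character(table$assessor_id)
  if (is.null(table$strategy)) table$strategy <- "a"
  key <- paste(table$trial_id, table$assessor_id, table$strategy)
  if (anyDuplicated(key)) {
    stopf("opinion means table: duplicated (trial, assessor, strategy) rows")
  }
  if (any(!is.finite(table$mean))) {
    stopf("opinion means table: non-finite means")
  }
  n_trials <- length(unique(table$trial_id))
  n_assessors <- length(unique(table$assessor_id))
  if (n_trials < 3L) stopf("need at least 3 trials for the mixed model")
  if (n_assessors < 2L) {
    stopf("unidentifiable layout: need at least 2 assessors")
  }
  per_trial <- table(table$trial_id)
  if (any(per_trial < 2L)) {
    stopf("every trial must be assessed by at least 2 assessors")
  }
  table
}

#' Fit the assessor-consistency mixed model
#'
#' Maximum-likelihood fit of a linear mixed model with fixed assessor
#' effects and random trial effects to the means of the per-assessor bias
#' distributions. Boundary estimates (variances of zero) are allowed;
#' layouts with an exactly saturated additive structure (zero residual
#' variance) are detected directly.
#'
#' @param table data frame with columns `trial_id`, `assessor_id`, `mean`
#'   (and optionally `strategy`), e.g. the output of
#'   [elicitation_normals()]. At least 3 trials, 2 assessors, and 2
#'   assessments per trial.
#' @return an object of class `mixed_fit`: list with `assessor_effects`
#'   (named fixed-effect estimates), `sigma2_trial`, `sigma2_resid`,
#'   `n_trials`, `n_assessors`, `table`, and the underlying `lme4` fit in
#'   `$model` (`NULL` for degenerate layouts).
#' @export
fit_mixed <- function(table) {
  table <- validate_opinion_means(table)
  table$.trial <- factor(table$trial_id)
  table$.assessor <- factor(table$assessor_id)

  # Saturated additive check: if assessor + trial effects reproduce the
  # means exactly, the ML residual variance is 0 and lmer cannot be used.
  lm_fit <- stats::lm(mean ~ .assessor + .trial, data = table)
  resid_ms <- mean(stats::residuals(lm_fit)^2)
  tot_var <- stats::var(table$mean)
  if (!is.finite(tot_var) || tot_var < 1e-14 || resid_ms < 1e-12) {
    # residuals vanish: trial effects are read off the additive fit
    co <- stats::coef(lm_fit)
    tl <- levels(table$.trial)
    u <- c(0, co[paste0(".trial", tl[-1])])
    u[is.na(u)] <- 0
    u <- u - mean(u)
    s2t <- mean(u^2)  # ML (boundary) estimate
    if (s2t < 1e-14) s2t <- 0
    a <- vapply(levels(table$.assessor), function(j) {
      mean(table$mean[table$.assessor == j])
    }, numeric(1))
    return(structure(list(assessor_effects = a, sigma2_trial = s2t,
                          sigma2_resid = 0,
                          n_trials = length(tl),
                          n_assessors = nlevels(table$.assessor),
                          table = table, model = NULL),
                     class = "mixed_fit"))
  }

  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(mean ~ 0 + .assessor + (1 | .trial), data = table,
               REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2t <- vc$vcov[vc$grp == ".trial"]
  s2r <- vc$vcov[vc$grp == "Residual"]
  a <- lme4::fixef(fit)
  names(a) <- sub("^\\.assessor", "", names(a))
  structure(list(assessor_effects = a, sigma2_trial = max(0, s2t),
                 sigma2_resid = max(0, s2r),
                 n_trials = nlevels(table$.trial),
                 n_assessors = nlevels(table$.assessor),
                 table = table, model = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Assessor-consistency mixed model (ML)\n")
  cat(sprintf("  trials %d, assessors %d\n", x$n_trials, x$n_assessors))
  cat(sprintf("  sigma2_trial %.4f, sigma2_resid %.4f, ICC %.3f\n",
              x$sigma2_trial, x$sigma2_resid,
              icc_from_fit(x)))
  invisible(x)
}

icc_from_fit <- function(fit) {
  tot <- fit$sigma2_trial + fit$sigma2_resid
  if (tot <= 0) return(0)
  fit$sigma2_trial / tot
}

#' Intraclass correlation with parametric-bootstrap confidence interval
#'
#' Point estimate: proportion of total variation in elicited bias means
#' explained by between-trial variation. The 95% CI is the 2.5/97.5
#' percentile interval of ICCs refitted on `n_boot` datasets simulated from
#' the fitted model (same layout, conditioning on the estimated fixed
#' assessor effects).
#'
#' @inheritParams fit_mixed
#' @param n_boot number of bootstrap replicates (at least 100).
#' @param seed integer seed; the bootstrap is reproducible bit-for-bit.
#' @return list with `icc`, `ci` (length-2 numeric), `sigma2_trial`,
#'   `sigma2_resid`, `n_boot`, and `degenerate` (`TRUE` when both variance
#'   components are zero, in which case `icc = 0` with a degenerate CI).
#' @export
icc_with_ci <- function(table, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) stopf("icc_with_ci: n_boot must be >= 100")
  fit <- fit_mixed(table)
  icc <- icc_from_fit(fit)
  if (fit$sigma2_trial + fit$sigma2_resid <= 0) {
    warnf(paste("both variance components are zero; ICC reported as 0",
                "with a degenerate interval"))
    return(list(icc = 0, ci = c(0, 0), sigma2_trial = 0, sigma2_resid = 0,
                n_boot = 0L, degenerate = TRUE))
  }

  tab <- fit$table
  a <- fit$assessor_effects[as.character(tab$.assessor)]
  trial_f <- tab$.trial
  n_tr <- fit$n_trials
  s_t <- sqrt(fit$sigma2_trial)
  s_r <- sqrt(fit$sigma2_resid)

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      u <- stats::rnorm(n_tr, 0, s_t)[as.integer(trial_f)]
      y <- as.numeric(a) + u + stats::rnorm(nrow(tab), 0, s_r)
      refit <- tryCatch({
        if (!is.null(fit$model)) {
          m <- suppressWarnings(suppressMessages(lme4::refit(fit$model, y)))
          vc <- as.data.frame(lme4::VarCorr(m))
          c(vc$vcov[vc$grp == ".trial"], vc$vcov[vc$grp == "Residual"])
        } else {
          tab2 <- tab
          tab2$mean <- y
          f <- fit_mixed(tab2)
          c(f$sigma2_trial, f$sigma2_resid)
        }
      }, error = function(e) c(NA_real_, NA_real_))
      if (any(is.na(refit)) || sum(refit) <= 0) return(NA_real_)
      max(0, refit[1]) / sum(pmax(0, refit))
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  list(icc = icc, ci = ci, sigma2_trial = fit$sigma2_trial,
       sigma2_resid = fit$sigma2_resid, n_boot = length(boots),
       degenerate = FALSE)
}
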