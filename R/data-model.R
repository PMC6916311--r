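# Domain types and tabular readers/writers.
#
# The package works on three kinds of plain-text tables:
#   * trials CSV:        one randomized trial per row (2x2 binomial counts
#                        plus risk-of-bias judgements for three domains);
#   * elicitations CSV:  one assessor opinion per row (numeric IQR on the
#                        ratio-of-odds-ratios scale, or a selected area of a
#                        reference distribution);
#   * bias tables:       normal distributions on the log ratio-of-odds-ratios
#                        (log-ROR) scale, keyed by trial or by bias profile.

.JUDGEMENTS <- c("low", "high", "unclear")
.DOMAINS <- c("seq_gen", "alloc_conc", "blinding")
.ROB_COLS <- c("rob_seq", "rob_conc", "rob_blind")
.BIAS_SOURCES <- c("data", "opinion", "fused", "area")

#' Normalize a risk-of-bias judgement string
#'
#' Accepts `low`/`high`/`unclear` in any case, or the single letters
#' `L`/`H`/`U` as used in forest-plot annotations.
#'
#' @param x character vector of judgement strings.
#' @return character vector with elements in `c("low", "high", "unclear")`.
#' @keywords internal
normalize_judgement <- function(x) {
  z <- tolower(trimws(as.character(x)))
  z[z == "l"] <- "low"
  z[z == "h"] <- "high"
  z[z == "u"] <- "unclear"
  bad <- !(z %in% .JUDGEMENTS)
  if (any(bad)) {
    stopf("unknown risk-of-bias judgement(s): %s",
          paste(unique(x[bad]), collapse = ", "))
  }
  z
}

#' Construct a bias profile
#'
#' A bias profile records the risk-of-bias judgement (low, high or unclear)
#' for the three domains: sequence generation, allocation concealment and
#' blinding. High and unclear judgements are grouped into a single
#' "flagged" indicator per domain, because trials at high risk of bias are
#' typically too sparse to model separately from unclear ones. The original
#' judgements are retained for display.
#'
#' @param seq_gen,alloc_conc,blinding judgement strings
#'   (`low`/`high`/`unclear`, or `L`/`H`/`U`).
#' @return an object of class `bias_profile` with elements `judgements`
#'   (named character), `flags` (named 0/1 integer; 1 = high-or-unclear) and
#'   `key` (three-character profile key, see [profile_key()]).
#' @examples
#' bias_profile("unclear", "low", "low")
#' @export
bias_profile <- function(seq_gen, alloc_conc, blinding) {
  j <- normalize_judgement(c(seq_gen, alloc_conc, blinding))
  if (length(j) != 3L) stopf("each domain needs exactly one judgement")
  names(j) <- .DOMAINS
  flags <- as.integer(j != "low")
  names(flags) <- .DOMAINS
  structure(
    list(judgements = j, flags = flags,
         key = key_from_flags(flags)),
    class = "bias_profile"
  )
}

key_from_flags <- function(flags) {
  paste(ifelse(flags == 1L, "X", "L"), collapse = "")
}

#' Canonical key of a bias profile
#'
#' Encodes the three high-or-unclear flags as a three-character string over
#' `{L, X}` in domain order (sequence generation, allocation concealment,
#' blinding); `X` means high-or-unclear. `"LLL"` identifies trials with no
#' bias term. The key is injective over the 8 flag combinations.
#'
#' @param profile a [bias_profile()].
#' @return a string such as `"XLL"`.
#' @examples
#' profile_key(bias_profile("unclear", "low", "low")) # "XLL"
#' @export
profile_key <- function(profile) {
  if (!inherits(profile, "bias_profile")) {
    stopf("profile_key() expects a 'bias_profile' object")
  }
  profile$key
}

#' All flagged profile keys
#'
#' The seven profile keys with at least one high-or-unclear domain, in a
#' stable order ("XLL", "LXL", ..., "XXX").
#'
#' @return character vector of length 7.
#' @export
flagged_profile_keys <- function() {
  g <- expand.grid(b = c("L", "X"), c = c("L", "X"), s = c("L", "X"),
                   stringsAsFactors = FALSE)
  keys <- paste0(g$s, g$c, g$b)
  setdiff(keys, "LLL")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat("bias profile [", x$key, "]\n", sep = "")
  for (d in .DOMAINS) {
    cat(sprintf("  %-12s %s%s\n", d, x$judgements[[d]],
                if (x$flags[[d]] == 1L) "  (flagged)" else ""))
  }
  invisible(x)
}

# ---- trials ---------------------------------------------------------------

#' Validate a data frame of trial records
#'
#' Checks the trials schema, normalizes judgement strings, and derives the
#' per-domain high-or-unclear flags and the profile key. Used by
#' [read_trials()] and by the synthetic generators.
#'
#' @param df data frame with columns `trial_id`, `meta_id`, `events_ctrl`,
#'   `n_ctrl`, `events_trt`, `n_trt`, `rob_seq`, `rob_conc`, `rob_blind`.
#' @return the validated data frame, class `bias_trials`, with added columns
#'   `flag_seq`, `flag_conc`, `flag_blind` and `profile_key`.
#' @export
as_bias_trials <- function(df) {
  req <- c("trial_id", "meta_id", "events_ctrl", "n_ctrl",
           "events_trt", "n_trt", .ROB_COLS)
  require_columns(df, req, "trials table")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$trial_id <- as.character(df$trial_id)
  df$meta_id <- as.character(df$meta_id)
  if (anyDuplicated(df$trial_id)) {
    stopf("duplicate trial_id(s): %s",
          paste(unique(df$trial_id[duplicated(df$trial_id)]), collapse = ", "))
  }
  for (col in c("events_ctrl", "n_ctrl", "events_trt", "n_trt")) {
    if (!is_count(df[[col]])) {
      stopf("trials table: column %s must hold non-negative integers", col)
    }
  }
  if (any(df$n_ctrl < 1) || any(df$n_trt < 1)) {
    bad <- df$trial_id[df$n_ctrl < 1 | df$n_trt < 1]
    stopf("trial(s) with empty arm: %s", paste(bad, collapse = ", "))
  }
  bad <- df$events_ctrl > df$n_ctrl | df$events_trt > df$n_trt
  if (any(bad)) {
    stopf("events exceed arm size for trial(s): %s",
          paste(df$trial_id[bad], collapse = ", "))
  }
  for (col in .ROB_COLS) df[[col]] <- normalize_judgement(df[[col]])
  df$flag_seq <- as.integer(df$rob_seq != "low")
  df$flag_conc <- as.integer(df$rob_conc != "low")
  df$flag_blind <- as.integer(df$rob_blind != "low")
  df$profile_key <- paste0(ifelse(df$flag_seq == 1L, "X", "L"),
                           ifelse(df$flag_conc == 1L, "X", "L"),
                           ifelse(df$flag_blind == 1L, "X", "L"))
  rownames(df) <- NULL
  class(df) <- c("bias_trials", "data.frame")
  df
}

#' Read trial records from CSV
#'
#' @param path path to a CSV file with header columns `trial_id`, `meta_id`,
#'   `events_ctrl`, `n_ctrl`, `events_trt`, `n_trt`, `rob_seq`, `rob_conc`,
#'   `rob_blind`. Judgement strings are case-insensitive
#'   (`low`/`high`/`unclear` or `L`/`H`/`U`).
#' @return a `bias_trials` data frame; see [as_bias_trials()].
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_bias_trials(df)
}

#' Write trial records to CSV
#'
#' Writes the schema columns only (derived flag columns are recomputed on
#' read), so write/read round trips reproduce the records.
#'
#' @param trials a `bias_trials` data frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  trials <- as_bias_trials(trials)
  cols <- c("trial_id", "meta_id", "events_ctrl", "n_ctrl",
            "events_trt", "n_trt", .ROB_COLS)
  utils::write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- elicitations ---------------------------------------------------------

.AREAS <- c("A", "B", "C", "D")

parse_areas <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(character(0))
  parts <- toupper(trimws(strsplit(s, "+", fixed = TRUE)[[1]]))
  if (any(!parts %in% .AREAS)) {
    stopf("unknown area label(s) in '%s' (expected subset of A,B,C,D)", s)
  }
  sort(unique(parts))
}

areas_contiguous <- function(areas) {
  pos <- sort(match(areas, .AREAS))
  length(pos) > 0L && all(diff(pos) == 1L)
}

#' Validate a data frame of elicitation records
#'
#' Each row is one assessor's opinion on one trial. Strategies `a` and `b`
#' carry a numeric interquartile range on the ratio-of-odds-ratios scale
#' (`lower_ror`, `upper_ror`); strategy `c` carries a selected area of the
#' reference distribution (`areas`, e.g. `"B+C"`): the four quartile regions
#' are labelled A (below the 25th percentile) through D (above the 75th).
#' Selected areas must be non-empty and contiguous.
#'
#' @param df data frame with columns `assessor_id`, `trial_id`, `strategy`,
#'   `lower_ror`, `upper_ror`, `areas`.
#' @return the validated data frame, class `elicitations`, with `areas`
#'   canonicalized (sorted, `+`-separated).
#' @export
as_elicitations <- function(df) {
  req <- c("assessor_id", "trial_id", "strategy",
           "lower_ror", "upper_ror", "areas")
  require_columns(df, req, "elicitations table")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$assessor_id <- as.character(df$assessor_id)
  df$trial_id <- as.character(df$trial_id)
  df$strategy <- tolower(trimws(as.character(df$strategy)))
  if (any(!df$strategy %in% c("a", "b", "c"))) {
    stopf("strategy must be one of a, b, c")
  }
  df$areas <- as.character(df$areas)
  df$lower_ror <- as.numeric(df$lower_ror)
  df$upper_ror <- as.numeric(df$upper_ror)
  for (i in seq_len(nrow(df))) {
    id <- sprintf("(assessor %s, trial %s)", df$assessor_id[i], df$trial_id[i])
    if (df$strategy[i] %in% c("a", "b")) {
      lo <- df$lower_ror[i]; up <- df$upper_ror[i]
      if (!is.finite(lo) || !is.finite(up) || lo <= 0) {
        stopf("elicitation %s: numeric IQR bounds must be positive reals", id)
      }
      if (lo >= up) {
        stopf("elicitation %s: lower_ror must be < upper_ror", id)
      }
    } else {
      areas <- parse_areas(df$areas[i])
      if (length(areas) == 0L) {
        stopf("elicitation %s: strategy c requires a non-empty area", id)
      }
      if (!areas_contiguous(areas)) {
        stopf("elicitation %s: areas '%s' are not contiguous",
              id, df$areas[i])
      }
      df$areas[i] <- paste(areas, collapse = "+")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("elicitations", "data.frame")
  df
}

#' Read elicitation records from CSV
#'
#' @param path CSV with columns `assessor_id`, `trial_id`, `strategy`,
#'   `lower_ror`, `upper_ror`, `areas` (empty unless strategy is `c`).
#' @return an `elicitations` data frame; see [as_elicitations()].
#' @export
read_elicitations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(areas = "character"))
  as_elicitations(df)
}

#' Write elicitation records to CSV
#' @param elic an `elicitations` data frame.
#' @param path output path.
#' @export
write_elicitations <- function(elic, path) {
  elic <- as_elicitations(elic)
  cols <- c("assessor_id", "trial_id", "strategy",
            "lower_ror", "upper_ror", "areas")
  utils::write.csv(as.data.frame(elic)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- bias distributions ---------------------------------------------------

#' Construct a normal bias distribution on the log-ROR scale
#'
#' The universal currency between modules: expected total bias in one trial
#' (or one bias profile) is `N(mean, sd^2)` on the log ratio-of-odds-ratios
#' scale. Negative means represent exaggeration of intervention benefit.
#'
#' @param mean mean log-ROR.
#' @param sd standard deviation (log-ROR), must be positive.
#' @param source provenance tag: `"data"` (meta-epidemiological evidence),
#'   `"opinion"` (pooled elicited IQRs), `"fused"` (statistical combination)
#'   or `"area"` (opinions elicited as areas of a reference distribution).
#' @param profile_key the bias-profile key this distribution applies to, or
#'   `"n/a"` for trial-specific distributions.
#' @return an object of class `bias_dist`.
#' @export
bias_dist <- function(mean, sd, source = "data", profile_key = "n/a") {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stopf("bias_dist: mean must be a finite number")
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stopf("bias_dist: sd must be a positive finite number")
  }
  source <- match.arg(source, .BIAS_SOURCES)
  structure(list(mean = mean, sd = sd, source = source,
                 profile_key = as.character(profile_key)),
            class = "bias_dist")
}

#' @export
print.bias_dist <- function(x, ...) {
  cat(sprintf(
    "bias distribution (log-ROR): N(%.4f, sd = %.4f)  [source: %s%s]\n",
    x$mean, x$sd, x$source,
    if (x$profile_key != "n/a") paste0(", profile ", x$profile_key) else ""))
  cat(sprintf("  median ROR %.3f, central 50%% ROR (%.3f, %.3f)\n",
              exp(x$mean), exp(x$mean - 0.6745 * x$sd),
              exp(x$mean + 0.6745 * x$sd)))
  invisible(x)
}

# ---- trial-keyed bias prior tables ---------------------------------------

#' Validate a trial-keyed bias prior table
#'
#' @param df data frame with columns `trial_id`, `mean_logror`, `sd_logror`
#'   and optionally `source`.
#' @return validated data frame, class `bias_priors`.
#' @export
as_bias_priors <- function(df) {
  require_columns(df, c("trial_id", "mean_logror", "sd_logror"),
                  "bias prior table")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$trial_id <- as.character(df$trial_id)
  if (is.null(df$source)) df$source <- "data"
  if (anyDuplicated(df$trial_id)) {
    stopf("bias prior table: duplicate trial_id(s): %s",
          paste(unique(df$trial_id[duplicated(df$trial_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$mean_logror))) {
    stopf("bias prior table: non-finite mean_logror")
  }
  if (any(!is.finite(df$sd_logror) | df$sd_logror <= 0)) {
    stopf("bias prior table: sd_logror must be positive for all trials")
  }
  class(df) <- c("bias_priors", "data.frame")
  df
}

#' Read a trial-keyed bias prior table from CSV
#' @param path CSV with columns `trial_id`, `mean_logror`, `sd_logror`,
#'   optionally `source`.
#' @return a `bias_priors` data frame.
#' @export
read_bias_priors <- function(path) {
  as_bias_priors(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a trial-keyed bias prior table to CSV
#' @param priors a `bias_priors` data frame.
#' @param path output path.
#' @export
write_bias_priors <- function(priors, path) {
  priors <- as_bias_priors(priors)
  cols <- c("trial_id", "mean_logror", "sd_logror", "source")
  utils::write.csv(as.data.frame(priors)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- MCMC configuration ---------------------------------------------------

#' MCMC configuration
#'
#' Defaults mirror the published analysis: three chains, 500,000 retained
#' iterations after a 25,000-iteration burn-in. `benefit_direction` states
#' which direction of the odds ratio represents intervention benefit; bias
#' priors are always expressed on the orientation in which negative log-ROR
#' means exaggeration of benefit, and the model flips the sign of the bias
#' term internally when benefit corresponds to OR > 1.
#'
#' @param n_chains number of chains (at least 2; convergence diagnostics
#'   need multiple chains).
#' @param n_iter retained sampling iterations per chain (after burn-in).
#' @param n_burnin burn-in iterations per chain.
#' @param seed integer seed controlling all chain RNGs and initial values.
#' @param benefit_direction `"or_lt_1"` (benefit = odds ratio below 1) or
#'   `"or_gt_1"`.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 500000L, n_burnin = 25000L,
                        seed = 1L,
                        benefit_direction = c("or_lt_1", "or_gt_1")) {
  benefit_direction <- match.arg(benefit_direction)
  n_chains <- as.integer(n_chains)
  n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin)
  if (n_chains < 2L) stopf("mcmc_config: n_chains must be >= 2")
  if (n_burnin < 0L || n_iter <= 0L) {
    stopf("mcmc_config: need n_iter > 0 and n_burnin >= 0")
  }
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 seed = as.integer(seed),
                 benefit_direction = benefit_direction),
            class = "mcmc_config")
}

# ---- posterior summaries --------------------------------------------------

#' Construct a posterior summary
#'
#' Posterior medians and central 95% credible intervals of the intervention
#' odds ratio `exp(d)` and the between-trial heterogeneity variance `tau^2`,
#' plus the largest potential-scale-reduction factor across monitored
#' parameters.
#'
#' @param or_median,or_lo,or_hi odds-ratio median and 2.5/97.5 percentiles.
#' @param tau2_median,tau2_lo,tau2_hi heterogeneity variance summaries.
#' @param rhat_max largest Gelman-Rubin statistic.
#' @return an object of class `posterior_summary`.
#' @export
posterior_summary <- function(or_median, or_lo, or_hi,
                              tau2_median, tau2_lo, tau2_hi, rhat_max) {
  vals <- c(or_median = or_median, or_lo = or_lo, or_hi = or_hi,
            tau2_median = tau2_median, tau2_lo = tau2_lo, tau2_hi = tau2_hi,
            rhat_max = rhat_max)
  if (any(!is.finite(vals))) stopf("posterior_summary: non-finite field")
  if (!(or_lo <= or_median && or_median <= or_hi)) {
    stopf("posterior_summary: need or_lo <= or_median <= or_hi")
  }
  if (!(tau2_lo <= tau2_median && tau2_median <= tau2_hi)) {
    stopf("posterior_summary: need tau2_lo <= tau2_median <= tau2_hi")
  }
  if (any(c(tau2_median, tau2_lo, tau2_hi) < 0)) {
    stopf("posterior_summary: tau2 quantities must be >= 0")
  }
  structure(as.list(vals), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("OR    %.3f (95%% CrI %.3f-%.3f)\n",
              x$or_median, x$or_lo, x$or_hi))
  cat(sprintf("tau^2 %.3f (95%% CrI %.4f-%.3f)\n",
              x$tau2_median, x$tau2_lo, x$tau2_hi))
  cat(sprintf("max Rhat %.3f\n", x$rhat_max))
  invisible(x)
}

#' Write a posterior summary to JSON
#'
#' Writes all summary fields plus run metadata (package version and, when
#' supplied, the MCMC configuration echo including the seed). The file
#' round-trips through [read_summary()].
#'
#' @param summary a [posterior_summary()].
#' @param path output path.
#' @param config optional [mcmc_config()] echoed into the metadata.
#' @export
write_summary <- function(summary, path, config = NULL) {
  if (!inherits(summary, "posterior_summary")) {
    stopf("write_summary() expects a 'posterior_summary' object")
  }
  doc <- unclass(summary)
  doc$meta <- list(package = "biasmeta",
                   version = as.character(utils::packageVersion("biasmeta")))
  if (!is.null(config)) doc$meta$config <- unclass(config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a posterior summary from JSON
#' @param path a file written by [write_summary()].
#' @return a `posterior_summary`; run metadata is attached as attribute
#'   `"meta"`.
#' @export
read_summary <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- posterior_summary(doc$or_median, doc$or_lo, doc$or_hi,
                         doc$tau2_median, doc$tau2_lo, doc$tau2_hi,
                         doc$rhat_max)
  attr(s, "meta") <- doc$meta
  s
}
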