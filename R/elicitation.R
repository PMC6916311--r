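# Processing of elicited opinions into normal bias distributions.
#
# Assessors state an interquartile range (IQR) for total bias on the
# ratio-of-odds-ratios scale, either freely (strategy a), on the axis of an
# empirical reference distribution (strategy b), or by selecting quartile
# areas of that reference distribution (strategy c). Each opinion is mapped
# to a normal distribution on the log-ROR scale and opinions are pooled
# across assessors by medians.

# Elicited bounds are snapped to a 0.02 grid on the log-ROR scale, and an
# IQR corresponds to mean +/- 0.67 sd under normality. 0.67 is the 75th
# standard-normal percentile rounded to two decimals; it is deliberately
# stored as the rounded constant, not recomputed as qnorm(0.75).
.LOG_ROR_GRID <- 0.02
.IQR_NORMAL_CONST <- 0.67

#' Round a log-ROR value to the elicitation grid
#'
#' Snaps `x` to the nearest multiple of 0.02 on the log ratio-of-odds-ratios
#' scale. Exact midpoints are resolved half-away-from-zero (a midpoint is
#' recognized with a 1e-9 tolerance in grid units to absorb floating-point
#' representation of decimals).
#'
#' @param x numeric vector of finite log-ROR values.
#' @return `x` rounded to the 0.02 grid; never further than 0.01 from `x`.
#' @examples
#' round_log_ror(-0.1985) # -0.20
#' round_log_ror(0.03)    #  0.04 (midpoint, away from zero)
#' @export
round_log_ror <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stopf("round_log_ror: input must be finite numeric")
  }
  sign(x) * floor(abs(x) / .LOG_ROR_GRID + 0.5 + 1e-9) * .LOG_ROR_GRID
}

#' Map a numeric IQR opinion to a normal distribution
#'
#' The elicited bounds (ratio-of-odds-ratios scale) are log-transformed and
#' rounded to the 0.02 grid, giving `L` and `U`; the assessor's opinion is
#' then the normal with mean `(L+U)/2` and sd `(U-L)/(2*0.67)`, i.e. the
#' normal whose interquartile range is approximately `(L, U)`.
#'
#' @param lower_ror,upper_ror elicited IQR bounds, `0 < lower < upper`.
#' @param assessor_id,trial_id identifiers carried through to the result.
#' @param strategy elicitation strategy label carried through (grouping only).
#' @return a one-row data frame (class `assessor_normals`) with columns
#'   `assessor_id`, `trial_id`, `strategy`, `mean`, `sd`.
#' @examples
#' iqr_to_normal(0.82, 1.00)  # mean -0.10, sd 0.1/0.67
#' @export
iqr_to_normal <- function(lower_ror, upper_ror, assessor_id = "",
                          trial_id = "", strategy = "a") {
  n <- length(lower_ror)
  stopifnot(length(upper_ror) == n)
  if (any(!is.finite(lower_ror) | lower_ror <= 0) ||
      any(!is.finite(upper_ror) | upper_ror <= 0)) {
    stopf("iqr_to_normal: bounds must be positive finite reals")
  }
  if (any(lower_ror >= upper_ror)) {
    stopf("iqr_to_normal: need lower_ror < upper_ror")
  }
  L <- round_log_ror(log(lower_ror))
  U <- round_log_ror(log(upper_ror))
  degenerate <- abs(U - L) < .LOG_ROR_GRID / 2
  if (any(degenerate)) {
    stopf("iqr_to_normal: zero-width opinion after 0.02-grid rounding%s",
          if (any(nzchar(trial_id))) {
            paste0(" (trial ", paste(rep_len(trial_id, n)[degenerate],
                                     collapse = ", "), ")")
          } else "")
  }
  out <- data.frame(
    assessor_id = rep_len(as.character(assessor_id), n),
    trial_id = rep_len(as.character(trial_id), n),
    strategy = rep_len(as.character(strategy), n),
    mean = (L + U) / 2,
    sd = (U - L) / (2 * .IQR_NORMAL_CONST),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assessor_normals", "data.frame")
  out
}

#' Quartiles of a selected area of a reference distribution
#'
#' A selected area of the reference normal (contiguous union of its quartile
#' regions A, B, C, D) is a truncated normal. This returns the 25% and 75%
#' quantiles of that truncated distribution on the log-ROR scale, which form
#' the IQR subsequently mapped to a normal opinion. Exact in probability
#' space: with cumulative bounds `(p_lo, p_hi)` of the selected area, the
#' quartiles are `mu + sd * qnorm(p_lo + q * (p_hi - p_lo))` for q = 0.25,
#' 0.75. Areas A and D extend to infinity (probability bounds 0 and 1), not
#' to any plotted axis limit.
#'
#' @param reference a [bias_dist()] (the data-based distribution for the
#'   trial's bias profile), or a numeric `c(mean, sd)` pair.
#' @param areas character: either a single string like `"B+C"` or a vector
#'   of labels in `A`-`D`. Must be non-empty and contiguous.
#' @return named numeric `c(lower, upper)` on the log-ROR scale.
#' @examples
#' area_to_iqr(bias_dist(0, 1), "A+B+C+D") # quartiles of N(0,1)
#' @export
area_to_iqr <- function(reference, areas) {
  if (inherits(reference, "bias_dist")) {
    mu <- reference$mean; sd <- reference$sd
  } else if (is.numeric(reference) && length(reference) == 2L) {
    mu <- reference[[1]]; sd <- reference[[2]]
    if (!is.finite(mu) || !is.finite(sd) || sd <= 0) {
      stopf("area_to_iqr: reference must have finite mean and positive sd")
    }
  } else {
    stopf("area_to_iqr: reference must be a bias_dist or c(mean, sd)")
  }
  if (length(areas) == 1L && grepl("+", areas, fixed = TRUE)) {
    areas <- parse_areas(areas)
  } else {
    areas <- toupper(as.character(areas))
    if (any(!areas %in% .AREAS)) stopf("area_to_iqr: unknown area label")
    areas <- sort(unique(areas))
  }
  if (length(areas) == 0L) stopf("area_to_iqr: empty area selection")
  if (!areas_contiguous(areas)) {
    stopf("area_to_iqr: areas %s are not contiguous",
          paste(areas, collapse = "+"))
  }
  pos <- range(match(areas, .AREAS))
  p_lo <- (pos[1] - 1L) * 0.25
  p_hi <- pos[2] * 0.25
  lower <- mu + sd * stats::qnorm(p_lo + 0.25 * (p_hi - p_lo))
  upper <- mu + sd * stats::qnorm(p_lo + 0.75 * (p_hi - p_lo))
  c(lower = lower, upper = upper)
}

#' Pool assessor opinions for one trial
#'
#' The pooled bias distribution takes the median of the assessors' means and
#' the median of their standard deviations (standard median: midpoint of the
#' central pair for even counts). Median pooling represents a "typical"
#' assessor and is robust to extreme opinions, unlike linear or logarithmic
#' opinion pools.
#'
#' @param opinions an `assessor_normals` data frame (columns `trial_id`,
#'   `mean`, `sd`), all rows for the same trial.
#' @param source source tag of the pooled distribution (`"opinion"` for
#'   numeric IQR strategies, `"area"` for area selections).
#' @return a [bias_dist()].
#' @export
pool_assessors <- function(opinions, source = "opinion") {
  if (!is.data.frame(opinions) || nrow(opinions) == 0L) {
    stopf("pool_assessors: need a non-empty table of assessor opinions")
  }
  require_columns(opinions, c("trial_id", "mean", "sd"), "assessor opinions")
  if (length(unique(opinions$trial_id)) != 1L) {
    stopf("pool_assessors: opinions mix trial_ids (%s)",
          paste(unique(opinions$trial_id), collapse = ", "))
  }
  if (any(opinions$sd <= 0)) stopf("pool_assessors: sd must be positive")
  bias_dist(stats::median(opinions$mean), stats::median(opinions$sd),
            source = source)
}

#' Convert elicitation records to per-assessor normal distributions
#'
#' Strategies `a` (plain scale) and `b` (numeric range marked on the
#' empirical distribution) are processed identically via [iqr_to_normal()];
#' the strategy label is kept only for grouping. Strategy `c` (selected
#' area) first maps the area to the IQR of the corresponding truncated
#' reference normal via [area_to_iqr()], then passes that IQR through the
#' same grid rounding and normal mapping as the numeric strategies.
#'
#' @param elic an `elicitations` data frame (see [as_elicitations()]).
#' @param reference_map named list of [bias_dist()] keyed by profile key
#'   (required when strategy `c` records are present); see
#'   [load_bias_table()].
#' @param trial_keys named character vector mapping trial_id to profile key
#'   (required with strategy `c`); typically
#'   `setNames(trials$profile_key, trials$trial_id)`.
#' @return an `assessor_normals` data frame.
#' @export
elicitation_normals <- function(elic, reference_map = NULL,
                                trial_keys = NULL) {
  elic <- as_elicitations(elic)
  rows <- vector("list", nrow(elic))
  for (i in seq_len(nrow(elic))) {
    st <- elic$strategy[i]
    if (st %in% c("a", "b")) {
      rows[[i]] <- iqr_to_normal(elic$lower_ror[i], elic$upper_ror[i],
                                 elic$assessor_id[i], elic$trial_id[i], st)
    } else {
      if (is.null(reference_map) || is.null(trial_keys)) {
        stopf("strategy c records need reference_map and trial_keys")
      }
      key <- unname(trial_keys[elic$trial_id[i]])
      if (is.na(key)) stopf("no profile key for trial %s", elic$trial_id[i])
      ref <- lookup_bias(reference_map, key)
      iqr <- area_to_iqr(ref, elic$areas[i])
      rows[[i]] <- iqr_to_normal(exp(iqr[["lower"]]), exp(iqr[["upper"]]),
                                 elic$assessor_id[i], elic$trial_id[i], st)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("assessor_normals", "data.frame")
  out
}

#' Process elicitations into a trial-keyed bias prior table
#'
#' End-to-end surface for the opinion-based methods: converts the records of
#' one elicitation strategy into assessor normals and pools them per trial.
#' Strategy `a` gives the plain opinion-based priors (method 2), `b` the
#' data-informed numeric opinions (method 4), `c` the area-selection
#' opinions (method 5).
#'
#' @inheritParams elicitation_normals
#' @param strategy which elicitation strategy to process (`"a"`, `"b"` or
#'   `"c"`).
#' @return a `bias_priors` data frame (columns `trial_id`, `mean_logror`,
#'   `sd_logror`, `source`).
#' @export
process_elicitations <- function(elic, strategy = c("a", "b", "c"),
                                 reference_map = NULL, trial_keys = NULL) {
  strategy <- match.arg(strategy)
  elic <- as_elicitations(elic)
  elic <- elic[elic$strategy == strategy, , drop = FALSE]
  if (nrow(elic) == 0L) {
    stopf("no elicitation records with strategy '%s'", strategy)
  }
  normals <- elicitation_normals(elic, reference_map, trial_keys)
  src <- if (strategy == "c") "area" else "opinion"
  pooled <- lapply(split(normals, normals$trial_id), pool_assessors,
                   source = src)
  out <- data.frame(
    trial_id = names(pooled),
    mean_logror = vapply(pooled, function(b) b$mean, numeric(1)),
    sd_logror = vapply(pooled, function(b) b$sd, numeric(1)),
    source = src,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  as_bias_priors(out)
}
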