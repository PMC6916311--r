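# Statistical combination of opinion-based and data-based bias distributions.

#' Combine an opinion-based and a data-based bias distribution
#'
#' Treats one normal distribution as the prior and the other as a single
#' normal observation; the posterior is the conjugate normal with
#' precision-weighted mean and summed precisions:
#' \deqn{w_d = 1/\sigma_d^2,\; w_o = 1/\sigma_o^2,\quad
#'   \mu = (w_d \mu_d + w_o \mu_o) / (w_d + w_o),\quad
#'   \sigma = (w_d + w_o)^{-1/2}.}
#' The form is symmetric in the two inputs, so which one plays the prior is
#' immaterial. Both sources carry equal weight; `opinion_power` scales the
#' opinion precision and is reserved for sensitivity analyses (default 1).
#'
#' @param opinion,data [bias_dist()] objects (any source tags).
#' @param opinion_power optional power on the opinion precision.
#' @return a [bias_dist()] with `source = "fused"`; its sd is always smaller
#'   than either input sd, and its mean lies between the input means.
#' @examples
#' combine_normals(bias_dist(-0.1, 0.2, "opinion"), bias_dist(-0.2, 0.1))
#' @export
combine_normals <- function(opinion, data, opinion_power = 1) {
  if (!inherits(opinion, "bias_dist") || !inherits(data, "bias_dist")) {
    stopf("combine_normals: both inputs must be 'bias_dist' objects")
  }
  if (opinion$sd <= 0 || data$sd <= 0) {
    stopf("combine_normals: standard deviations must be positive")
  }
  if (!is.numeric(opinion_power) || opinion_power <= 0) {
    stopf("combine_normals: opinion_power must be positive")
  }
  w_o <- opinion_power / opinion$sd^2
  w_d <- 1 / data$sd^2
  bias_dist((w_d * data$mean + w_o * opinion$mean) / (w_d + w_o),
            1 / sqrt(w_d + w_o),
            source = "fused",
            profile_key = data$profile_key)
}

#' Fuse two trial-keyed bias prior tables (method 3)
#'
#' Applies [combine_normals()] per trial to an opinion-based prior table and
#' a data-based prior table. Both tables must cover exactly the same trials.
#'
#' @param opinion,data `bias_priors` data frames.
#' @param opinion_power see [combine_normals()].
#' @return a `bias_priors` data frame with `source = "fused"`.
#' @export
combine_bias_tables <- function(opinion, data, opinion_power = 1) {
  opinion <- as_bias_priors(opinion)
  data <- as_bias_priors(data)
  only_o <- setdiff(opinion$trial_id, data$trial_id)
  only_d <- setdiff(data$trial_id, opinion$trial_id)
  if (length(only_o) || length(only_d)) {
    stopf("combine_bias_tables: tables cover different trials (%s)",
          paste(c(only_o, only_d), collapse = ", "))
  }
  data <- data[match(opinion$trial_id, data$trial_id), , drop = FALSE]
  fused <- mapply(function(mo, so, md, sd_) {
    b <- combine_normals(bias_dist(mo, so, "opinion"),
                         bias_dist(md, sd_, "data"),
                         opinion_power = opinion_power)
    c(b$mean, b$sd)
  }, opinion$mean_logror, opinion$sd_logror,
     data$mean_logror, data$sd_logror)
  as_bias_priors(data.frame(
    trial_id = opinion$trial_id,
    mean_logror = fused[1, ],
    sd_logror = fused[2, ],
    source = "fused",
    stringsAsFactors = FALSE
  ))
}
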