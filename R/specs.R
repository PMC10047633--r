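#' Model specification for the multivariate hurdle log-normal model
#'
#' Collects the prior hyperparameters and structural switches of the
#' behavioural model.  The fixed-effect design itself is determined by the
#' data format: a mean log-distance per treatment x context, a trial slope
#' per context, and a slope on globally standardised SVL per context.  The
#' random-effect structure is treatment-specific individual intercepts with
#' a per-treatment 3x3 cross-context correlation, plus an egg-mass intercept
#' per context.  Residual SDs are treatment-by-context constants on the log
#' scale (a distributional submodel), and the hurdle submodel has a
#' treatment-specific intercept on the logit scale for the novel and
#' predator contexts.
#'
#' @param prior_fixed_sd standard deviation of the zero-mean normal prior on
#'   fixed effects and hurdle logit intercepts (default 10, a wide prior).
#' @param prior_sd_df,prior_sd_scale degrees of freedom and scale of the
#'   half-Student-t prior on all standard-deviation parameters (defaults 3
#'   and 2.5, the conventional weakly informative choice).
#' @param lkj_eta shape of the LKJ prior on correlation matrices (default 2,
#'   mildly favouring moderate correlations).
#' @param random which random-effect blocks to include; dropping
#'   `"individual"` or `"eggmass"` fixes that block at zero (useful for
#'   degenerate test models).
#' @param fix_sigma optional 3x3 matrix of residual SDs (treatment x
#'   context) held fixed instead of sampled; `NULL` (default) samples them.
#' @param standardize_svl standardise SVL globally (z-score over all
#'   records) before it enters the linear predictor.
#' @return A list of class `"behavior_spec"`.
#' @export
behavior_spec <- function(prior_fixed_sd = 10,
                          prior_sd_df = 3,
                          prior_sd_scale = 2.5,
                          lkj_eta = 2,
                          random = c("individual", "eggmass"),
                          fix_sigma = NULL,
                          standardize_svl = TRUE) {
  stopifnot(prior_fixed_sd > 0, prior_sd_df > 0, prior_sd_scale > 0,
            lkj_eta > 0)
  if (length(random) && !all(random %in% c("individual", "eggmass")))
    stop("random must be a subset of c(\"individual\", \"eggmass\")")
  if (!is.null(fix_sigma)) {
    fix_sigma <- .tc_matrix(fix_sigma, "fix_sigma")
    if (any(fix_sigma <= 0)) stop("fix_sigma entries must be positive")
  }
  structure(list(prior_fixed_sd = prior_fixed_sd,
                 prior_sd_df = prior_sd_df,
                 prior_sd_scale = prior_sd_scale,
                 lkj_eta = lkj_eta,
                 random = random,
                 fix_sigma = fix_sigma,
                 standardize_svl = standardize_svl),
            class = "behavior_spec")
}

#' Model specification for the Gaussian random-slope body-size model
#'
#' Priors and structure for the growth model: per-treatment mean SVL at
#' trial 0, a common trial slope, per-treatment random intercepts and
#' slopes for individuals (2x2 covariance with an intercept--slope
#' correlation under an LKJ prior), an egg-mass intercept, and a Gaussian
#' residual.
#'
#' @inheritParams behavior_spec
#' @return A list of class `"bodysize_spec"`.
#' @export
bodysize_spec <- function(prior_fixed_sd = 10,
                          prior_sd_df = 3,
                          prior_sd_scale = 2.5,
                          lkj_eta = 2,
                          random = c("individual", "eggmass")) {
  stopifnot(prior_fixed_sd > 0, prior_sd_df > 0, prior_sd_scale > 0,
            lkj_eta > 0)
  if (length(random) && !all(random %in% c("individual", "eggmass")))
    stop("random must be a subset of c(\"individual\", \"eggmass\")")
  structure(list(prior_fixed_sd = prior_fixed_sd,
                 prior_sd_df = prior_sd_df,
                 prior_sd_scale = prior_sd_scale,
                 lkj_eta = lkj_eta,
                 random = random),
            class = "bodysize_spec")
}

#' Extract one body-size record per individual and trial
#'
#' SVL is measured once per trial (from the familiar-context recording) and
#' repeated across the behavioural rows of that trial; this collapses a
#' trial table to the unique (individual, trial) size records the growth
#' model is fitted to.
#'
#' @param trials a validated trial data frame.
#' @return Data frame with columns `individual_id`, `eggmass_id`,
#'   `treatment`, `trial`, `svl`.
#' @export
size_records <- function(trials) {
  trials <- validate_trials(trials)
  key <- paste(trials$individual_id, trials$trial)
  df <- trials[!duplicated(key),
               c("individual_id", "eggmass_id", "treatment", "trial", "svl")]
  rownames(df) <- NULL
  df[order(df$individual_id, df$trial), ]
}
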