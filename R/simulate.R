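# Multivariate normal draw: n x d matrix, rows iid N(0, Sigma).
.rmvn <- function(n, Sigma) {
  d <- nrow(Sigma)
  if (n == 0L) return(matrix(0, 0, d))
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(stats::rnorm(n * d), n, d) %*% rt
}

#' Simulate a behavioural experiment with known truth
#'
#' Generates a long-format trial table with the exact statistical structure
#' the models in this package assume.  For each focal individual in
#' treatment `t`, a 3-vector of among-individual deviations is drawn from a
#' zero-mean multivariate normal with variances `V_among[t, ]` and
#' correlation `Omega[[t]]`; egg-mass deviations are drawn independently per
#' context.  Body size follows the Gaussian random-slope growth model, and
#' the trial-specific SVL (globally standardised) enters the behavioural
#' linear predictor.  In the novel and predator contexts each trial records
#' distance 0 with probability `p_hurdle[t, c]` (the hurdle process,
#' independent of the continuous part); otherwise the distance is
#' log-normal around
#' `mu + beta_trial * trial + beta_svl * z(svl) + individual + egg-mass`.
#' The familiar context never records a zero.
#'
#' @param params an `"hlmm_params"` object, e.g. [default_params()].
#' @param seed integer seed; defaults to `params$seed`.  Two calls with the
#'   same parameters and seed return identical datasets.
#' @return An object of class `"hlmm_sim"`: a list with
#'   \describe{
#'     \item{trials}{data frame with columns `individual_id`, `eggmass_id`,
#'       `treatment`, `context`, `trial`, `distance`, `svl`.}
#'     \item{truth}{the parameters plus realized latent effects
#'       (`u` among-individual deviations, `w` egg-mass deviations, growth
#'       intercepts/slopes, the SVL standardisation used).}
#'   }
#' @examples
#' sim <- simulate_trials(default_params(seed = 42))
#' table(sim$trials$context, sim$trials$distance == 0)
#' @export
simulate_trials <- function(params, seed = params$seed) {
  validate_params(params)
  set.seed(seed)
  n_t <- params$n_individuals_per_treatment
  n_ind <- sum(n_t)
  K <- params$n_trials
  E <- params$n_egg_masses

  ind_id <- sprintf("ind_%03d", seq_len(n_ind))
  treat <- rep(TREATMENTS, times = n_t)
  # clutches span treatments (rotation), matching a design where focal
  # individuals from the same nests are split across treatments
  egg_of <- sprintf("em_%02d", ((seq_len(n_ind) - 1L) %% E) + 1L)
  egg_lev <- sprintf("em_%02d", seq_len(E))

  # among-individual behavioural deviations, per treatment block
  u <- matrix(0, n_ind, 3, dimnames = list(ind_id, CONTEXTS))
  for (t in 1:3) {
    sdv <- sqrt(params$V_among[t, ])
    Sigma <- diag(sdv) %*% params$Omega[[t]] %*% diag(sdv)
    u[treat == TREATMENTS[t], ] <- .rmvn(n_t[t], Sigma)
  }

  # egg-mass deviations, independent across contexts
  w <- sapply(params$V_eggmass, function(v) stats::rnorm(E, 0, sqrt(v)))
  dimnames(w) <- list(egg_lev, CONTEXTS)

  # growth model: per-individual (intercept, slope) with per-treatment
  # covariance, plus an egg-mass intercept
  g <- params$growth
  gr <- matrix(0, n_ind, 2, dimnames = list(ind_id, c("intercept", "slope")))
  for (t in 1:3) {
    s1 <- sqrt(g$V_size_intercept[t]); s2 <- sqrt(g$V_size_slope[t])
    rho <- g$size_int_slope_cor[t]
    Sg <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
    gr[treat == TREATMENTS[t], ] <- .rmvn(n_t[t], Sg)
  }
  w_size <- stats::rnorm(E, 0, sqrt(g$V_size_eggmass))

  # SVL per individual x trial (mm), one measurement per trial
  tr_idx <- rep(seq_len(n_ind), each = K)
  k <- rep.int(0:(K - 1L), n_ind)
  t_of_ind <- match(treat, TREATMENTS)
  svl <- g$size_mu[t_of_ind[tr_idx]] + g$size_trial_slope * k +
    gr[tr_idx, 1] + gr[tr_idx, 2] * k +
    w_size[match(egg_of, egg_lev)[tr_idx]] +
    stats::rnorm(n_ind * K, 0, sqrt(g$size_resid_var))
  svl <- pmax(svl, 0.1)  # SVL is a physical length
  svl_mat <- matrix(svl, n_ind, K, byrow = TRUE)

  svl_center <- mean(svl)
  svl_scale <- stats::sd(svl)
  if (!is.finite(svl_scale) || svl_scale == 0) svl_scale <- 1

  # behavioural records: individual x context x trial
  rows <- expand.grid(trial = 0:(K - 1L), context = CONTEXTS,
                      ind = seq_len(n_ind), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  i <- rows$ind
  c_idx <- match(rows$context, CONTEXTS)
  t_idx <- t_of_ind[i]
  svl_row <- svl_mat[cbind(i, rows$trial + 1L)]
  z <- (svl_row - svl_center) / svl_scale
  eta <- params$mu[cbind(t_idx, c_idx)] +
    params$beta_trial[c_idx] * rows$trial +
    params$beta_svl[c_idx] * z +
    u[cbind(i, c_idx)] +
    w[cbind(match(egg_of, egg_lev)[i], c_idx)]
  sig <- sqrt(params$sigma2_log[cbind(t_idx, c_idx)])
  dist <- exp(eta + stats::rnorm(length(eta), 0, sig))
  zero <- stats::runif(length(eta)) < params$p_hurdle[cbind(t_idx, c_idx)]
  dist[zero] <- 0

  trials <- data.frame(
    individual_id = ind_id[i],
    eggmass_id = egg_of[i],
    treatment = treat[i],
    context = rows$context,
    trial = rows$trial,
    distance = dist,
    svl = svl_row,
    stringsAsFactors = FALSE
  )
  if (params$dropout > 0) {
    keep <- stats::runif(nrow(trials)) >= params$dropout
    trials <- trials[keep, , drop = FALSE]
    rownames(trials) <- NULL
  }

  structure(list(
    trials = trials,
    truth = list(params = params, u = u, w = w, growth_effects = gr,
                 w_size = stats::setNames(w_size, egg_lev),
                 svl_center = svl_center, svl_scale = svl_scale,
                 seed = seed)
  ), class = "hlmm_sim")
}

#' @export
print.hlmm_sim <- function(x, ...) {
  cat("Simulated behavioural experiment:", nrow(x$trials), "trial records,",
      length(unique(x$trials$individual_id)), "individuals,",
      length(unique(x$trials$eggmass_id)), "egg masses\n")
  zf <- tapply(x$trials$distance == 0, x$trials$context, mean)[CONTEXTS]
  cat("  zero fraction by context:",
      paste(sprintf("%s=%.3f", CONTEXTS, zf), collapse = ", "), "\n")
  invisible(x)
}
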