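# log density of rows of X under N(0, Sigma); errors if Sigma is not PD
.dmvnorm0 <- function(X, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  d <- ncol(X)
  Z <- backsolve(ch, t(X), transpose = TRUE)
  -0.5 * colSums(Z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# zero-mean MVN log density built from SDs and a correlation matrix,
# tolerating zero SDs: degenerate dimensions must hold exact zeros (point
# mass, contributing 0 to the log density), the rest use the sub-correlation
.dmvnorm0_sdcor <- function(X, sdv, Omega) {
  zero <- sdv == 0
  ll <- 0
  if (any(zero)) {
    if (any(X[, zero, drop = FALSE] != 0)) return(-Inf)
    X <- X[, !zero, drop = FALSE]
    Omega <- Omega[!zero, !zero, drop = FALSE]
    sdv <- sdv[!zero]
  }
  if (!length(sdv)) return(0)
  Sigma <- diag(sdv, nrow = length(sdv)) %*% Omega %*%
    diag(sdv, nrow = length(sdv))
  ll + sum(.dmvnorm0(X, Sigma))
}

#' Log density of the log-normal distribution
#'
#' Standard log-normal log-density, used for positive distances in the
#' familiar context and for the positive part of the hurdle distribution.
#'
#' @param y positive observation(s).
#' @param mu,sigma mean and SD of `log(y)`; `sigma > 0`.
#' @return Log-density, vectorised over `y`.
#' @examples
#' lognormal_logpdf(1, 0, 1)  # -0.5 * log(2 * pi)
#' @export
lognormal_logpdf <- function(y, mu, sigma) {
  if (any(y <= 0)) stop("y must be positive for the log-normal density")
  if (any(sigma <= 0)) stop("sigma must be positive")
  stats::dlnorm(y, meanlog = mu, sdlog = sigma, log = TRUE)
}

#' Log density of the hurdle log-normal distribution
#'
#' Two-part mixture for non-negative responses with exact zeros: an
#' observation is zero with probability `p` (the individual never left the
#' acclimation zone) and otherwise log-normal with parameters `(mu, sigma)`.
#' The density integrates to one over `[0, Inf)`: mass `p` at zero plus
#' `(1 - p)` times the log-normal density on the positive half-line.
#'
#' @param y non-negative observation(s).
#' @param p zero probability in `[0, 1]`.
#' @param mu,sigma log-scale location and SD of the positive part.
#' @return Log-density, vectorised over `y`.
#' @examples
#' hurdle_lognormal_logpdf(0, 0.5, 0, 1)  # log(0.5)
#' @export
hurdle_lognormal_logpdf <- function(y, p, mu, sigma) {
  if (any(y < 0)) stop("y must be non-negative for the hurdle density")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(sigma <= 0)) stop("sigma must be positive")
  n <- length(y)
  p <- rep_len(p, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  z <- y == 0
  out[z] <- log(p[z])
  out[!z] <- log1p(-p[!z]) +
    stats::dlnorm(y[!z], mu[!z], sigma[!z], log = TRUE)
  out
}

# shared bookkeeping: per-row treatment/context indices and standardised SVL
.row_design <- function(trials, svl_center = NULL, svl_scale = NULL,
                        standardize_svl = TRUE) {
  t_idx <- match(trials$treatment, TREATMENTS)
  c_idx <- match(trials$context, CONTEXTS)
  if (standardize_svl) {
    if (is.null(svl_center)) svl_center <- mean(trials$svl)
    if (is.null(svl_scale)) {
      svl_scale <- stats::sd(trials$svl)
      if (!is.finite(svl_scale) || svl_scale == 0) svl_scale <- 1
    }
    z <- (trials$svl - svl_center) / svl_scale
  } else {
    svl_center <- 0; svl_scale <- 1; z <- trials$svl
  }
  list(t_idx = t_idx, c_idx = c_idx, z = z,
       svl_center = svl_center, svl_scale = svl_scale)
}

#' Linear predictor of the behavioural model
#'
#' For each record, `mu[t, c] + beta_trial[c] * trial + beta_svl[c] * z(svl)
#' + u[individual, c] + w[eggmass, c]`, where `z()` is the global SVL
#' standardisation.
#'
#' @param trials a validated trial data frame.
#' @param pars parameter list with elements `mu` (3x3 treatment x context),
#'   `beta_trial`, `beta_svl` (length 3 by context), `u` (individuals x 3
#'   matrix of among-individual deviations, rownames = `individual_id`) and
#'   `w` (egg masses x 3, rownames = `eggmass_id`).  `u`/`w` may be omitted
#'   for a population-level predictor.
#' @param svl_center,svl_scale optional standardisation constants; defaults
#'   recompute them from `trials`.
#' @return Numeric vector of linear predictors (log scale), one per row.
#' @export
linear_predictor <- function(trials, pars, svl_center = NULL,
                             svl_scale = NULL) {
  trials <- validate_trials(trials)
  d <- .row_design(trials, svl_center, svl_scale)
  eta <- pars$mu[cbind(d$t_idx, d$c_idx)] +
    pars$beta_trial[d$c_idx] * trials$trial +
    pars$beta_svl[d$c_idx] * d$z
  if (!is.null(pars$u)) {
    i <- match(trials$individual_id, rownames(pars$u))
    if (anyNA(i)) stop("unknown individual_id in trials: ",
                       trials$individual_id[which(is.na(i))[1]])
    eta <- eta + pars$u[cbind(i, d$c_idx)]
  }
  if (!is.null(pars$w)) {
    e <- match(trials$eggmass_id, rownames(pars$w))
    if (anyNA(e)) stop("unknown eggmass_id in trials: ",
                       trials$eggmass_id[which(is.na(e))[1]])
    eta <- eta + pars$w[cbind(e, d$c_idx)]
  }
  eta
}

#' Joint log-likelihood of the multivariate hurdle log-normal model
#'
#' Sum over records of the context-appropriate log density -- log-normal in
#' the familiar context, hurdle log-normal with treatment-specific zero
#' probability in the novel and predator contexts -- plus the log densities
#' of the latent effects: each individual's 3-vector of deviations under
#' its treatment's among-individual covariance (built from `sd_among` and
#' `Omega`), and each egg-mass deviation under its context's variance.
#' Zeros contribute only the hurdle mass (standard hurdle factorisation);
#' they carry no information about the continuous part or the latent
#' effects.
#'
#' @param trials a validated trial data frame.
#' @param pars parameter list: the [linear_predictor()] elements plus
#'   `sd_among` (3x3 treatment x context SDs), `Omega` (list of 3
#'   correlation matrices), `V_eggmass` (length 3), `sigma` (3x3 residual
#'   SDs on the log scale) and `p_hurdle` (3x3 zero probabilities, familiar
#'   column 0).
#' @param svl_center,svl_scale optional SVL standardisation constants.
#' @return A finite scalar log-likelihood (or an error for invalid input).
#' @export
joint_loglik <- function(trials, pars, svl_center = NULL, svl_scale = NULL) {
  trials <- validate_trials(trials)
  d <- .row_design(trials, svl_center, svl_scale)
  ll <- 0
  if (nrow(trials)) {
    eta <- linear_predictor(trials, pars, d$svl_center, d$svl_scale)
    sig <- pars$sigma[cbind(d$t_idx, d$c_idx)]
    p <- pars$p_hurdle[cbind(d$t_idx, d$c_idx)]
    fam <- d$c_idx == 1L
    if (any(fam))
      ll <- ll + sum(lognormal_logpdf(trials$distance[fam], eta[fam],
                                      sig[fam]))
    if (any(!fam))
      ll <- ll + sum(hurdle_lognormal_logpdf(trials$distance[!fam], p[!fam],
                                             eta[!fam], sig[!fam]))
  }
  # latent-effect terms
  if (!is.null(pars$u) && nrow(pars$u)) {
    ind <- unique(trials[, c("individual_id", "treatment")])
    t_of <- match(ind$treatment, TREATMENTS)[match(rownames(pars$u),
                                                   ind$individual_id)]
    for (t in 1:3) {
      rows <- which(t_of == t)
      if (!length(rows)) next
      ll <- ll + .dmvnorm0_sdcor(pars$u[rows, , drop = FALSE],
                                 pars$sd_among[t, ], pars$Omega[[t]])
    }
  }
  if (!is.null(pars$w) && nrow(pars$w)) {
    for (c in 1:3) {
      if (pars$V_eggmass[c] == 0) {
        if (any(pars$w[, c] != 0)) ll <- -Inf
      } else {
        ll <- ll + sum(stats::dnorm(pars$w[, c], 0, sqrt(pars$V_eggmass[c]),
                                    log = TRUE))
      }
    }
  }
  ll
}

#' Log-likelihood of the Gaussian random-slope body-size model
#'
#' `svl = alpha[t] + beta_trial * trial + g0[i] + g1[i] * trial + w[e] +
#' residual`, with per-treatment 2x2 covariance of the individual
#' (intercept, slope) pair, an egg-mass intercept variance, and Gaussian
#' residual variance `sigma2`.  Latent effects contribute their own log
#' densities, as in [joint_loglik()].
#'
#' @param size a data frame from [size_records()].
#' @param pars list with `alpha` (length 3), `beta_trial` (scalar), `g`
#'   (individuals x 2 matrix, rownames = `individual_id`), `w` (named
#'   vector by `eggmass_id`), `sd_intercept`, `sd_slope`,
#'   `cor_int_slope` (length 3, per treatment), `V_eggmass` (scalar) and
#'   `sigma2` (residual variance).
#' @return Scalar log-likelihood.
#' @export
bodysize_loglik <- function(size, pars) {
  t_idx <- match(size$treatment, TREATMENTS)
  if (anyNA(t_idx)) stop("unknown treatment label in size records")
  eta <- pars$alpha[t_idx] + pars$beta_trial * size$trial
  if (!is.null(pars$g)) {
    i <- match(size$individual_id, rownames(pars$g))
    if (anyNA(i)) stop("unknown individual_id in size records")
    eta <- eta + pars$g[i, 1] + pars$g[i, 2] * size$trial
  }
  if (!is.null(pars$w)) {
    e <- match(size$eggmass_id, names(pars$w))
    if (anyNA(e)) stop("unknown eggmass_id in size records")
    eta <- eta + pars$w[e]
  }
  ll <- sum(stats::dnorm(size$svl, eta, sqrt(pars$sigma2), log = TRUE))
  if (!is.null(pars$g) && nrow(pars$g)) {
    ind <- unique(size[, c("individual_id", "treatment")])
    t_of <- match(ind$treatment, TREATMENTS)[match(rownames(pars$g),
                                                   ind$individual_id)]
    for (t in 1:3) {
      rows <- which(t_of == t)
      if (!length(rows)) next
      rho <- pars$cor_int_slope[t]
      Omega2 <- matrix(c(1, rho, rho, 1), 2, 2)
      ll <- ll + .dmvnorm0_sdcor(pars$g[rows, , drop = FALSE],
                                 c(pars$sd_intercept[t], pars$sd_slope[t]),
                                 Omega2)
    }
  }
  if (!is.null(pars$w) && length(pars$w))
    ll <- ll + sum(stats::dnorm(pars$w, 0, sqrt(pars$V_eggmass), log = TRUE))
  ll
}
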