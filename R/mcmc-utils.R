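#' MCMC settings
#'
#' Sampler settings for [fit_behavior()] and [fit_bodysize()].  The default
#' is the report-scale configuration: four chains of 8500 iterations with a
#' burn-in of 1000 and a thinning interval of 100, retaining
#' `4 * floor((8500 - 1000) / 100) = 300` draws.  [mcmc_control_test()] is a
#' desk-scale configuration for quick runs and continuous testing.
#'
#' @param chains number of chains (>= 1; >= 2 needed for R-hat).
#' @param iter total iterations per chain.
#' @param burnin burn-in iterations discarded per chain (`< iter`).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed; chain streams are derived from it, so a fit is
#'   reproducible given the seed.
#' @param adapt adapt random-walk proposal scales during burn-in (frozen
#'   afterwards, preserving detailed balance of the retained draws).
#' @return A list of class `"mcmc_control"`.
#' @examples
#' n_retained(mcmc_control())  # 300
#' @export
mcmc_control <- function(chains = 4L, iter = 8500L, burnin = 1000L,
                         thin = 100L, seed = 1L, adapt = TRUE) {
  chains <- as.integer(chains); iter <- as.integer(iter)
  burnin <- as.integer(burnin); thin <- as.integer(thin)
  if (chains < 1L) stop("chains must be >= 1")
  if (burnin >= iter) stop("burnin must be smaller than iter")
  if (thin < 1L) stop("thin must be >= 1")
  if (floor((iter - burnin) / thin) < 1L)
    stop("settings retain no draws; decrease thin or increase iter")
  structure(list(chains = chains, iter = iter, burnin = burnin, thin = thin,
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "mcmc_control")
}

#' @rdname mcmc_control
#' @export
mcmc_control_test <- function(chains = 2L, iter = 500L, burnin = 100L,
                              thin = 2L, seed = 1L, adapt = TRUE) {
  mcmc_control(chains, iter, burnin, thin, seed, adapt)
}

#' @rdname mcmc_control
#' @param control an `"mcmc_control"` object.
#' @export
n_retained <- function(control) {
  control$chains * (floor((control$iter - control$burnin) / control$thin))
}

# inverse-gamma draw (shape/rate parameterisation)
.rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)

# half-Student-t log density (location 0, scale A, df nu), x > 0
.dhalft <- function(x, nu, A, log = TRUE) {
  out <- log(2) + stats::dt(x / A, df = nu, log = TRUE) - log(A)
  if (log) out else exp(out)
}

.rhalft <- function(n, nu, A) abs(A * stats::rt(n, df = nu))

# exact draw from the LKJ(eta) distribution over 3x3 correlation matrices,
# via the C-vine construction (partial correlations are shifted Betas);
# returns c(r12, r13, r23)
.rlkj3 <- function(eta) {
  b1 <- eta + 0.5
  r12 <- 2 * stats::rbeta(1, b1, b1) - 1
  r13 <- 2 * stats::rbeta(1, b1, b1) - 1
  p23 <- 2 * stats::rbeta(1, eta, eta) - 1
  r23 <- p23 * sqrt((1 - r12^2) * (1 - r13^2)) + r12 * r13
  c(r12, r13, r23)
}

# single correlation under LKJ(eta) for a 2x2 matrix
.rlkj2 <- function(eta) 2 * stats::rbeta(1, eta, eta) - 1

# lower-triangular factor A with A A' = diag(exp(lam)) Omega diag(exp(lam))
# for a 3x3 (or 2x2) correlation given by off-diagonal entries r;
# NULL when Omega is not positive definite
.lt_factor <- function(lam, r) {
  d <- length(lam)
  Om <- diag(d)
  if (d == 3L) {
    Om[rbind(c(1, 2), c(1, 3), c(2, 3))] <- r
    Om[rbind(c(2, 1), c(3, 1), c(3, 2))] <- r
  } else {
    Om[1, 2] <- Om[2, 1] <- r
  }
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  diag(exp(lam), d) %*% t(ch)
}

# Gibbs update for a variance with a half-t(nu, A) prior on its SD, using
# the inverse-gamma scale-mixture representation:
#   sigma2 | a ~ IG(nu/2, nu/a),  a ~ IG(1/2, 1/A^2)
# Conditionals given n residuals with sum of squares SS are both IG.
.update_variance_halft <- function(sigma2, a, n, SS, nu, A) {
  sigma2 <- .rinvgamma(1, (nu + n) / 2, nu / a + SS / 2)
  a <- .rinvgamma(1, (nu + 1) / 2, nu / sigma2 + 1 / A^2)
  c(sigma2 = sigma2, a = a)
}

# one scalar random-walk Metropolis step; lp must return -Inf/NULL-safe
# log posterior. Returns list(x, lp, accepted).
.mh_step <- function(x, lp_x, lp_fun, scale) {
  prop <- x + stats::rnorm(1, 0, scale)
  lp_p <- lp_fun(prop)
  if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp_x)
    list(x = prop, lp = lp_p, accepted = TRUE)
  else list(x = x, lp = lp_x, accepted = FALSE)
}

# Robbins-Monro scale adaptation toward 44% acceptance (scalar proposals)
.adapt_scale <- function(scale, accepted, it) {
  gain <- min(0.25, 1 / sqrt(it))
  scale * exp(gain * ((if (accepted) 1 else 0) - 0.44))
}

# derive one RNG seed per chain from the master seed
.chain_seeds <- function(seed, chains) {
  set.seed(seed)
  sample.int(2147483646L, chains)
}
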