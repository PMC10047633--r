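#' Convert posterior SD draws to variance draws
#'
#' Group-effect posteriors are parameterised as standard deviations; this
#' squares them element-wise to the variance scale used by repeatability.
#'
#' @param sd_draws non-negative numeric vector (or array) of SD draws.
#' @return Element-wise squares, same shape.
#' @export
sd_to_variance <- function(sd_draws) {
  if (any(sd_draws < 0)) stop("sd draws must be non-negative")
  sd_draws^2
}

#' Within-individual variance on the natural scale
#'
#' The residual variance of a (hurdle) log-normal model lives on the log
#' scale; the reporting convention implemented here takes its exponential
#' as the natural-scale within-individual variance, so that among- and
#' within-individual components share a scale for repeatability.  Setting
#' `complete = TRUE` instead applies the full log-normal variance transform
#' `(exp(s2) - 1) * exp(2 * mu + s2)`, which additionally needs the
#' log-scale mean `mu`; it is off by default because the simple
#' exponential is the convention the reported tables use.
#'
#' @param resid_var_draws residual variance draws on the log scale
#'   (non-negative).
#' @param complete use the complete log-normal data-scale variance.
#' @param mu log-scale mean draws, required when `complete = TRUE`.
#' @return Natural-scale within-individual variance draws.
#' @examples
#' within_variance_natural(0)          # 1
#' within_variance_natural(log(2.796)) # 2.796
#' @export
within_variance_natural <- function(resid_var_draws, complete = FALSE,
                                    mu = NULL) {
  if (any(resid_var_draws < 0)) stop("residual variance must be non-negative")
  if (!complete) return(exp(resid_var_draws))
  if (is.null(mu)) stop("mu draws are required when complete = TRUE")
  (exp(resid_var_draws) - 1) * exp(2 * mu + resid_var_draws)
}

#' Repeatability from variance draws
#'
#' Per-draw ratio `R = V_among / (V_among + V_within)`, the proportion of
#' phenotypic variance attributable to differences among individuals.
#' Computed draw-wise and then summarised, so the posterior mean of `R` is
#' the mean of ratios (not the ratio of means; the two differ by a small
#' Jensen gap).  Draws where both components are zero are excluded, with
#' the count reported in the `"n_excluded"` attribute.
#'
#' @param V_among,V_within equal-length non-negative draw vectors.
#' @return Vector of repeatability draws in `[0, 1]` with attribute
#'   `n_excluded`.
#' @examples
#' repeatability(0.175, 1.770)  # about 0.090
#' @export
repeatability <- function(V_among, V_within) {
  if (length(V_among) != length(V_within))
    stop("V_among and V_within must have equal length")
  if (any(V_among < 0) || any(V_within < 0))
    stop("variance draws must be non-negative")
  both0 <- V_among == 0 & V_within == 0
  R <- (V_among / (V_among + V_within))[!both0]
  attr(R, "n_excluded") <- sum(both0)
  R
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws -- the narrowest interval with at least the requested
#' posterior mass, assuming a unimodal posterior.
#'
#' @param draws numeric vector of at least 20 draws.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(1:100)  # width 94
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  n <- length(draws)
  if (n < 20L) stop("hpdi needs at least 20 draws")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  j <- which.min(widths)
  c(lower = x[j], upper = x[j + m - 1L])
}

# equal-tail (central) interval, for the quantile reporting option
.eti <- function(draws, mass = 0.95) {
  q <- stats::quantile(draws, c((1 - mass) / 2, 1 - (1 - mass) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

.interval <- function(draws, mass = 0.95, type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  if (type == "hpdi") hpdi(draws, mass) else .eti(draws, mass)
}

#' Posterior treatment contrast
#'
#' Per-draw difference of a quantity between two treatments, summarised by
#' the posterior mean and a 95% HPDI.  Both the signed difference
#' (direction) and the absolute difference (magnitude, mirroring the
#' reporting convention of the contrast tables) are returned.
#'
#' @param draws_by_treatment named list (or matrix with named columns) of
#'   aligned draw vectors, names among `TREATMENTS`.
#' @param pair character vector of 2 treatment names: the contrast is
#'   `pair[1] - pair[2]`.
#' @param mass interval mass.
#' @param type interval type, `"hpdi"` (default) or `"quantile"`.
#' @return Object of class `"contrast_result"`: list with `pair`, draw
#'   vectors `signed` and `absolute`, and their `mean` and interval
#'   summaries.
#' @export
treatment_contrast <- function(draws_by_treatment, pair, mass = 0.95,
                               type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  if (is.matrix(draws_by_treatment))
    draws_by_treatment <- as.list(as.data.frame(draws_by_treatment))
  if (!all(pair %in% names(draws_by_treatment)))
    stop("pair must name two elements of draws_by_treatment")
  a <- draws_by_treatment[[pair[1]]]
  b <- draws_by_treatment[[pair[2]]]
  if (length(a) != length(b)) stop("draw vectors must have equal length")
  d <- a - b
  structure(list(
    pair = paste(pair[1], "-", pair[2]),
    signed = d, absolute = abs(d),
    signed_mean = mean(d), signed_interval = .interval(d, mass, type),
    absolute_mean = mean(abs(d)),
    absolute_interval = .interval(abs(d), mass, type)
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Contrast", x$pair, "\n")
  cat(sprintf("  signed:   %.3f [%.3f, %.3f]\n", x$signed_mean,
              x$signed_interval[1], x$signed_interval[2]))
  cat(sprintf("  absolute: %.3f [%.3f, %.3f]\n", x$absolute_mean,
              x$absolute_interval[1], x$absolute_interval[2]))
  invisible(x)
}

#' Convert hurdle logit draws to probabilities
#'
#' Inverse-logit transform of hurdle-intercept draws, giving the posterior
#' probability that a trial records distance zero (the individual never
#' left the acclimation zone).
#'
#' @param logit_draws numeric draws on the logit scale.
#' @return Probability draws in (0, 1).
#' @examples
#' logit_to_probability(0)  # 0.5
#' @export
logit_to_probability <- function(logit_draws) stats::plogis(logit_draws)

#' Convert covariance matrices to correlation matrices
#'
#' `D^{-1/2} Sigma D^{-1/2}` with `D = diag(Sigma)`, applied to a single
#' matrix or to an array of draws (draw index last).  A zero diagonal
#' element leaves the affected correlations undefined (`NA`), flagged via
#' a warning.
#'
#' @param Sigma a `d x d` covariance matrix, or a `d x d x n` array of
#'   draws.
#' @return Correlation matrix (or array) with unit diagonal.
#' @export
cov_to_corr <- function(Sigma) {
  one <- function(S) {
    v <- diag(S)
    if (any(v == 0)) {
      warning("zero variance on the diagonal: correlations undefined")
      s <- sqrt(ifelse(v > 0, v, NA_real_))
    } else s <- sqrt(v)
    R <- S / tcrossprod(s)
    diag(R) <- ifelse(v > 0, 1, NA_real_)
    R
  }
  if (is.matrix(Sigma)) return(one(Sigma))
  if (length(dim(Sigma)) == 3L) {
    out <- Sigma
    for (i in seq_len(dim(Sigma)[3])) out[, , i] <- one(Sigma[, , i])
    return(out)
  }
  stop("Sigma must be a matrix or a 3-d array of matrices")
}
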