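# split each chain of a chains x draws matrix into halves
.split_chains <- function(mat) {
  n <- ncol(mat)
  half <- floor(n / 2)
  if (half < 1L) return(mat)
  rbind(mat[, seq_len(half), drop = FALSE],
        mat[, (n - half + 1L):n, drop = FALSE])
}

#' Split R-hat for one parameter
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, and the usual between/within variance ratio is taken over the
#' resulting sequences, so within-chain trends inflate the statistic.
#' Returns `NA` when the chains carry no variance (e.g. a parameter held
#' fixed), where the statistic is undefined.
#'
#' @param mat numeric matrix, `chains x draws`, at least 2 chains.
#' @return Scalar R-hat (>= 1 up to Monte-Carlo noise), or `NA`.
#' @export
rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("R-hat needs at least 2 chains")
  sp <- .split_chains(mat)
  m <- nrow(sp); n <- ncol(sp)
  if (n < 2L) return(NA_real_)
  means <- rowMeans(sp)
  vars <- apply(sp, 1L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size for one parameter
#'
#' Split-chain effective sample size: per-sequence autocovariances are
#' combined with the between-sequence variance, summed with Geyer's initial
#' monotone positive-pair truncation, and inverted to an ESS.  Capped at
#' the total number of draws.
#'
#' @param mat numeric matrix, `chains x draws`.
#' @return Scalar ESS, or `NA` for degenerate (zero-variance) input.
#' @export
ess <- function(mat) {
  mat <- as.matrix(mat)
  sp <- .split_chains(mat)
  m <- nrow(sp); n <- ncol(sp)
  if (n < 4L) return(NA_real_)
  vars <- apply(sp, 1L, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(rowMeans(sp))
  var_plus <- (n - 1) / n * W + B / n
  acov <- sapply(seq_len(m), function(k)
    stats::acf(sp[k, ], lag.max = n - 1L, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  mean_acov <- rowMeans(acov)  # lag 0 .. n-1
  rho <- c(1, 1 - (W - mean_acov[-1L]) / var_plus)
  # Geyer initial monotone positive sequence on paired autocorrelation sums
  s <- 0; prev <- Inf
  for (t in seq_len(floor(length(rho) / 2))) {
    p <- rho[2 * t - 1] + rho[2 * t]
    if (!is.finite(p) || p < 0) break
    p <- min(p, prev)
    s <- s + p
    prev <- p
  }
  tau <- max(-1 + 2 * s, 1 / (m * n))
  min(m * n / tau, m * n)
}

.diagnostics_array <- function(draws) {
  nm <- dimnames(draws)[[3]]
  nchain <- dim(draws)[1]
  out <- data.frame(parameter = nm,
                    mean = NA_real_, sd = NA_real_,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(nm)) {
    mat <- draws[, , j, drop = FALSE]
    dim(mat) <- dim(draws)[1:2]
    x <- as.vector(mat)
    out$mean[j] <- mean(x)
    out$sd[j] <- stats::sd(x)
    if (nchain >= 2L) out$rhat[j] <- rhat(mat)
    out$ess[j] <- ess(mat)
  }
  out
}

#' Convergence diagnostics of a fitted model
#'
#' Split R-hat and effective sample size for every retained parameter of a
#' [fit_behavior()] or [fit_bodysize()] result, with posterior means and
#' SDs.  With a single chain R-hat is unavailable and reported as `NA`.
#'
#' @param fit a `"behavior_fit"` or `"bodysize_fit"`.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `rhat`,
#'   `ess`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, c("behavior_fit", "bodysize_fit")))
  fit$diagnostics
}
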