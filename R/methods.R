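#' @export
print.behavior_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("Multivariate hurdle log-normal mixed model fit\n")
  cat("  individuals:", nrow(x$ind_tab), " egg masses:",
      length(x$egg_lev), " records:", nrow(x$trials), "\n")
  cat("  chains:", d[1], " retained draws:", d[1] * d[2],
      sprintf(" (%d per chain)\n", d[2]))
  if (isTRUE(x$convergence_flag))
    cat("  WARNING: split R-hat exceeds 1.05 for some parameters --",
        "inspect diagnostics(fit)\n")
  else cat("  convergence: all split R-hat <= 1.05\n")
  invisible(x)
}

#' @export
print.bodysize_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("Gaussian random-slope body-size model fit\n")
  cat("  individuals:", nrow(x$ind_tab), " size records:", nrow(x$size), "\n")
  cat("  chains:", d[1], " retained draws:", d[1] * d[2], "\n")
  if (isTRUE(x$convergence_flag))
    cat("  WARNING: split R-hat exceeds 1.05 for some parameters --",
        "inspect diagnostics(fit)\n")
  invisible(x)
}

#' Summarise a fitted model
#'
#' Posterior mean, SD, 95% HPDI, split R-hat and ESS for every retained
#' parameter.
#'
#' @param object a fitted model.
#' @param mass interval mass.
#' @param type interval type.
#' @param ... unused.
#' @return A data frame of class `"summary.behavior_fit"` (printed
#'   compactly).
#' @export
summary.behavior_fit <- function(object, mass = 0.95,
                                 type = c("hpdi", "quantile"), ...) {
  type <- match.arg(type)
  m <- .dm(object)
  ints <- t(apply(m, 2, .interval, mass = mass, type = type))
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m), sd = apply(m, 2, stats::sd),
                    lower = ints[, 1], upper = ints[, 2],
                    rhat = object$diagnostics$rhat,
                    ess = object$diagnostics$ess)
  rownames(out) <- NULL
  attr(out, "convergence_flag") <- object$convergence_flag
  class(out) <- c("summary.behavior_fit", "data.frame")
  out
}

#' @rdname summary.behavior_fit
#' @export
summary.bodysize_fit <- summary.behavior_fit

#' @export
print.summary.behavior_fit <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  y[, -1] <- round(y[, -1], digits)
  print(y, row.names = FALSE)
  if (isTRUE(attr(x, "convergence_flag")))
    cat("WARNING: split R-hat exceeds 1.05 for some parameters\n")
  invisible(x)
}

#' @export
coef.behavior_fit <- function(object, ...) {
  m <- .dm(object)
  fixed <- grep("^(mu|beta_trial|beta_svl)\\[", colnames(m), value = TRUE)
  colMeans(m[, fixed, drop = FALSE])
}

#' @export
coef.bodysize_fit <- function(object, ...) {
  m <- .dm(object)
  colMeans(m[, c(sprintf("alpha[%s]", TREATMENTS), "beta_trial"),
             drop = FALSE])
}

#' Traceplots of posterior draws
#'
#' One panel per selected parameter, chains overlaid.
#'
#' @param x a fitted model.
#' @param pars parameter names (default: the first 6).
#' @param ... passed to [graphics::matplot()].
#' @return The fit, invisibly.
#' @export
plot.behavior_fit <- function(x, pars = NULL, ...) {
  nm <- dimnames(x$draws)[[3]]
  if (is.null(pars)) pars <- nm[seq_len(min(6L, length(nm)))]
  pars <- intersect(pars, nm)
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), min(2, length(pars))),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    mat <- t(x$draws[, , p])
    graphics::matplot(mat, type = "l", lty = 1, main = p,
                      xlab = "draw", ylab = "", ...)
  }
  invisible(x)
}

#' @rdname plot.behavior_fit
#' @export
plot.bodysize_fit <- plot.behavior_fit

#' @export
fitted.behavior_fit <- function(object, ...) {
  m <- .dm(object)
  pars <- list(
    mu = matrix(colMeans(m[, 1:9, drop = FALSE]), 3, 3, byrow = TRUE,
                dimnames = list(TREATMENTS, CONTEXTS)),
    beta_trial = colMeans(m[, sprintf("beta_trial[%s]", CONTEXTS)]),
    beta_svl = colMeans(m[, sprintf("beta_svl[%s]", CONTEXTS)]),
    u = object$u_mean, w = object$w_mean
  )
  linear_predictor(object$trials, pars, object$svl_center, object$svl_scale)
}

#' @export
residuals.behavior_fit <- function(object, ...) {
  eta <- fitted(object)
  y <- object$trials$distance
  out <- rep(NA_real_, length(y))
  out[y > 0] <- log(y[y > 0]) - eta[y > 0]
  out
}

#' @export
fitted.bodysize_fit <- function(object, ...) {
  m <- .dm(object)
  alpha <- colMeans(m[, sprintf("alpha[%s]", TREATMENTS), drop = FALSE])
  bt <- mean(m[, "beta_trial"])
  s <- object$size
  i <- match(s$individual_id, rownames(object$g_mean))
  e <- match(s$eggmass_id, names(object$w_mean))
  alpha[match(s$treatment, TREATMENTS)] + bt * s$trial +
    object$g_mean[i, 1] + object$g_mean[i, 2] * s$trial +
    object$w_mean[e]
}

#' @export
residuals.bodysize_fit <- function(object, ...) {
  object$size$svl - fitted(object)
}
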