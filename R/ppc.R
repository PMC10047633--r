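# simulate one replicate dataset conditional on the observed design
# (rows, treatments, contexts, trials, standardised SVL) with fresh latent
# effects drawn from one posterior draw's hyperparameters
.pp_replicate <- function(fit, pars) {
  tr <- fit$trials
  d <- .row_design(tr, fit$svl_center, fit$svl_scale,
                   fit$spec$standardize_svl)
  ind_tab <- fit$ind_tab
  n_ind <- nrow(ind_tab)
  t_of_ind <- match(ind_tab$treatment, TREATMENTS)
  egg_lev <- fit$egg_lev
  pair_lab <- c("familiar,novel", "familiar,predator", "novel,predator")

  u <- matrix(0, n_ind, 3)
  for (t in 1:3) {
    ids <- which(t_of_ind == t)
    if (!length(ids)) next
    tn <- TREATMENTS[t]
    sdv <- sapply(CONTEXTS, function(c) pars[sprintf("sd_among[%s,%s]", tn, c)])
    rr <- sapply(pair_lab, function(p) pars[sprintf("cor[%s,%s]", tn, p)])
    Om <- matrix(c(1, rr[1], rr[2], rr[1], 1, rr[3], rr[2], rr[3], 1), 3, 3)
    u[ids, ] <- .rmvn(length(ids), diag(sdv) %*% Om %*% diag(sdv))
  }
  w <- sapply(CONTEXTS, function(c)
    stats::rnorm(length(egg_lev), 0, pars[sprintf("sd_egg[%s]", c)]))
  w <- matrix(w, length(egg_lev), 3)

  i <- match(tr$individual_id, ind_tab$individual_id)
  e <- match(tr$eggmass_id, egg_lev)
  tc <- cbind(d$t_idx, d$c_idx)
  mu <- matrix(pars[sprintf("mu[%s,%s]", rep(TREATMENTS, each = 3),
                            rep(CONTEXTS, 3))], 3, 3, byrow = TRUE)
  bt <- pars[sprintf("beta_trial[%s]", CONTEXTS)]
  bs <- pars[sprintf("beta_svl[%s]", CONTEXTS)]
  sig <- matrix(pars[sprintf("sigma[%s,%s]", rep(TREATMENTS, each = 3),
                             rep(CONTEXTS, 3))], 3, 3, byrow = TRUE)
  eta <- mu[tc] + bt[d$c_idx] * tr$trial + bs[d$c_idx] * d$z +
    u[cbind(i, d$c_idx)] + w[cbind(e, d$c_idx)]
  y <- exp(eta + stats::rnorm(nrow(tr), 0, sig[tc]))
  for (t in 1:3) for (c in 2:3) {
    sel <- d$t_idx == t & d$c_idx == c
    if (!any(sel)) next
    p <- stats::plogis(pars[sprintf("hurdle[%s,%s]", TREATMENTS[t],
                                    CONTEXTS[c])])
    y[sel][stats::runif(sum(sel)) < p] <- 0
  }
  rep_tr <- tr
  rep_tr$distance <- y
  rep_tr
}

#' Simulate replicated datasets from a fitted behavioural model
#'
#' Posterior predictive simulation: each replicate takes one retained draw,
#' regenerates latent individual and egg-mass effects from that draw's
#' hyperparameters, and simulates distances over the observed design
#' (population-level, "new individuals" prediction).
#'
#' @param object a `"behavior_fit"`.
#' @param nsim number of replicated datasets.
#' @param seed integer seed (reproducible given the fit and seed).
#' @param ... unused.
#' @return List of `nsim` trial data frames.
#' @export
simulate.behavior_fit <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(seed)
  m <- .dm(object)
  rows <- sample.int(nrow(m), nsim, replace = nsim > nrow(m))
  lapply(rows, function(r) .pp_replicate(object, m[r, ]))
}

.pp_summaries <- function(trials) {
  out <- NULL
  for (t in TREATMENTS) for (c in CONTEXTS) {
    sel <- trials$treatment == t & trials$context == c
    if (!any(sel)) next
    y <- trials$distance[sel]
    pos <- y > 0
    out <- rbind(out, data.frame(
      treatment = t, context = c,
      zero_fraction = mean(!pos),
      mean_log_pos = if (any(pos)) mean(log(y[pos])) else NA_real_,
      var_log_pos = if (sum(pos) > 1) stats::var(log(y[pos])) else NA_real_))
  }
  out
}

#' Posterior predictive checks
#'
#' Compares observed summary statistics -- the zero fraction and the mean
#' and variance of log positive distances, per treatment x context -- with
#' their posterior predictive distributions over replicated datasets.  The
#' tail probability is `Pr(replicate >= observed)`; values near 0 or 1
#' flag summaries the model fails to reproduce.  For data simulated from
#' the model itself, tail probabilities are approximately uniform.
#'
#' @param fit a `"behavior_fit"`.
#' @param nsim number of replicated datasets.
#' @param seed integer seed.
#' @return Data frame of class `"ppc_summary"`: one row per cell and
#'   statistic with the observed value, predictive mean, central 95%
#'   predictive interval, and tail probability.
#' @export
posterior_predictive <- function(fit, nsim = 200, seed = 1L) {
  stopifnot(inherits(fit, "behavior_fit"))
  reps <- simulate(fit, nsim = nsim, seed = seed)
  obs <- .pp_summaries(fit$trials)
  stats_long <- function(df, tag) {
    out <- NULL
    for (s in c("zero_fraction", "mean_log_pos", "var_log_pos"))
      out <- rbind(out, data.frame(treatment = df$treatment,
                                   context = df$context, statistic = s,
                                   value = df[[s]], rep = tag))
    out
  }
  obs_l <- stats_long(obs, 0L)
  rep_l <- do.call(rbind, lapply(seq_along(reps), function(k)
    stats_long(.pp_summaries(reps[[k]]), k)))
  key <- function(d) paste(d$treatment, d$context, d$statistic)
  out <- obs_l[, c("treatment", "context", "statistic", "value")]
  names(out)[4] <- "observed"
  out$pred_mean <- NA_real_; out$pred_lower <- NA_real_
  out$pred_upper <- NA_real_; out$p_tail <- NA_real_
  rk <- key(rep_l)
  for (j in seq_len(nrow(out))) {
    vals <- rep_l$value[rk == key(out[j, ])]
    vals <- vals[is.finite(vals)]
    if (!length(vals) || !is.finite(out$observed[j])) next
    out$pred_mean[j] <- mean(vals)
    ci <- .eti(vals)
    out$pred_lower[j] <- ci[1]; out$pred_upper[j] <- ci[2]
    out$p_tail[j] <- mean(vals >= out$observed[j])
  }
  class(out) <- c("ppc_summary", "data.frame")
  out
}

#' @export
print.ppc_summary <- function(x, digits = 3, ...) {
  y <- x; class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
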