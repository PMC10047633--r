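# collapse the chains x draws x params array to a (chains*draws) x params
# matrix of posterior draws
.dm <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(2, 1, 3)), dim(d)[1] * dim(d)[2], dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Posterior draws as a matrix
#'
#' Retained draws of every model parameter with chains stacked, one column
#' per parameter (named as in the fit's `draws` array).
#'
#' @param fit a `"behavior_fit"` or `"bodysize_fit"`.
#' @return Numeric matrix, `(chains * draws) x parameters`.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, c("behavior_fit", "bodysize_fit")))
  .dm(fit)
}

.summarise_draws <- function(x, mass, type) {
  ci <- .interval(x, mass, type)
  c(mean = mean(x), lower = ci[[1]], upper = ci[[2]])
}

#' Among- and within-individual variance summaries
#'
#' Posterior draws of the among-individual variance (squared group-effect
#' SDs) and the natural-scale within-individual variance (exponential of
#' the log-scale residual variance) for every treatment x context cell,
#' summarised by posterior mean and 95% interval.
#'
#' @param fit a `"behavior_fit"`.
#' @param mass interval mass.
#' @param type `"hpdi"` or `"quantile"`.
#' @param complete use the complete log-normal data-scale variance for the
#'   within component (see [within_variance_natural()]).
#' @return Data frame (treatment x context rows) with V_among and V_within
#'   summaries; draw matrices are attached as attributes `"V_among"` and
#'   `"V_within"` (columns `treatment.context`).
#' @export
variance_summary <- function(fit, mass = 0.95, type = c("hpdi", "quantile"),
                             complete = FALSE) {
  stopifnot(inherits(fit, "behavior_fit"))
  type <- match.arg(type)
  m <- .dm(fit)
  out <- NULL
  Va <- Vw <- NULL
  for (t in TREATMENTS) for (c in CONTEXTS) {
    va <- sd_to_variance(m[, sprintf("sd_among[%s,%s]", t, c)])
    s2 <- sd_to_variance(m[, sprintf("sigma[%s,%s]", t, c)])
    vw <- if (complete)
      within_variance_natural(s2, complete = TRUE,
                              mu = m[, sprintf("mu[%s,%s]", t, c)])
    else within_variance_natural(s2)
    sa <- .summarise_draws(va, mass, type)
    sw <- .summarise_draws(vw, mass, type)
    out <- rbind(out, data.frame(treatment = t, context = c,
                                 V_among = sa[1], V_among_lower = sa[2],
                                 V_among_upper = sa[3],
                                 V_within = sw[1], V_within_lower = sw[2],
                                 V_within_upper = sw[3]))
    Va <- cbind(Va, va); Vw <- cbind(Vw, vw)
  }
  rownames(out) <- NULL
  colnames(Va) <- colnames(Vw) <-
    paste(out$treatment, out$context, sep = ".")
  attr(out, "V_among") <- Va
  attr(out, "V_within") <- Vw
  out
}

#' Adjusted repeatability summaries
#'
#' Per-draw repeatability `R = V_among / (V_among + V_within)` for each
#' treatment x context cell, with posterior mean and 95% interval.  The
#' estimates are adjusted in the sense that trial order and body size are
#' controlled as fixed effects in the model the draws come from.
#'
#' @inheritParams variance_summary
#' @return Data frame with columns `treatment`, `context`, `R`, `lower`,
#'   `upper`; repeatability draw matrix attached as attribute `"draws"`.
#' @export
repeatability_summary <- function(fit, mass = 0.95,
                                  type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  vs <- variance_summary(fit, mass, type)
  Va <- attr(vs, "V_among"); Vw <- attr(vs, "V_within")
  out <- NULL; Rd <- NULL
  for (j in seq_len(ncol(Va))) {
    R <- repeatability(Va[, j], Vw[, j])
    s <- .summarise_draws(R, mass, type)
    out <- rbind(out, data.frame(treatment = vs$treatment[j],
                                 context = vs$context[j],
                                 R = s[1], lower = s[2], upper = s[3]))
    Rd <- cbind(Rd, R)
  }
  rownames(out) <- NULL
  colnames(Rd) <- colnames(Va)
  attr(out, "draws") <- Rd
  out
}

#' Posterior acclimation-zone probabilities
#'
#' Hurdle intercept draws converted from the logit to the probability
#' scale: the probability that a trial in the novel or predator context
#' records distance zero, per treatment.
#'
#' @inheritParams variance_summary
#' @return Data frame with columns `treatment`, `context`, `p`, `lower`,
#'   `upper`; probability draw matrix attached as attribute `"draws"`.
#' @export
hurdle_probability <- function(fit, mass = 0.95,
                               type = c("hpdi", "quantile")) {
  stopifnot(inherits(fit, "behavior_fit"))
  type <- match.arg(type)
  m <- .dm(fit)
  out <- NULL; Pd <- NULL
  for (t in TREATMENTS) for (c in CONTEXTS[2:3]) {
    p <- logit_to_probability(m[, sprintf("hurdle[%s,%s]", t, c)])
    s <- .summarise_draws(p, mass, type)
    out <- rbind(out, data.frame(treatment = t, context = c,
                                 p = s[1], lower = s[2], upper = s[3]))
    Pd <- cbind(Pd, p)
  }
  rownames(out) <- NULL
  colnames(Pd) <- paste(out$treatment, out$context, sep = ".")
  attr(out, "draws") <- Pd
  out
}

#' Among-individual cross-context correlations (behavioural syndromes)
#'
#' Assembles, per retained draw and treatment, the 3x3 among-individual
#' covariance matrix from the SD and correlation draws, converts it to a
#' correlation matrix with [cov_to_corr()] (per-draw conversion), and
#' summarises each context pair.
#'
#' @inheritParams variance_summary
#' @return Data frame with columns `treatment`, `pair`, `cor`, `lower`,
#'   `upper`; correlation draw matrix attached as attribute `"draws"`.
#' @export
syndrome_correlations <- function(fit, mass = 0.95,
                                  type = c("hpdi", "quantile")) {
  stopifnot(inherits(fit, "behavior_fit"))
  type <- match.arg(type)
  m <- .dm(fit)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  pair_lab <- c("familiar,novel", "familiar,predator", "novel,predator")
  out <- NULL; Cd <- NULL
  for (t in TREATMENTS) {
    sdv <- sapply(CONTEXTS, function(c) m[, sprintf("sd_among[%s,%s]", t, c)])
    rr <- sapply(pair_lab, function(p) m[, sprintf("cor[%s,%s]", t, p)])
    n <- nrow(sdv)
    Sig <- array(0, c(3, 3, n))
    for (i in seq_len(n)) {
      Om <- diag(3)
      Om[rbind(pairs, pairs[, 2:1])] <- c(rr[i, ], rr[i, ])
      D <- diag(sdv[i, ])
      Sig[, , i] <- D %*% Om %*% D
    }
    Cor <- cov_to_corr(Sig)
    for (j in 1:3) {
      cd <- Cor[pairs[j, 1], pairs[j, 2], ]
      s <- .summarise_draws(cd, mass, type)
      out <- rbind(out, data.frame(treatment = t, pair = pair_lab[j],
                                   cor = s[1], lower = s[2], upper = s[3]))
      Cd <- cbind(Cd, cd)
    }
  }
  rownames(out) <- NULL
  colnames(Cd) <- paste(out$treatment, out$pair, sep = ".")
  attr(out, "draws") <- Cd
  out
}

#' Growth-model summaries and treatment contrasts
#'
#' Posterior summaries of the body-size model in the layout of the study's
#' growth tables: population means (per-treatment mean SVL at trial 0 and
#' the trial slope), egg-mass variance, among-individual variance in
#' initial size and in growth rate; plus all pairwise treatment contrasts
#' (signed and absolute) for the means and both variances.
#'
#' @param fit a `"bodysize_fit"`.
#' @inheritParams variance_summary
#' @return List with data frames `estimates` and `contrasts`.
#' @export
growth_summaries <- function(fit, mass = 0.95, type = c("hpdi", "quantile")) {
  stopifnot(inherits(fit, "bodysize_fit"))
  type <- match.arg(type)
  m <- .dm(fit)
  est <- NULL
  add <- function(df, quantity, label, x) {
    s <- .summarise_draws(x, mass, type)
    rbind(df, data.frame(quantity = quantity, label = label,
                         mean = s[1], lower = s[2], upper = s[3]))
  }
  for (t in TREATMENTS)
    est <- add(est, "population_mean", t, m[, sprintf("alpha[%s]", t)])
  est <- add(est, "trial_slope", "trial", m[, "beta_trial"])
  est <- add(est, "V_eggmass", "eggmass", sd_to_variance(m[, "sd_egg"]))
  for (t in TREATMENTS)
    est <- add(est, "V_initial_size", t,
               sd_to_variance(m[, sprintf("sd_int[%s]", t)]))
  for (t in TREATMENTS)
    est <- add(est, "V_growth_rate", t,
               sd_to_variance(m[, sprintf("sd_slope[%s]", t)]))
  rownames(est) <- NULL

  pairs <- list(c("no_competition", "conspecific"),
                c("no_competition", "heterospecific"),
                c("conspecific", "heterospecific"))
  cons <- NULL
  for (q in c("population_mean", "V_initial_size", "V_growth_rate")) {
    draws <- switch(q,
      population_mean = lapply(TREATMENTS, function(t)
        m[, sprintf("alpha[%s]", t)]),
      V_initial_size = lapply(TREATMENTS, function(t)
        sd_to_variance(m[, sprintf("sd_int[%s]", t)])),
      V_growth_rate = lapply(TREATMENTS, function(t)
        sd_to_variance(m[, sprintf("sd_slope[%s]", t)])))
    names(draws) <- TREATMENTS
    for (p in pairs) {
      ct <- treatment_contrast(draws, p, mass, type)
      cons <- rbind(cons, data.frame(
        quantity = q, pair = ct$pair,
        signed_mean = ct$signed_mean,
        signed_lower = ct$signed_interval[[1]],
        signed_upper = ct$signed_interval[[2]],
        abs_mean = ct$absolute_mean,
        abs_lower = ct$absolute_interval[[1]],
        abs_upper = ct$absolute_interval[[2]]))
    }
  }
  rownames(cons) <- NULL
  list(estimates = est, contrasts = cons)
}
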