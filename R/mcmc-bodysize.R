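# --- Gaussian random-slope growth model -----------------------------------

.prep_bodysize <- function(size) {
  n <- nrow(size)
  t_idx <- match(size$treatment, TREATMENTS)
  if (anyNA(t_idx)) stop("unknown treatment label in size records")
  ind_tab <- unique(size[, c("individual_id", "eggmass_id", "treatment")])
  rownames(ind_tab) <- NULL
  n_ind <- nrow(ind_tab)
  t_of_ind <- match(ind_tab$treatment, TREATMENTS)
  egg_lev <- unique(size$eggmass_id)
  n_egg <- length(egg_lev)
  ind_row <- match(size$individual_id, ind_tab$individual_id)
  egg_row <- match(size$eggmass_id, egg_lev)
  k <- size$trial
  # fixed effects plus egg-mass intercept indicators in one Gaussian block
  X <- cbind(t_idx == 1L, t_idx == 2L, t_idx == 3L, k) * 1
  if (n_egg) {
    Xe <- matrix(0, n, n_egg)
    Xe[cbind(seq_len(n), egg_row)] <- 1
    X <- cbind(X, Xe)
  }
  list(size = size, n = n, y = size$svl, k = k, t_idx = t_idx,
       ind_tab = ind_tab, n_ind = n_ind, t_of_ind = t_of_ind,
       egg_lev = egg_lev, n_egg = n_egg, ind_row = ind_row,
       egg_row = egg_row, X = X, Gram = crossprod(X))
}

.bodysize_par_names <- function() {
  c(sprintf("alpha[%s]", TREATMENTS), "beta_trial",
    sprintf("sd_int[%s]", TREATMENTS), sprintf("sd_slope[%s]", TREATMENTS),
    sprintf("cor_int_slope[%s]", TREATMENTS), "sd_egg", "sigma")
}

.growth_block_logpost <- function(U, lam, rho, nu, A, eta) {
  if (abs(rho) >= 1) return(-Inf)
  lp <- sum(.dhalft(exp(lam), nu, A) + lam) + (eta - 1) * log1p(-rho^2)
  n <- nrow(U)
  if (n) {
    sdv <- exp(lam)
    detO <- 1 - rho^2
    M <- U %*% diag(1 / sdv, 2)
    quad <- sum(M[, 1]^2 - 2 * rho * M[, 1] * M[, 2] + M[, 2]^2) / detO
    lp <- lp - 0.5 * quad - n * (0.5 * log(detO) + sum(lam)) -
      n * log(2 * pi)
  }
  lp
}

.run_bodysize_chain <- function(prep, spec, control, chain_seed) {
  set.seed(chain_seed)
  nu <- spec$prior_sd_df; A <- spec$prior_sd_scale
  eta_lkj <- spec$lkj_eta; fs2 <- spec$prior_fixed_sd^2
  inc_ind <- "individual" %in% spec$random && prep$n_ind > 0L
  inc_egg <- "eggmass" %in% spec$random && prep$n_egg > 0L

  active <- if (inc_egg) seq_len(4L + prep$n_egg) else 1:4
  Xa <- prep$X[, active, drop = FALSE]
  Gram_a <- prep$Gram[active, active, drop = FALSE]
  p_a <- length(active)

  beta <- numeric(p_a)
  beta[1:3] <- tapply(prep$y, prep$t_idx, mean)[as.character(1:3)]
  beta[is.na(beta)] <- 0
  beta[1:4] <- beta[1:4] + stats::rnorm(4L, 0, 0.1)
  sigma2 <- max(stats::var(prep$y), 0.01); a_sig <- 1
  g <- matrix(0, prep$n_ind, 2L)
  w <- numeric(prep$n_egg)
  lam <- matrix(c(log(0.5), log(0.1)), 3, 2, byrow = TRUE) +
    matrix(stats::rnorm(6, 0, 0.1), 3, 2)
  rho <- numeric(3L)
  V_egg <- 0.1; a_egg <- 1
  scl_lam <- matrix(0.4, 3, 2); scl_r <- rep(0.3, 3L)
  scl_lam_nc <- matrix(0.4, 3, 2); scl_r_nc <- rep(0.3, 3L)

  ndraw <- floor((control$iter - control$burnin) / control$thin)
  draws <- matrix(NA_real_, ndraw, 15L)
  g_sum <- matrix(0, prep$n_ind, 2L); w_sum <- numeric(prep$n_egg)
  drawn <- 0L
  inds_of_t <- lapply(1:3, function(t) which(prep$t_of_ind == t))
  kk <- prep$k

  for (it in seq_len(control$iter)) {
    adapting <- control$adapt && it <= control$burnin

    ## fixed effects and egg-mass intercepts (one conjugate block)
    prior_vec <- c(rep(1 / fs2, 4L), if (inc_egg) rep(1 / V_egg, prep$n_egg))
    re <- if (inc_ind) g[prep$ind_row, 1] + g[prep$ind_row, 2] * kk else 0
    prec <- diag(prior_vec, p_a) + Gram_a / sigma2
    b <- crossprod(Xa, (prep$y - re) / sigma2)
    ch <- chol(prec)
    beta <- as.vector(backsolve(ch, backsolve(ch, b, transpose = TRUE)) +
                        backsolve(ch, stats::rnorm(p_a)))
    if (inc_egg) w <- beta[-(1:4)]
    eta_fix <- as.vector(Xa %*% beta)
    resid0 <- prep$y - eta_fix

    ## individual (intercept, slope) pairs, plus a location interweave of
    ## the treatment means against the mean random intercept
    if (inc_ind) {
      sums <- rowsum(cbind(resid0, resid0 * kk, 1, kk, kk^2), prep$ind_row)
      idx <- as.integer(rownames(sums))
      for (t in 1:3) {
        ids <- inds_of_t[[t]]
        if (!length(ids)) next
        sdv <- exp(lam[t, ]); rr <- rho[t]
        Omega <- matrix(c(1, rr, rr, 1), 2, 2)
        P0 <- chol2inv(chol(Omega)) / tcrossprod(sdv)
        for (i in ids) {
          row <- match(i, idx)
          if (is.na(row)) { s <- rep(0, 5) } else s <- sums[row, ]
          Prec <- P0 + matrix(c(s[3], s[4], s[4], s[5]), 2, 2) / sigma2
          bi <- c(s[1], s[2]) / sigma2
          chi <- chol(Prec)
          g[i, ] <- backsolve(chi, backsolve(chi, bi, transpose = TRUE)) +
            backsolve(chi, stats::rnorm(2L))
        }
        # holding alpha + g0 fixed, redraw alpha from its conditional
        v <- g[ids, 1] + beta[t]
        prec_a <- length(ids) * P0[1, 1] + 1 / fs2
        mean_a <- (P0[1, 1] * sum(v) + P0[1, 2] * sum(g[ids, 2])) / prec_a
        a_new <- stats::rnorm(1, mean_a, 1 / sqrt(prec_a))
        delta <- a_new - beta[t]
        beta[t] <- a_new
        g[ids, 1] <- v - a_new
        resid0[prep$t_idx == t] <- resid0[prep$t_idx == t] - delta
      }
    }

    ## residual variance
    residf <- resid0 -
      (if (inc_ind) g[prep$ind_row, 1] + g[prep$ind_row, 2] * kk else 0)
    upd <- .update_variance_halft(sigma2, a_sig, prep$n, sum(residf^2), nu, A)
    sigma2 <- upd[1]; a_sig <- upd[2]

    ## egg-mass variance
    if (inc_egg) {
      upd <- .update_variance_halft(V_egg, a_egg, prep$n_egg, sum(w^2), nu, A)
      V_egg <- upd[1]; a_egg <- upd[2]
    } else V_egg <- .rhalft(1, nu, A)^2

    ## per-treatment (intercept, slope) covariance
    for (t in 1:3) {
      ids <- inds_of_t[[t]]
      if (!inc_ind || !length(ids)) {
        lam[t, ] <- log(.rhalft(2, nu, A))
        rho[t] <- .rlkj2(eta_lkj)
        next
      }
      U <- g[ids, , drop = FALSE]
      lp <- .growth_block_logpost(U, lam[t, ], rho[t], nu, A, eta_lkj)
      for (j in 1:2) {
        res <- .mh_step(lam[t, j], lp, function(x) {
          l2 <- lam[t, ]; l2[j] <- x
          .growth_block_logpost(U, l2, rho[t], nu, A, eta_lkj)
        }, scl_lam[t, j])
        lam[t, j] <- res$x; lp <- res$lp
        if (adapting) scl_lam[t, j] <- .adapt_scale(scl_lam[t, j],
                                                    res$accepted, it)
      }
      res <- .mh_step(rho[t], lp, function(x)
        .growth_block_logpost(U, lam[t, ], x, nu, A, eta_lkj), scl_r[t])
      rho[t] <- res$x
      if (adapting) scl_r[t] <- .adapt_scale(scl_r[t], res$accepted, it)

      ## interweaving: non-centered update with whitened effects fixed
      Amat <- .lt_factor(lam[t, ], rho[t])
      if (is.null(Amat)) next
      Ut <- forwardsolve(Amat, t(U))   # 2 x n_t
      rw_t <- resid0
      sel <- prep$t_idx == t
      loc <- match(prep$ind_row[sel], ids)
      st <- rowsum(cbind(rw_t[sel], rw_t[sel] * kk[sel], 1, kk[sel],
                         kk[sel]^2), loc)
      Sm <- matrix(0, length(ids), 5L)
      Sm[as.integer(rownames(st)), ] <- st
      lp_nc_fun <- function(lamv, rv) {
        if (abs(rv) >= 1) return(-Inf)
        Ac <- .lt_factor(lamv, rv)
        if (is.null(Ac)) return(-Inf)
        Uc <- t(Ac %*% Ut)
        quad <- sum(Uc[, 1]^2 * Sm[, 3] + 2 * Uc[, 1] * Uc[, 2] * Sm[, 4] +
                      Uc[, 2]^2 * Sm[, 5] -
                      2 * (Uc[, 1] * Sm[, 1] + Uc[, 2] * Sm[, 2]))
        -0.5 * quad / sigma2 + sum(.dhalft(exp(lamv), nu, A) + lamv) +
          (eta_lkj - 1) * log1p(-rv^2)
      }
      lp <- lp_nc_fun(lam[t, ], rho[t])
      for (j in 1:2) {
        res <- .mh_step(lam[t, j], lp, function(x) {
          l2 <- lam[t, ]; l2[j] <- x
          lp_nc_fun(l2, rho[t])
        }, scl_lam_nc[t, j])
        lam[t, j] <- res$x; lp <- res$lp
        if (adapting) scl_lam_nc[t, j] <- .adapt_scale(scl_lam_nc[t, j],
                                                       res$accepted, it)
      }
      res <- .mh_step(rho[t], lp, function(x)
        lp_nc_fun(lam[t, ], x), scl_r_nc[t])
      rho[t] <- res$x
      if (adapting) scl_r_nc[t] <- .adapt_scale(scl_r_nc[t], res$accepted, it)
      Anew <- .lt_factor(lam[t, ], rho[t])
      if (!is.null(Anew)) g[ids, ] <- t(Anew %*% Ut)
    }

    if (it > control$burnin && (it - control$burnin) %% control$thin == 0L) {
      drawn <- drawn + 1L
      draws[drawn, ] <- c(beta[1:4], exp(lam[, 1]), exp(lam[, 2]), rho,
                          sqrt(V_egg), sqrt(sigma2))
      g_sum <- g_sum + g; w_sum <- w_sum + w
    }
  }
  list(draws = draws, g_sum = g_sum, w_sum = w_sum, ndraw = drawn)
}

#' Fit the Gaussian random-slope body-size model
#'
#' Samples the posterior of the growth model: per-treatment mean SVL at
#' trial 0, a common trial slope, per-treatment individual random
#' intercepts and slopes with an intercept--slope correlation (LKJ prior),
#' an egg-mass intercept, and a Gaussian residual.  The sampler follows the
#' same scheme as [fit_behavior()] (conjugate Gaussian and inverse-gamma
#' mixture blocks; adaptive Metropolis for covariance blocks).
#'
#' @param trials either a full trial table (SVL records are extracted with
#'   [size_records()]) or a data frame already in size-record form.
#' @param spec a [bodysize_spec()].
#' @param control an [mcmc_control()].
#' @return An object of class `"bodysize_fit"` with the same components as
#'   a `"behavior_fit"` (draws array, diagnostics, latent means).
#' @export
fit_bodysize <- function(trials, spec = bodysize_spec(),
                         control = mcmc_control()) {
  stopifnot(inherits(spec, "bodysize_spec"), inherits(control, "mcmc_control"))
  size <- if (!is.null(trials$distance)) size_records(trials) else trials
  need <- c("individual_id", "eggmass_id", "treatment", "trial", "svl")
  missing_cols <- setdiff(need, names(size))
  if (length(missing_cols))
    stop("size records missing column(s): ",
         paste(missing_cols, collapse = ", "))
  prep <- .prep_bodysize(size)
  seeds <- .chain_seeds(control$seed, control$chains)
  res <- lapply(seeds, function(s)
    .run_bodysize_chain(prep, spec, control, s))
  nm <- .bodysize_par_names()
  ndraw <- res[[1]]$ndraw
  draws <- array(NA_real_, dim = c(control$chains, ndraw, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  for (k in seq_along(res)) draws[k, , ] <- res[[k]]$draws
  tot <- control$chains * max(ndraw, 1L)
  g_mean <- Reduce(`+`, lapply(res, `[[`, "g_sum")) / tot
  w_mean <- Reduce(`+`, lapply(res, `[[`, "w_sum")) / tot
  rownames(g_mean) <- prep$ind_tab$individual_id
  colnames(g_mean) <- c("intercept", "slope")
  names(w_mean) <- prep$egg_lev
  diag_df <- .diagnostics_array(draws)
  structure(list(
    draws = draws,
    diagnostics = diag_df,
    convergence_flag = any(diag_df$rhat > 1.05, na.rm = TRUE),
    g_mean = g_mean, w_mean = w_mean,
    ind_tab = prep$ind_tab, egg_lev = prep$egg_lev,
    size = prep$size,
    spec = spec, control = control
  ), class = "bodysize_fit")
}
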