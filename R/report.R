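# --- table analogues of the study's reporting layout ----------------------

.behavior_estimates_table <- function(fit, mass = 0.95,
                                      type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  m <- .dm(fit)
  add <- function(df, quantity, treatment, context, x) {
    s <- .summarise_draws(x, mass, type)
    rbind(df, data.frame(quantity = quantity, treatment = treatment,
                         context = context, mean = s[1], lower = s[2],
                         upper = s[3]))
  }
  out <- NULL
  for (t in TREATMENTS) for (c in CONTEXTS)
    out <- add(out, "population_mean", t, c, m[, sprintf("mu[%s,%s]", t, c)])
  for (c in CONTEXTS) {
    out <- add(out, "svl_slope", "all", c, m[, sprintf("beta_svl[%s]", c)])
    out <- add(out, "trial_slope", "all", c, m[, sprintf("beta_trial[%s]", c)])
    out <- add(out, "V_eggmass", "all", c,
               sd_to_variance(m[, sprintf("sd_egg[%s]", c)]))
  }
  vs <- variance_summary(fit, mass, type)
  Va <- attr(vs, "V_among"); Vw <- attr(vs, "V_within")
  for (j in seq_len(nrow(vs))) {
    out <- add(out, "V_among", vs$treatment[j], vs$context[j], Va[, j])
    out <- add(out, "V_within", vs$treatment[j], vs$context[j], Vw[, j])
  }
  hp <- hurdle_probability(fit, mass, type)
  Pd <- attr(hp, "draws")
  for (j in seq_len(nrow(hp)))
    out <- add(out, "p_stay_az", hp$treatment[j], hp$context[j], Pd[, j])
  rownames(out) <- NULL
  out
}

.behavior_contrasts_table <- function(fit, mass = 0.95,
                                      type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  m <- .dm(fit)
  vs <- variance_summary(fit, mass, type)
  Va <- attr(vs, "V_among"); Vw <- attr(vs, "V_within")
  hp <- hurdle_probability(fit, mass, type)
  Pd <- attr(hp, "draws")
  pairs <- list(c("no_competition", "conspecific"),
                c("no_competition", "heterospecific"),
                c("conspecific", "heterospecific"))
  out <- NULL
  grab <- function(quantity, c) {
    switch(quantity,
      population_mean = stats::setNames(lapply(TREATMENTS, function(t)
        m[, sprintf("mu[%s,%s]", t, c)]), TREATMENTS),
      V_among = stats::setNames(lapply(TREATMENTS, function(t)
        Va[, paste(t, c, sep = ".")]), TREATMENTS),
      V_within = stats::setNames(lapply(TREATMENTS, function(t)
        Vw[, paste(t, c, sep = ".")]), TREATMENTS),
      p_stay_az = stats::setNames(lapply(TREATMENTS, function(t)
        Pd[, paste(t, c, sep = ".")]), TREATMENTS))
  }
  for (q in c("population_mean", "V_among", "V_within", "p_stay_az")) {
    ctx <- if (q == "p_stay_az") CONTEXTS[2:3] else CONTEXTS
    for (c in ctx) {
      draws <- grab(q, c)
      for (p in pairs) {
        ct <- treatment_contrast(draws, p, mass, type)
        out <- rbind(out, data.frame(
          quantity = q, context = c, pair = ct$pair,
          signed_mean = ct$signed_mean,
          signed_lower = ct$signed_interval[[1]],
          signed_upper = ct$signed_interval[[2]],
          abs_mean = ct$absolute_mean,
          abs_lower = ct$absolute_interval[[1]],
          abs_upper = ct$absolute_interval[[2]]))
      }
    }
  }
  rownames(out) <- NULL
  out
}

.repeatability_contrasts_table <- function(fit, mass = 0.95,
                                           type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  rs <- repeatability_summary(fit, mass, type)
  Rd <- attr(rs, "draws")
  pairs <- list(c("no_competition", "conspecific"),
                c("no_competition", "heterospecific"),
                c("conspecific", "heterospecific"))
  out <- NULL
  for (c in CONTEXTS) {
    draws <- stats::setNames(lapply(TREATMENTS, function(t)
      Rd[, paste(t, c, sep = ".")]), TREATMENTS)
    for (p in pairs) {
      ct <- treatment_contrast(draws, p, mass, type)
      out <- rbind(out, data.frame(
        context = c, pair = ct$pair,
        signed_mean = ct$signed_mean,
        signed_lower = ct$signed_interval[[1]],
        signed_upper = ct$signed_interval[[2]],
        abs_mean = ct$absolute_mean,
        abs_lower = ct$absolute_interval[[1]],
        abs_upper = ct$absolute_interval[[2]]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write the six report tables of a full analysis
#'
#' Emits CSV analogues of the study's reporting layout: growth-model
#' population means and variances (table 1) and their treatment contrasts
#' (table 2); behavioural population means, among/within variances and
#' acclimation-zone probabilities (table 3) and their contrasts (table 4);
#' repeatabilities (table 5) and repeatability contrasts (table 6).  A
#' header file records the seed, MCMC settings, priors and interval type.
#'
#' @param behavior a `"behavior_fit"`.
#' @param bodysize a `"bodysize_fit"`.
#' @param dir output directory (created if needed).
#' @param mass interval mass.
#' @param type interval type (`"hpdi"` default, `"quantile"` for
#'   equal-tail intervals).
#' @return Named character vector of the files written, invisibly.
#' @export
report_tables <- function(behavior, bodysize, dir, mass = 0.95,
                          type = c("hpdi", "quantile")) {
  type <- match.arg(type)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- growth_summaries(bodysize, mass, type)
  tables <- list(
    table1_growth_estimates = gs$estimates,
    table2_growth_contrasts = gs$contrasts,
    table3_behavior_estimates = .behavior_estimates_table(behavior, mass, type),
    table4_behavior_contrasts = .behavior_contrasts_table(behavior, mass, type),
    table5_repeatability = repeatability_summary(behavior, mass, type),
    table6_repeatability_contrasts =
      .repeatability_contrasts_table(behavior, mass, type)
  )
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- tables[[nm]]
    attributes(df)[setdiff(names(attributes(df)),
                           c("names", "row.names", "class"))] <- NULL
    utils::write.csv(df, p, row.names = FALSE)
    paths[nm] <- p
  }
  header <- c(
    "# analysis report header",
    paste0("package_version: ", as.character(utils::packageVersion("hurdlemm"))),
    paste0("interval_type: ", type),
    paste0("interval_mass: ", mass),
    paste0("chains: ", behavior$control$chains),
    paste0("iterations: ", behavior$control$iter),
    paste0("burnin: ", behavior$control$burnin),
    paste0("thin: ", behavior$control$thin),
    paste0("seed: ", behavior$control$seed),
    paste0("prior_fixed_sd: ", behavior$spec$prior_fixed_sd),
    paste0("prior_sd_df: ", behavior$spec$prior_sd_df),
    paste0("prior_sd_scale: ", behavior$spec$prior_sd_scale),
    paste0("lkj_eta: ", behavior$spec$lkj_eta),
    paste0("convergence_flag_behavior: ", behavior$convergence_flag),
    paste0("convergence_flag_bodysize: ", bodysize$convergence_flag)
  )
  hp <- file.path(dir, "report_header.txt")
  writeLines(header, hp)
  paths["header"] <- hp
  invisible(paths)
}
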