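# one small shared fit for the summary/PPC method tests
p_small <- default_params(seed = 71)
p_small$n_individuals_per_treatment <- c(10L, 10L, 10L)
p_small$n_egg_masses <- 5L
sim_small <- simulate_trials(p_small, seed = 71)
fit_small <- fit_behavior(sim_small$trials,
                          control = mcmc_control(chains = 2, iter = 300,
                                                 burnin = 60, thin = 2,
                                                 seed = 71))
gfit_small <- fit_bodysize(sim_small$trials,
                           control = mcmc_control(chains = 2, iter = 300,
                                                  burnin = 60, thin = 2,
                                                  seed = 72))

test_that("variance, repeatability, hurdle and syndrome summaries are
           draw-consistent", {
  m <- posterior_draws(fit_small)
  vs <- variance_summary(fit_small)
  expect_equal(nrow(vs), 9)
  j <- which(vs$treatment == "conspecific" & vs$context == "novel")
  expect_equal(vs$V_among[j],
               mean(m[, "sd_among[conspecific,novel]"]^2))
  expect_equal(vs$V_within[j],
               mean(exp(m[, "sigma[conspecific,novel]"]^2)))
  rs <- repeatability_summary(fit_small)
  expect_equal(nrow(rs), 9)
  Rd <- attr(rs, "draws")
  expect_true(all(Rd >= 0 & Rd <= 1))
  va <- m[, "sd_among[conspecific,novel]"]^2
  vw <- exp(m[, "sigma[conspecific,novel]"]^2)
  expect_equal(rs$R[j], mean(va / (va + vw)))
  hp <- hurdle_probability(fit_small)
  expect_equal(nrow(hp), 6)
  expect_equal(hp$p[hp$treatment == "no_competition" & hp$context == "novel"],
               mean(plogis(m[, "hurdle[no_competition,novel]"])))
  sc <- syndrome_correlations(fit_small)
  expect_equal(nrow(sc), 9)
  expect_true(all(abs(sc$cor) <= 1))
  # with zero-free SD draws, per-draw cov->cor returns the cor draws
  expect_equal(sc$cor[sc$treatment == "no_competition" &
                        sc$pair == "familiar,novel"],
               mean(m[, "cor[no_competition,familiar,novel]"]))
})

test_that("fit methods expose coefficients, summaries and residuals", {
  expect_output(print(fit_small), "hurdle log-normal")
  s <- summary(fit_small)
  expect_true(all(c("parameter", "mean", "rhat", "ess") %in% names(s)))
  expect_equal(nrow(s), 51)
  cf <- coef(fit_small)
  expect_length(cf, 15)
  expect_true(all(grepl("^(mu|beta)", names(cf))))
  r <- residuals(fit_small)
  expect_length(r, nrow(sim_small$trials))
  expect_true(all(is.na(r[sim_small$trials$distance == 0])))
  expect_true(all(is.finite(r[sim_small$trials$distance > 0])))
  cg <- coef(gfit_small)
  expect_length(cg, 4)
  gr <- residuals(gfit_small)
  expect_length(gr, nrow(gfit_small$size))
  gs <- growth_summaries(gfit_small)
  expect_equal(sort(unique(gs$estimates$quantity)),
               sort(c("population_mean", "trial_slope", "V_eggmass",
                      "V_initial_size", "V_growth_rate")))
  expect_equal(nrow(gs$contrasts), 9)
  pdf(NULL)
  expect_invisible(plot(fit_small, pars = dimnames(fit_small$draws)[[3]][1:2]))
  dev.off()
})

test_that("posterior predictive replicates respect the model structure and
           the seed", {
  reps <- simulate(fit_small, nsim = 3, seed = 9)
  expect_length(reps, 3)
  for (rp in reps) {
    expect_equal(nrow(rp), nrow(sim_small$trials))
    expect_true(all(rp$distance[rp$context == "familiar"] > 0))
    expect_true(all(rp$distance >= 0))
  }
  reps2 <- simulate(fit_small, nsim = 3, seed = 9)
  expect_identical(reps, reps2)
  reps3 <- simulate(fit_small, nsim = 3, seed = 10)
  expect_false(identical(reps[[1]]$distance, reps3[[1]]$distance))
})

test_that("posterior predictive checks flag nothing extreme on data the
           model generated", {
  ppc <- posterior_predictive(fit_small, nsim = 150, seed = 5)
  expect_s3_class(ppc, "ppc_summary")
  zf <- ppc[ppc$statistic == "zero_fraction", ]
  fam <- zf[zf$context == "familiar", ]
  expect_true(all(fam$observed == 0))
  expect_true(all(fam$pred_mean == 0))
  nonfam <- zf[zf$context != "familiar", ]
  expect_true(all(nonfam$p_tail > 0.005 & nonfam$p_tail < 0.995))
  ml <- ppc[ppc$statistic == "mean_log_pos", ]
  expect_true(all(ml$p_tail > 0.005 & ml$p_tail < 0.995))
})
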