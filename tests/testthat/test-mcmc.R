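test_that("control settings validate and count retained draws", {
  expect_equal(n_retained(mcmc_control()), 300)
  expect_equal(n_retained(mcmc_control(chains = 2, iter = 500, burnin = 100,
                                       thin = 2)), 2 * 200)
  expect_error(mcmc_control(burnin = 600, iter = 500), "burnin")
  expect_error(mcmc_control(thin = 0), "thin")
  expect_error(mcmc_control(chains = 0), "chains")
})

test_that("the sampler reproduces a conjugate normal-mean posterior", {
  set.seed(1)
  n <- 40
  y <- exp(rnorm(n, 1.5, 0.7))
  tr <- data.frame(individual_id = sprintf("i%02d", 1:n), eggmass_id = "e1",
                   treatment = "no_competition", context = "familiar",
                   trial = 0L, distance = y, svl = 5)
  spec <- behavior_spec(random = character(0),
                        fix_sigma = matrix(0.7, 3, 3))
  fit <- fit_behavior(tr, spec, mcmc_control(chains = 2, iter = 2000,
                                             burnin = 100, thin = 1,
                                             seed = 7))
  draws <- posterior_draws(fit)[, "mu[no_competition,familiar]"]
  # exact posterior: known variance 0.49, prior N(0, 100)
  v_post <- 1 / (n / 0.49 + 1 / 100)
  m_post <- v_post * sum(log(y)) / 0.49
  nd <- length(draws)
  expect_lt(abs(mean(draws) - m_post), 3 * sqrt(v_post / nd))
  expect_lt(abs(sd(draws) - sqrt(v_post)),
            3 * sqrt(v_post / (2 * (nd - 1))))
})

test_that("fits are exactly reproducible given the seed", {
  p <- default_params(seed = 4)
  p$n_individuals_per_treatment <- c(6L, 6L, 6L)
  p$n_egg_masses <- 3L
  sim <- simulate_trials(p, seed = 4)
  ctl <- mcmc_control(chains = 2, iter = 120, burnin = 20, thin = 2,
                      seed = 11)
  f1 <- fit_behavior(sim$trials, control = ctl)
  f2 <- fit_behavior(sim$trials, control = ctl)
  expect_identical(f1$draws, f2$draws)
  g1 <- fit_bodysize(sim$trials, control = ctl)
  g2 <- fit_bodysize(sim$trials, control = ctl)
  expect_identical(g1$draws, g2$draws)
  ctl2 <- mcmc_control(chains = 2, iter = 120, burnin = 20, thin = 2,
                       seed = 12)
  f3 <- fit_behavior(sim$trials, control = ctl2)
  expect_false(identical(f1$draws, f3$draws))
  # retained-draw bookkeeping matches the settings arithmetic
  expect_equal(dim(f1$draws)[1] * dim(f1$draws)[2], n_retained(ctl))
})

test_that("split R-hat and ESS behave under null, shifted and degenerate
           chains", {
  set.seed(5)
  iid <- matrix(rnorm(4 * 5000), 4, 5000)
  expect_gt(rhat(iid), 0.99)
  expect_lt(rhat(iid), 1.01)
  expect_gt(ess(iid), 0.5 * 4 * 5000)
  shifted <- iid
  shifted[1, ] <- shifted[1, ] + 3
  expect_gt(rhat(shifted), 1.1)
  flat <- matrix(1, 2, 100)
  expect_true(is.na(rhat(flat)))
  expect_true(is.na(ess(flat)))
  expect_error(rhat(matrix(rnorm(100), 1, 100)), "2 chains")
  # a within-chain trend also inflates split R-hat
  trended <- matrix(rnorm(2 * 2000), 2, 2000) +
    matrix(seq(0, 3, length.out = 2000), 2, 2000, byrow = TRUE)
  expect_gt(rhat(trended), 1.1)
})

test_that("prior-only sampling reproduces the prior moments", {
  fit <- fit_behavior(NULL, behavior_spec(),
                      mcmc_control(chains = 2, iter = 4000, burnin = 100,
                                   thin = 1, seed = 3))
  m <- posterior_draws(fit)
  mu <- m[, "mu[no_competition,familiar]"]
  expect_lt(abs(mean(mu)), 3 * 10 / sqrt(length(mu)))
  expect_equal(sd(mu), 10, tolerance = 0.1)
  h <- m[, "hurdle[conspecific,novel]"]
  expect_equal(sd(h), 10, tolerance = 0.1)
  # half-t(3, 2.5) prior on SDs: compare a bounded transform against a
  # direct Monte-Carlo sample, with an ESS-aware error allowance
  sig <- m[, "sigma[conspecific,novel]"]
  set.seed(99)
  ref <- abs(2.5 * rt(2e5, 3))
  neff <- ess(t(matrix(atan(sig), ncol = 2)))
  se <- sd(atan(sig)) / sqrt(max(neff, 50))
  expect_lt(abs(mean(atan(sig)) - mean(atan(ref))), 4 * se + 0.01)
  # LKJ(2) prior on a 3x3 correlation: each off-diagonal is a shifted
  # Beta(2.5, 2.5), so mean 0 and sd sqrt(1/6)
  r <- m[, "cor[heterospecific,familiar,novel]"]
  expect_lt(abs(mean(r)), 0.05)
  expect_equal(sd(r), sqrt(1 / 6), tolerance = 0.1)
})

test_that("the convergence flag trips on deliberately unmixed chains", {
  p <- default_params(seed = 6)
  p$n_individuals_per_treatment <- c(8L, 8L, 8L)
  p$n_egg_masses <- 4L
  sim <- simulate_trials(p, seed = 6)
  # absurdly short run: burn-in 1, no adaptation time, chains disagree
  fit <- fit_behavior(sim$trials,
                      control = mcmc_control(chains = 2, iter = 12,
                                             burnin = 2, thin = 1,
                                             seed = 2))
  expect_true(is.data.frame(diagnostics(fit)))
  expect_true("rhat" %in% names(diagnostics(fit)))
  expect_true(isTRUE(fit$convergence_flag) || all(
    diagnostics(fit)$rhat <= 1.05, na.rm = TRUE))
})
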