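test_that("hurdle zeros appear at the requested rate and only where allowed", {
  p <- default_params(seed = 11)
  p$n_individuals_per_treatment <- c(850L, 0L, 0L)
  p$n_egg_masses <- 10L
  p$p_hurdle["no_competition", "novel"] <- 0.5
  sim <- simulate_trials(p, seed = 11)
  novel <- sim$trials[sim$trials$context == "novel", ]
  expect_gte(nrow(novel), 5000)
  expect_equal(mean(novel$distance == 0), 0.5, tolerance = 0.015 / 0.5)
  expect_true(all(sim$trials$distance[sim$trials$context == "familiar"] > 0))
})

test_that("zeros never occur outside the novel and predator contexts", {
  sim <- simulate_trials(default_params(seed = 2))
  zero_ctx <- unique(sim$trials$context[sim$trials$distance == 0])
  expect_true(all(zero_ctx %in% c("novel", "predator")))
})

test_that("positive distances are log-normal around the linear predictor", {
  p <- default_params(seed = 5)
  p$n_individuals_per_treatment <- c(400L, 0L, 0L)
  p$mu[] <- 0
  p$beta_trial[] <- 0; p$beta_svl[] <- 0
  p$V_among[] <- 0; p$V_eggmass[] <- 0
  p$sigma2_log[] <- 1
  p$p_hurdle[, 2:3] <- 0
  sim <- simulate_trials(p, seed = 5)
  x <- log(sim$trials$distance)
  expect_lt(abs(mean(x)), 3 / sqrt(length(x)))
  expect_equal(var(x), 1, tolerance = 0.1)
})

test_that("simulation is reproducible given the seed", {
  p <- default_params(seed = 99)
  s1 <- simulate_trials(p)
  s2 <- simulate_trials(p)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth$u, s2$truth$u)
  s3 <- simulate_trials(p, seed = 100)
  expect_false(identical(s1$trials$distance, s3$trials$distance))
})

test_that("among-individual variance of individual means approaches
           V_among plus the egg-mass share as trials accumulate", {
  p <- default_params(seed = 13)
  p$n_individuals_per_treatment <- c(1000L, 0L, 0L)
  p$n_trials <- 50L
  p$n_egg_masses <- 100L
  p$mu[] <- 6
  p$beta_trial[] <- 0; p$beta_svl[] <- 0
  p$V_among[1, ] <- 0.5
  p$V_eggmass[] <- 0.2
  p$sigma2_log[] <- 1
  p$p_hurdle[, 2:3] <- 0
  sim <- simulate_trials(p, seed = 13)
  fam <- sim$trials[sim$trials$context == "familiar", ]
  means <- tapply(log(fam$distance), fam$individual_id, mean)
  # V_among + V_eggmass + sigma2/n_trials
  expect_equal(var(as.vector(means)), 0.5 + 0.2 + 1 / 50, tolerance = 0.10)
})

test_that("realized individual deviations recover the cross-context
           correlation matrix", {
  p <- default_params(seed = 21)
  p$n_individuals_per_treatment <- c(5000L, 0L, 0L)
  p$n_trials <- 2L
  Om <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.2, 0.3, 0.2, 1), 3, 3)
  p$Omega[[1]] <- Om
  p$V_among[1, ] <- c(0.4, 0.6, 0.5)
  sim <- simulate_trials(p, seed = 21)
  u <- sim$truth$u[seq_len(5000), ]
  expect_true(all(abs(cor(u)[upper.tri(Om)] - Om[upper.tri(Om)]) < 0.05))
  expect_true(all(abs(diag(var(u)) - p$V_among[1, ]) < 0.05))
})

test_that("record dropout removes rows missing-at-random when enabled", {
  p <- default_params(seed = 31)
  p$dropout <- 0.2
  sim <- simulate_trials(p, seed = 31)
  full <- sum(p$n_individuals_per_treatment) * 3 * p$n_trials
  expect_lt(nrow(sim$trials), full)
  expect_equal(nrow(sim$trials) / full, 0.8, tolerance = 0.05)
})
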