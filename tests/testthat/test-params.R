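test_that("default parameters reproduce the anchored study design", {
  p <- default_params()
  expect_identical(p$n_individuals_per_treatment, c(54L, 56L, 51L))
  expect_identical(p$n_trials, 6L)
  expect_equal(p$V_among["heterospecific", "familiar"], 0.686)
  expect_equal(p$p_hurdle["no_competition", "novel"], 0.375)
  expect_equal(unname(p$beta_trial["familiar"]), -0.114)
  expect_equal(p$growth$size_trial_slope, 0.056)
  expect_equal(p$mu["no_competition", "familiar"], 6.228)
  # log-scale residual variances invert exactly to the natural-scale values
  expect_equal(within_variance_natural(p$sigma2_log["no_competition",
                                                    "familiar"]), 2.796)
  expect_equal(unname(exp(p$sigma2_log["conspecific", "novel"])), 3.466)
  expect_true(all(p$p_hurdle[, "familiar"] == 0))
})

test_that("parameter invariants are enforced", {
  p <- default_params()
  bad <- p; bad$V_among[1, 1] <- -0.1
  expect_error(validate_params(bad), "non-negative")
  bad <- p; bad$p_hurdle[2, 2] <- 1.4
  expect_error(validate_params(bad), "0, 1")
  bad <- p; bad$p_hurdle[1, 1] <- 0.2
  expect_error(validate_params(bad), "familiar")
  bad <- p; bad$n_trials <- 1L
  expect_error(validate_params(bad), "n_trials")
  bad <- p; bad$Omega[[2]][1, 2] <- 0.5  # asymmetric
  expect_error(validate_params(bad), "symmetric")
  bad <- p
  bad$Omega[[3]] <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(validate_params(bad), "semi-definite")
})
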