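test_that("scale transforms are exact element-wise maps", {
  expect_equal(sd_to_variance(0), 0)
  expect_equal(sd_to_variance(2), 4)
  x <- abs(rnorm(200))
  expect_equal(sd_to_variance(x), sapply(x, function(v) v * v))
  expect_error(sd_to_variance(c(1, -0.1)), "non-negative")

  expect_equal(within_variance_natural(0), 1)
  expect_equal(within_variance_natural(1), exp(1))
  expect_equal(within_variance_natural(log(2.796)), 2.796)
  # complete log-normal data-scale variance, opt-in
  s2 <- 0.8; mu <- 6
  expect_equal(within_variance_natural(s2, complete = TRUE, mu = mu),
               (exp(s2) - 1) * exp(2 * mu + s2))
  expect_error(within_variance_natural(0.5, complete = TRUE), "mu")
})

test_that("repeatability is an exact per-draw ratio with guarded edges", {
  expect_equal(as.numeric(repeatability(0, 2.5)), 0)
  expect_equal(as.numeric(repeatability(1.3, 1.3)), 0.5)
  expect_equal(as.numeric(repeatability(0.175, 1.770)), 0.175 / 1.945)
  # scale equivariance
  va <- runif(100, 0, 2); vw <- runif(100, 0.1, 3)
  expect_equal(as.numeric(repeatability(5 * va, 5 * vw)),
               as.numeric(repeatability(va, vw)))
  r <- repeatability(va, vw)
  expect_true(all(r >= 0 & r <= 1))
  # both-zero draws are excluded and counted
  r2 <- repeatability(c(0, 1, 0), c(0, 1, 2))
  expect_equal(attr(r2, "n_excluded"), 1)
  expect_equal(length(r2), 2)
  expect_error(repeatability(1:3, 1:2), "equal length")
})

test_that("hpdi is the exact shortest window and never wider than the
           equal-tail interval", {
  expect_equal(unname(hpdi(1:100, 0.95)), c(1, 95))
  expect_equal(diff(hpdi(1:100, 0.95)), 94, ignore_attr = TRUE)
  expect_equal(unname(hpdi(rep(3.2, 50))), c(3.2, 3.2))
  expect_error(hpdi(1:100, 1.2), "mass")
  expect_error(hpdi(1:10), "20 draws")
  set.seed(14)
  for (k in 1:20) {
    draws <- switch(1 + k %% 3,
                    rexp(200 + k), rnorm(150), rlnorm(300, 0, 0.8))
    for (mass in c(0.5, 0.8, 0.95)) {
      got <- hpdi(draws, mass)
      want <- oracle_hpdi(draws, mass)
      expect_equal(unname(got), want)
      # never wider than the central order-statistic interval holding at
      # least the same number of sorted draws (interpolated quantiles can
      # undercut any attainable window, so compare by counts)
      q <- quantile(draws, c((1 - mass) / 2, 1 - (1 - mass) / 2),
                    names = FALSE, type = 1)
      expect_lte(diff(got), q[2] - q[1] + 1e-12)
    }
  }
  # exponential-shaped posteriors: lower bound hugs zero
  set.seed(15)
  ex <- rexp(5000)
  expect_lt(hpdi(ex)[1], quantile(ex, 0.025))
  expect_lt(hpdi(ex)[1], 0.01)
})

test_that("treatment contrasts report signed and absolute differences", {
  a <- rnorm(500, 2, 0.3)
  same <- list(no_competition = a, conspecific = a)
  ct <- treatment_contrast(same, c("no_competition", "conspecific"))
  expect_equal(ct$signed_mean, 0)
  expect_equal(unname(ct$signed_interval), c(0, 0))
  expect_equal(unname(ct$absolute_interval), c(0, 0))
  const <- list(no_competition = rep(3, 100), heterospecific = rep(1, 100))
  ct2 <- treatment_contrast(const, c("no_competition", "heterospecific"))
  expect_equal(ct2$signed_mean, 2)
  expect_equal(ct2$absolute_mean, 2)
  expect_error(treatment_contrast(list(no_competition = 1:5,
                                       conspecific = 1:4),
                                  c("no_competition", "conspecific")),
               "equal length")
  # equal-in-distribution posteriors: absolute difference piles up near 0
  set.seed(16)
  eq <- list(no_competition = rnorm(4000), conspecific = rnorm(4000))
  ct3 <- treatment_contrast(eq, c("no_competition", "conspecific"))
  expect_lt(ct3$absolute_interval[[1]], 0.05)
  expect_lt(abs(ct3$signed_mean), 0.1)
})

test_that("logit draws convert exactly and monotonically to probabilities", {
  expect_equal(logit_to_probability(0), 0.5)
  expect_equal(logit_to_probability(log(0.375 / 0.625)), 0.375)
  x <- sort(rnorm(100, 0, 3))
  p <- logit_to_probability(x)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("covariance draws convert to correlations by diagonal
           normalisation", {
  S <- matrix(c(4, 3, 3, 9), 2, 2)
  expect_equal(cov_to_corr(S)[1, 2], 0.5)
  expect_equal(cov_to_corr(diag(3)), diag(3))
  set.seed(17)
  for (k in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A) + diag(0.1, 3)
    D <- diag(1 / sqrt(diag(S)))
    expect_equal(cov_to_corr(S), D %*% S %*% D, tolerance = 1e-12)
  }
  # array of draws
  arr <- array(0, c(2, 2, 5))
  for (i in 1:5) arr[, , i] <- matrix(c(4, 2, 2, 25), 2, 2)
  out <- cov_to_corr(arr)
  expect_equal(out[1, 2, 3], 2 / 10)
  expect_true(all(out[1, 1, ] == 1))
  # zero variance flags undefined correlations
  expect_warning(z <- cov_to_corr(matrix(c(0, 0, 0, 4), 2, 2)),
                 "zero variance")
  expect_true(is.na(z[1, 2]))
})
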