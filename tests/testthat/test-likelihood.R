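test_that("log-normal and hurdle densities match closed forms", {
  expect_equal(lognormal_logpdf(1, 0, 1), -0.5 * log(2 * pi))
  expect_equal(lognormal_logpdf(exp(1), 1, 1), -1 - 0.5 * log(2 * pi))
  expect_equal(hurdle_lognormal_logpdf(0, 0.5, 3, 2), log(0.5))
  expect_equal(hurdle_lognormal_logpdf(1, 0, 0, 1), -0.5 * log(2 * pi))
  # change of variables: density of y equals density of log y minus log y
  y <- c(0.3, 1.7, 9.2)
  expect_equal(lognormal_logpdf(y, 0.4, 1.3),
               dnorm(log(y), 0.4, 1.3, log = TRUE) - log(y))
  expect_error(lognormal_logpdf(0, 0, 1), "positive")
  expect_error(lognormal_logpdf(-2, 0, 1), "positive")
  expect_error(hurdle_lognormal_logpdf(-1, 0.5, 0, 1), "non-negative")
  expect_error(hurdle_lognormal_logpdf(1, 1.5, 0, 1), "0, 1")
})

test_that("the hurdle density integrates to one over the whole support", {
  for (p in c(0, 0.3, 0.7)) for (mu in c(-1, 0, 1.5))
    for (sigma in c(0.5, 1, 2)) {
      cont <- integrate(function(y)
        exp(hurdle_lognormal_logpdf(y, p, mu, sigma)),
        lower = 1e-12, upper = Inf, rel.tol = 1e-9)$value
      total <- p + cont
      expect_equal(total, 1, tolerance = 1e-6)
    }
})

test_that("the linear predictor composes intercepts, slopes and latent
           effects additively", {
  tr <- make_toy()
  pars <- make_toy_pars(tr)
  zero <- pars
  zero$u[] <- 0; zero$w[] <- 0
  zero$beta_trial[] <- 0; zero$beta_svl[] <- 0
  one <- tr[tr$trial == 0, ][1, ]
  eta <- linear_predictor(one, zero)
  t <- match(one$treatment, TREATMENTS); c <- match(one$context, CONTEXTS)
  expect_equal(eta, zero$mu[t, c])
  # a trial slope of -0.114 moves the predictor by -0.570 from trial 0 to 5
  sl <- zero
  sl$beta_trial[] <- -0.114
  two <- rbind(one, one); two$trial <- c(0L, 5L)
  eta2 <- linear_predictor(two, sl)
  expect_equal(eta2[2] - eta2[1], -0.570)
  # additivity in an individual deviation
  bump <- zero
  bump$u[one$individual_id, ] <- 1
  expect_equal(linear_predictor(one, bump), eta + 1)
  # unknown ids are lookup errors
  stranger <- one; stranger$individual_id <- "i99"
  expect_error(linear_predictor(stranger, pars), "unknown individual_id")
})

test_that("joint_loglik matches a brute-force per-record oracle", {
  tr <- make_toy(seed = 42)   # 36 records over all cells
  tr20 <- tr[seq_len(20), ]
  pars <- make_toy_pars(tr)
  expect_equal(joint_loglik(tr20, pars,
                            svl_center = mean(tr20$svl),
                            svl_scale = sd(tr20$svl)),
               oracle_joint_loglik(tr20, pars), tolerance = 1e-8)
  full <- joint_loglik(tr, pars, svl_center = mean(tr$svl),
                       svl_scale = sd(tr$svl))
  expect_equal(full, oracle_joint_loglik(tr, pars), tolerance = 1e-8)
  # invariant to record ordering
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(joint_loglik(perm, pars, svl_center = mean(tr$svl),
                            svl_scale = sd(tr$svl)), full)
  # empty record set leaves only the latent-effect terms (egg-mass terms;
  # individual terms need the record-derived treatment assignment)
  empty <- tr[0, ]
  lat <- joint_loglik(empty, pars, svl_center = 0, svl_scale = 1)
  w_terms <- sum(dnorm(pars$w, 0,
                       rep(sqrt(pars$V_eggmass), each = nrow(pars$w)),
                       log = TRUE))
  expect_equal(lat, w_terms)
  # single familiar record decomposes into data density plus latent terms
  one <- tr[tr$context == "familiar", ][1, ]
  eta <- linear_predictor(one, pars, svl_center = mean(tr$svl),
                          svl_scale = sd(tr$svl))
  t <- match(one$treatment, TREATMENTS)
  D <- diag(pars$sd_among[t, ])
  u_term <- oracle_mvn0(pars$u[one$individual_id, ],
                        D %*% pars$Omega[[t]] %*% D)
  expect_equal(joint_loglik(one, pars, svl_center = mean(tr$svl),
                            svl_scale = sd(tr$svl)),
               lognormal_logpdf(one$distance, eta, pars$sigma[t, 1]) +
                 u_term + w_terms)
  # non-positive-definite among-individual covariance is a named error
  bad <- pars
  bad$Omega[[1]] <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(joint_loglik(tr, bad), "positive definite")
})

test_that("the likelihood decreases as a residual moves away from its mean", {
  tr <- make_toy()
  pars <- make_toy_pars(tr)
  i <- which(tr$context == "familiar")[1]
  eta <- linear_predictor(tr, pars)[i]
  offsets <- c(0, 0.5, 1, 2, 4)
  lls <- sapply(offsets, function(d) {
    tr2 <- tr
    tr2$distance[i] <- exp(eta + d)
    joint_loglik(tr2, pars, svl_center = mean(tr$svl), svl_scale = sd(tr$svl))
  })
  expect_true(all(diff(lls) < 0))
})

test_that("bodysize_loglik matches its brute-force oracle and nests the
           intercept-only model", {
  tr <- make_toy(seed = 3, n_per = 2, trials_per = 3)
  size <- size_records(tr)
  ids <- unique(size$individual_id)
  eggs <- unique(size$eggmass_id)
  set.seed(9)
  pars <- list(alpha = c(5.2, 5.0, 4.2), beta_trial = 0.06,
               g = matrix(rnorm(length(ids) * 2, 0, 0.3), length(ids), 2,
                          dimnames = list(ids, NULL)),
               w = setNames(rnorm(length(eggs), 0, 0.2), eggs),
               sd_intercept = c(0.5, 0.6, 0.6),
               sd_slope = c(0.06, 0.09, 0.08),
               cor_int_slope = c(0.2, -0.1, 0),
               V_eggmass = 0.15, sigma2 = 0.04)
  expect_equal(bodysize_loglik(size, pars), oracle_bodysize_loglik(size, pars),
               tolerance = 1e-8)
  # zero latent variances with unit residual variance: plain normal sum
  flat <- pars
  flat$g <- NULL; flat$w <- NULL; flat$sigma2 <- 1
  eta <- flat$alpha[match(size$treatment, TREATMENTS)] +
    flat$beta_trial * size$trial
  expect_equal(bodysize_loglik(size, flat),
               sum(dnorm(size$svl - eta, log = TRUE)))
  # slope variance 0 (slopes at 0) equals the random-intercept-only model
  nested <- pars
  nested$g[, 2] <- 0
  nested$sd_slope <- c(0, 0, 0)
  nested$cor_int_slope <- c(0, 0, 0)
  int_only <- bodysize_loglik(size, nested)
  # manual intercept-only oracle
  ll <- 0
  for (row in seq_len(nrow(size))) {
    rec <- size[row, ]
    t <- match(rec$treatment, TREATMENTS)
    eta <- nested$alpha[t] + nested$beta_trial * rec$trial +
      nested$g[rec$individual_id, 1] + nested$w[rec$eggmass_id]
    ll <- ll + dnorm(rec$svl, eta, sqrt(nested$sigma2), log = TRUE)
  }
  ind <- unique(size[, c("individual_id", "treatment")])
  for (row in seq_len(nrow(ind))) {
    t <- match(ind$treatment[row], TREATMENTS)
    ll <- ll + dnorm(nested$g[ind$individual_id[row], 1], 0,
                     nested$sd_intercept[t], log = TRUE)
  }
  for (e in names(nested$w))
    ll <- ll + dnorm(nested$w[e], 0, sqrt(nested$V_eggmass), log = TRUE)
  expect_equal(int_only, unname(ll))
})
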