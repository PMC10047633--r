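# Independent brute-force oracles, coded naively row by row with explicit
# density formulas (no shared code with the package internals).

oracle_lognormal <- function(y, mu, sigma) {
  -log(y * sigma * sqrt(2 * pi)) - (log(y) - mu)^2 / (2 * sigma^2)
}

oracle_mvn0 <- function(x, Sigma) {
  d <- length(x)
  -0.5 * d * log(2 * pi) - 0.5 * log(det(Sigma)) -
    0.5 * as.numeric(t(x) %*% solve(Sigma) %*% x)
}

# naive per-record joint log-likelihood of the behavioural model
oracle_joint_loglik <- function(trials, pars) {
  zc <- mean(trials$svl); zs <- sd(trials$svl)
  ll <- 0
  for (row in seq_len(nrow(trials))) {
    rec <- trials[row, ]
    t <- match(rec$treatment, TREATMENTS)
    c <- match(rec$context, CONTEXTS)
    z <- (rec$svl - zc) / zs
    eta <- pars$mu[t, c] + pars$beta_trial[c] * rec$trial +
      pars$beta_svl[c] * z +
      pars$u[rec$individual_id, c] + pars$w[rec$eggmass_id, c]
    sig <- pars$sigma[t, c]
    if (c == 1L) {
      ll <- ll + oracle_lognormal(rec$distance, eta, sig)
    } else {
      p <- pars$p_hurdle[t, c]
      if (rec$distance == 0) ll <- ll + log(p)
      else ll <- ll + log(1 - p) + oracle_lognormal(rec$distance, eta, sig)
    }
  }
  ind <- unique(trials[, c("individual_id", "treatment")])
  for (row in seq_len(nrow(ind))) {
    t <- match(ind$treatment[row], TREATMENTS)
    D <- diag(pars$sd_among[t, ])
    Sigma <- D %*% pars$Omega[[t]] %*% D
    ll <- ll + oracle_mvn0(pars$u[ind$individual_id[row], ], Sigma)
  }
  for (e in rownames(pars$w)) for (c in 1:3)
    ll <- ll + dnorm(pars$w[e, c], 0, sqrt(pars$V_eggmass[c]), log = TRUE)
  ll
}

# naive body-size log-likelihood
oracle_bodysize_loglik <- function(size, pars) {
  ll <- 0
  for (row in seq_len(nrow(size))) {
    rec <- size[row, ]
    t <- match(rec$treatment, TREATMENTS)
    eta <- pars$alpha[t] + pars$beta_trial * rec$trial +
      pars$g[rec$individual_id, 1] + pars$g[rec$individual_id, 2] * rec$trial +
      pars$w[rec$eggmass_id]
    ll <- ll + dnorm(rec$svl, eta, sqrt(pars$sigma2), log = TRUE)
  }
  ind <- unique(size[, c("individual_id", "treatment")])
  for (row in seq_len(nrow(ind))) {
    t <- match(ind$treatment[row], TREATMENTS)
    s1 <- pars$sd_intercept[t]; s2 <- pars$sd_slope[t]
    rho <- pars$cor_int_slope[t]
    Sigma <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
    ll <- ll + oracle_mvn0(pars$g[ind$individual_id[row], ], Sigma)
  }
  for (e in names(pars$w))
    ll <- ll + dnorm(pars$w[e], 0, sqrt(pars$V_eggmass), log = TRUE)
  unname(ll)
}

# exhaustive shortest-window HPDI search
oracle_hpdi <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(x[1], x[n]); bw <- Inf
  for (j in 1:(n - m + 1)) {
    wdt <- x[j + m - 1] - x[j]
    if (wdt < bw) { bw <- wdt; best <- c(x[j], x[j + m - 1]) }
  }
  best
}

# a small, fully populated toy dataset with known latent structure
make_toy <- function(seed = 42, n_per = 2, trials_per = 2) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(3 * n_per))
  treat <- rep(TREATMENTS, each = n_per)
  eggs <- rep(c("e1", "e2"), length.out = 3 * n_per)
  rows <- expand.grid(ind = seq_along(ids), context = CONTEXTS,
                      trial = seq_len(trials_per) - 1L,
                      stringsAsFactors = FALSE)
  dist <- exp(rnorm(nrow(rows), 6, 1))
  # plant some exact zeros outside the familiar context
  nonfam <- which(rows$context != "familiar")
  dist[sample(nonfam, length(nonfam) %/% 3)] <- 0
  data.frame(individual_id = ids[rows$ind], eggmass_id = eggs[rows$ind],
             treatment = treat[rows$ind], context = rows$context,
             trial = rows$trial, distance = dist,
             svl = round(runif(nrow(rows), 4, 6), 1),
             stringsAsFactors = FALSE)
}

# random parameter set matching a toy dataset's individuals and egg masses
make_toy_pars <- function(trials, seed = 7) {
  set.seed(seed)
  ids <- unique(trials$individual_id)
  eggs <- unique(trials$eggmass_id)
  Omega <- lapply(1:3, function(t) {
    r <- runif(1, -0.3, 0.3)
    m <- diag(3); m[1, 2] <- m[2, 1] <- r
    m
  })
  list(
    mu = matrix(rnorm(9, 6, 0.5), 3, 3,
                dimnames = list(TREATMENTS, CONTEXTS)),
    beta_trial = rnorm(3, -0.1, 0.05),
    beta_svl = rnorm(3, 0, 0.1),
    u = matrix(rnorm(length(ids) * 3, 0, 0.4), length(ids), 3,
               dimnames = list(ids, CONTEXTS)),
    w = matrix(rnorm(length(eggs) * 3, 0, 0.2), length(eggs), 3,
               dimnames = list(eggs, CONTEXTS)),
    sd_among = matrix(runif(9, 0.2, 0.8), 3, 3,
                      dimnames = list(TREATMENTS, CONTEXTS)),
    Omega = Omega,
    V_eggmass = runif(3, 0.05, 0.3),
    sigma = matrix(runif(9, 0.8, 1.5), 3, 3,
                   dimnames = list(TREATMENTS, CONTEXTS)),
    p_hurdle = matrix(c(0, 0, 0, runif(6, 0.2, 0.7)), 3, 3,
                      dimnames = list(TREATMENTS, CONTEXTS))
  )
}
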