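test_that("single-seizure log posterior decomposes per observation", {
  set.seed(14)
  W <- generate_network(8, 0.5, seed = 2)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0.25, seed = 3)
  obs <- gs$obs
  c0 <- rnorm(8)
  lp <- log_posterior_single(c0, obs, W, q)
  # a non-seizing region whose simulated onset exceeds t_lim contributes
  # the maximal Gaussian term -log(sigma sqrt(2 pi))
  con <- model_constants()
  t_sim <- simulate_onsets(W, q, c0, t_max = con$t_lim)
  ns <- which(obs$status == "non-seizing" & t_sim >= con$t_lim)
  if (length(ns)) {
    obs2 <- obs
    obs2$status[ns[1]] <- "hidden"; obs2$onset_s[ns[1]] <- NA
    expect_equal(lp - log_posterior_single(c0, obs2, W, q),
                 -log(con$sigma_t * sqrt(2 * pi)))
  }
  # no observations: prior only
  obs_prior <- seizure_observation(region_ids(W), rep("hidden", 8),
                                   rep(NA_real_, 8))
  expect_equal(log_posterior_single(c0, obs_prior, W, q),
               sum(dnorm(c0, log = TRUE)))
  # shifting one observed onset changes only that Gaussian term
  sz <- which(obs$status == "seizing")[1]
  obs3 <- obs
  obs3$onset_s[sz] <- obs3$onset_s[sz] + 1
  m <- min(t_sim[sz], con$t_lim)
  delta_expected <-
    dnorm(obs3$onset_s[sz], m, con$sigma_t, log = TRUE) -
    dnorm(obs$onset_s[sz], m, con$sigma_t, log = TRUE)
  expect_equal(log_posterior_single(c0, obs3, W, q) - lp, delta_expected)
  expect_equal(log_posterior_single(c(c0[-8], NaN), obs, W, q), -Inf)
})

test_that("analytic gradients match finite differences", {
  set.seed(15)
  W <- generate_network(10, 0.4, seed = 6)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0.3, seed = 8)
  for (rep in 1:20) {
    c0 <- rnorm(10)
    r <- log_posterior_single(c0, gs$obs, W, q, gradient = TRUE)
    fd <- vapply(1:10, function(i) {
      e <- rep(0, 10); e[i] <- 1e-5
      (log_posterior_single(c0 + e, gs$obs, W, q) -
         log_posterior_single(c0 - e, gs$obs, W, q)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(r$grad_c - fd) / pmax(abs(fd), 1)), 1e-4)
  }
})

test_that("multi-seizure posterior reduces and adds up correctly", {
  set.seed(16)
  W <- generate_network(8, 0.5, seed = 21)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0.25, seed = 22)
  d1 <- list(list(obs = gs$obs, W = W))
  c1 <- rnorm(8)
  con <- model_constants()
  qv <- c(-6, -2.5, 3, 5)
  hyper <- sum(dnorm(qv[1:2], 0, con$sigma_q, log = TRUE)) +
    sum(dnorm(qv[3:4], 0, con$sigma_q, log = TRUE) + log(2))
  # one-seizure cohort = single-seizure posterior + hyperprior
  expect_equal(log_posterior_multi(qv, list(c1), d1),
               hyper + log_posterior_single(c1, gs$obs, W, q))
  # duplicating a seizure doubles its data contribution
  d2 <- list(d1[[1]], d1[[1]])
  expect_equal(log_posterior_multi(qv, list(c1, c1), d2) - hyper,
               2 * (log_posterior_single(c1, gs$obs, W, q)))
  # support constraint
  expect_identical(log_posterior_multi(c(0, 0, -1, 0), list(c1), d1), -Inf)
})

test_that("prior-only sampling recovers standard-normal marginals", {
  W <- generate_network(10, 0.4, seed = 31)
  obs <- seizure_observation(region_ids(W), rep("hidden", 10),
                             rep(NA_real_, 10))
  fit <- fit_seizure(obs, W, q_star(), chains = 2, seed = 77)
  s <- summary(fit)
  expect_lt(max(abs(s$mean)), 0.15)
  expect_lt(max(abs(s$sd - 1)), 0.15)
  expect_true(all(s$rhat < 1.1))
  expect_true(all(s$n_eff > 30))
})

test_that("posterior matches exact inversion on a noiseless seizure", {
  W <- generate_network(10, 0.5, seed = 41)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0, noise_sd = 0, seed = 42)
  fit <- fit_seizure(gs$obs, W, q, chains = 2, seed = 43)
  post_mean <- coef(fit)
  post_sd <- summary(fit)$sd
  sz <- gs$obs$status == "seizing"
  c_exact <- gs$c_true  # noiseless generation: truth is the inversion
  expect_true(all(abs(post_mean[sz] - c_exact[sz]) <= 3 * post_sd[sz]))
})

test_that("well-posed synthetic fits converge by the standard thresholds", {
  W <- generate_network(12, 0.4, seed = 51)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0.25, seed = 52)
  fit <- fit_seizure(gs$obs, W, q, chains = 2, seed = 53)
  ok <- fit$diagnostics$rhat < 1.1 & fit$diagnostics$n_eff > 30
  expect_gte(mean(ok), 0.99)
})

test_that("the gradient-free fallback sampler agrees on a tiny network", {
  W <- generate_network(4, 0.8, seed = 61)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0, seed = 62)
  f1 <- fit_seizure(gs$obs, W, q, chains = 2, seed = 63)
  f2 <- fit_seizure(gs$obs, W, q, chains = 2, seed = 63, method = "rwm",
                    warmup = 2000, draws = 2000)
  m1 <- coef(f1); m2 <- coef(f2)
  s1 <- summary(f1)$sd
  expect_true(all(abs(m1 - m2) < pmax(0.5 * s1, 0.2)))
})

test_that("diagnostics flag stuck chains and compute sane R-hat / ESS", {
  # identical constant chains: stuck, R-hat undefined
  draws <- array(1, c(100, 2, 1))
  lp <- matrix(1, 100, 2)
  d <- mcmc_diagnostics(draws, lp)
  expect_true(all(d$stuck)); expect_true(d$all_stuck)
  expect_true(is.nan(d$rhat[1]))
  # iid standard normal chains: R-hat near 1, ESS below the cap
  set.seed(99)
  draws <- array(rnorm(500 * 4 * 3), c(500, 4, 3))
  lp <- matrix(rnorm(500 * 4), 500, 4)
  d <- mcmc_diagnostics(draws, lp)
  expect_true(all(d$rhat > 0.99 & d$rhat < 1.02))
  expect_true(all(d$n_eff <= 2000 + 1e-9))
  expect_false(any(d$stuck))
  # duplicated chain pair cannot exceed the total draw count
  half <- matrix(rnorm(500), 500, 1)
  dup <- array(cbind(half, half), c(500, 2, 1))
  d2 <- mcmc_diagnostics(dup, cbind(lp[, 1], lp[, 1]))
  expect_lte(d2$n_eff[1], 1000)
  expect_error(mcmc_diagnostics(array(rnorm(100), c(100, 1, 1)),
                                matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("recruitment probability is a proper CDF estimate", {
  set.seed(71)
  draws <- matrix(rexp(2000, rate = 1 / 30), 500, 4)
  colnames(draws) <- paste0("R", 1:4)
  r <- recruitment_probability(draws, times = seq(0, 200, by = 5))
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(apply(r, 2, function(x) all(diff(x) >= 0))))
  expect_equal(unname(r[1, ]), rep(0, 4))
  # r at the median posterior onset is about one half
  med <- apply(draws, 2, median)
  at_med <- vapply(1:4, function(j)
    mean(draws[, j] <= med[j]), numeric(1))
  expect_true(all(abs(at_med - 0.5) < 0.01))
})

test_that("high-excitability probability matches the normal tail", {
  set.seed(81)
  draws <- matrix(rnorm(1000 * 162), 1000, 162)
  p <- high_excitability_probability(draws, c_h = 2)
  expect_true(all(p >= 0 & p <= 1))
  # expected count over 162 prior regions
  expect_equal(sum(p), 162 * (1 - pnorm(2)), tolerance = 0.25)
  expect_equal(unname(high_excitability_probability(
    matrix(c(0, 1, 1.9), 3, 1), 2)), 0)
})

test_that("posterior predictive ensembles are reproducible and consistent", {
  W <- list(generate_network(10, 0.4, seed = 91))
  q <- q_star()
  e1 <- posterior_predictive_ensemble(q, W, n_seizures = 5, n_reps = 20,
                                      seed = 7)
  e2 <- posterior_predictive_ensemble(q, W, n_seizures = 5, n_reps = 20,
                                      seed = 7)
  expect_identical(e1$stats, e2$stats)
  # subsample envelopes contain the overall mean fraction
  m <- mean(e1$per_rep$frac_seizing)
  expect_gte(m, e1$envelope["5%", "frac_seizing"] - 1e-9)
  expect_lte(m, e1$envelope["95%", "frac_seizing"] + 1e-9)
  # saturating parameters recruit everything
  qs <- excitation_params(3, 3, 1, 1)
  es <- posterior_predictive_ensemble(qs, W, n_seizures = 3, n_reps = 5,
                                      seed = 8)
  expect_true(all(es$stats$frac_seizing == 1))
})
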