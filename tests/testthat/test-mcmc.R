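test_that("log prior is maximal at P0, truncated at zero, Gaussian in shape", {
  cfg <- mcmc_config(P0 = c(a = 1, b = 1), N = 10, prior_rel_sd = 0.6)
  at_mode <- log_prior(c(1, 1), cfg)
  expect_equal(at_mode, sum(dnorm(c(1, 1), c(1, 1), 0.6, log = TRUE)))
  # one prior-sd displacement costs exactly 1/2
  expect_equal(log_prior(c(1.6, 1), cfg) - at_mode, -0.5)
  expect_identical(log_prior(c(-0.1, 1), cfg), -Inf)
  expect_identical(log_prior(c(0, 1), cfg), -Inf)
  expect_error(log_prior(c(1, 1, 1), cfg), "dimension")
})

test_that("log likelihood has the Gaussian closed form and skips missing cells", {
  p <- lc_params()
  cond <- scenario("LC")
  ds <- generate_dataset("model1", p, cond, noise_sd = 1e-12, seed = 5)
  ds$noise_sd <- 1
  n <- length(ds$observations)
  ll0 <- log_likelihood(p, ds, "model1", cond, noise_sd = 1)
  expect_equal(ll0, -n * log(sqrt(2 * pi)), tolerance = 1e-6)
  # perturbing one observation by one error-sd costs exactly 1/2
  ds2 <- ds
  ds2$observations[4, 2] <- ds2$observations[4, 2] + 1
  expect_equal(log_likelihood(p, ds2, "model1", cond, noise_sd = 1) - ll0,
               -0.5, tolerance = 1e-6)
  # missing cells contribute nothing
  ds3 <- ds
  ds3$observations[2, ] <- NA
  expect_equal(log_likelihood(p, ds3, "model1", cond, noise_sd = 1),
               -(n - 4) * log(sqrt(2 * pi)), tolerance = 1e-6)
  # flat likelihood for an empty dataset
  expect_identical(log_likelihood(p, empty_dataset(), "model1", cond, 1), 0)
})

test_that("the proposal is a symmetric random walk scaled by w * P0", {
  P0 <- c(2, 0.5, 10)
  expect_identical(propose_params(P0, 0, P0), P0)
  set.seed(4)
  n <- 1e4
  draws <- t(replicate(n, propose_params(P0, 0.1, P0)))
  step <- sweep(draws, 2, P0)
  expect_true(all(abs(colMeans(step)) < 3 * 0.1 * P0 / sqrt(n)))
  expect_equal(unname(apply(step, 2, sd)), 0.1 * P0, tolerance = 0.05)
})

test_that("under a flat likelihood the sampler recovers the truncated prior", {
  P0 <- setNames(as.numeric(lc_params())[1:3], names(lc_params())[1:3])
  cfg <- mcmc_config(P0 = P0, N = 5e4, w = 0.5, prior_rel_sd = 0.6,
                     noise_sd = 1, seed = 42)
  chain <- run_mcmc("model1", empty_dataset(), scenario("LC"), cfg)
  expect_gt(chain$acceptance_rate, 0.1)
  # positive-truncated Gaussian with mean mu, sd 0.6*mu: the truncation
  # point sits at 5/3 sd below the mode, inflating the mean slightly
  z <- 1 / 0.6
  infl <- dnorm(z) / pnorm(z)
  for (j in 1:3) {
    x <- chain$samples[, j]
    mc_se <- sd(x) / sqrt(amoxkin:::ess(x))
    expect_lt(abs(mean(x) - P0[[j]] * (1 + 0.6 * infl)), 3 * mc_se)
    expect_equal(sd(x), 0.6 * P0[[j]] * sqrt(1 - z * infl - infl^2),
                 tolerance = 0.1)
  }
})

test_that("chain summaries are insensitive to the burn-in choice beyond 20%", {
  P0 <- c(K = 1)
  base <- list(P0 = P0, N = 4e4, w = 0.5, noise_sd = 1, seed = 9)
  c20 <- run_mcmc("model1", empty_dataset(), scenario("LC"),
                  do.call(mcmc_config, c(base, burn_in_frac = 0.2)))
  c50 <- run_mcmc("model1", empty_dataset(), scenario("LC"),
                  do.call(mcmc_config, c(base, burn_in_frac = 0.5)))
  x <- c20$samples[, 1]
  mc_se <- sd(x) / sqrt(amoxkin:::ess(x))
  expect_lt(abs(mean(x) - mean(c50$samples[, 1])), 3 * mc_se)
})

test_that("degenerate moves and seeds behave as contracts require", {
  P0 <- c(a = 1, b = 2)
  cfg <- mcmc_config(P0 = P0, N = 200, w = 0, noise_sd = 1, seed = 2)
  chain <- run_mcmc("model1", empty_dataset(), scenario("LC"), cfg)
  expect_equal(chain$acceptance_rate, 1)   # null moves always accepted
  cfg2 <- mcmc_config(P0 = P0, N = 500, w = 0.3, noise_sd = 1, seed = 6)
  a <- run_mcmc("model1", empty_dataset(), scenario("LC"), cfg2)
  b <- run_mcmc("model1", empty_dataset(), scenario("LC"), cfg2)
  expect_identical(a$samples, b$samples)
  expect_identical(a$acceptance_rate, b$acceptance_rate)
})

test_that("credible intervals match the Gaussian quantile oracle", {
  set.seed(8)
  draws <- matrix(rnorm(1e5), ncol = 1)
  ci <- credible_interval(draws, level = 0.99)
  expect_lt(abs(ci[1, "lower"] + 2.576), 0.05)
  expect_lt(abs(ci[1, "upper"] - 2.576), 0.05)
  # nesting and degenerate cases
  const <- matrix(rep(3.2, 100), ncol = 1)
  expect_equal(unname(credible_interval(const, 0.99)[1, ]), c(3.2, 3.2))
  expect_error(credible_interval(draws, level = 0), "level")
  expect_error(credible_interval(draws[0, , drop = FALSE], 0.99), "empty")
})

test_that("posterior summaries are means plus quantile intervals, order-invariant", {
  P0 <- c(a = 1, b = 2)
  cfg <- mcmc_config(P0 = P0, N = 2000, w = 0.5, noise_sd = 1, seed = 3)
  chain <- run_mcmc("model1", empty_dataset(), scenario("LC"), cfg)
  s <- posterior_summary(chain)
  expect_equal(unname(s$estimates), unname(colMeans(chain$samples)))
  perm <- chain
  perm$samples <- perm$samples[rev(seq_len(nrow(perm$samples))), ]
  s2 <- posterior_summary(perm)
  expect_equal(s$estimates, s2$estimates)
  expect_equal(s$ci, s2$ci)
  const_chain <- chain
  const_chain$samples <- matrix(rep(c(1, 2), each = 50), ncol = 2,
                                dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(posterior_summary(const_chain)$estimates), c(1, 2))
})

test_that("LC data are informative: the posterior contracts below the prior", {
  ds <- make_lc_dataset(seed = 21)
  cfg <- mcmc_config(P0 = lc_params(), N = 4000, w = 0.05, seed = 21)
  chain <- run_mcmc("model1", ds, scenario("LC"), cfg)
  post_sd <- sd(chain$samples[, "Kcat1"])
  expect_lt(post_sd, 0.6 * lc_params()[["Kcat1"]])
})

test_that("chains export with canonical columns and a config sidecar", {
  cfg <- mcmc_config(P0 = c(a = 1, b = 2), N = 100, w = 0.5, noise_sd = 1,
                     seed = 4)
  chain <- run_mcmc("model1", empty_dataset(), scenario("LC"), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chain(chain, path)
  df <- read.csv(path)
  expect_equal(names(df), c("a", "b", "log_posterior"))
  expect_equal(nrow(df), nrow(chain$samples))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$N, 100)
  expect_equal(side$seed, 4)
})
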