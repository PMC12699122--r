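test_that("zero feed reproduces the batch prediction", {
  p <- lc_params()
  cond_sb <- reactor_conditions(2.5, "iu_per_mL", c(80, 0, 60, 0),
                                mode = "semibatch",
                                feed = feed_schedule(0, 0, 0), t_end = 240)
  tt <- seq(0, 240, 40)
  a <- predict_semibatch("model1", p, cond_sb, t_eval = tt)
  b <- simulate_reactor("model1", p, scenario("LC"), t_eval = tt)
  expect_equal(a$states, b$states, tolerance = 1e-9)
  expect_error(predict_semibatch("model1", p, scenario("LC")), "semibatch")
})

test_that("moiety sums grow exactly by the integrated feed", {
  cond <- semibatch_scenario()
  tt <- c(0, 60, 120, 200, 400)
  tr <- predict_semibatch("model1", lc_params(), cond, t_eval = tt)
  fed <- pmin(tt, 120) * 0.2    # quadrature of the step feed
  ester <- rowSums(tr$states[, c("C_AB", "C_AN", "C_AOH")])
  nucleus <- rowSums(tr$states[, c("C_AN", "C_NH")])
  expect_equal(ester, 80 + fed, tolerance = 1e-6)
  expect_equal(nucleus, 60 + fed, tolerance = 1e-6)
})

test_that("feeding more 6-APA does not reduce cumulative synthesis flux", {
  p <- lc_params()
  synth_integral <- function(fnh_rate) {
    feed <- feed_schedule(c(0, 120), fab = c(0.2, 0), fnh = c(fnh_rate, 0))
    cond <- reactor_conditions(2.5, "iu_per_mL", c(80, 0, 60, 0),
                               mode = "semibatch", feed = feed, t_end = 400)
    tr <- simulate_reactor("model1", p, cond)
    vS <- apply(tr$states, 1, function(s) rates_model1(pmax(s, 0), p, 2.5)[["vS"]])
    sum(diff(tr$times) * (head(vS, -1) + tail(vS, -1)) / 2)
  }
  expect_gte(synth_integral(0.4), synth_integral(0.2) - 1e-6)
})

test_that("parameters calibrated on batch data transfer to semi-batch prediction", {
  ds <- make_lc_dataset(seed = 81)
  cfg <- mcmc_config(P0 = lc_params(), N = 1500, w = 0.05, seed = 81)
  chain <- run_mcmc("model1", ds, scenario("LC"), cfg)
  fit <- posterior_summary(chain)
  cond_sb <- semibatch_scenario()
  sb_data <- generate_dataset("model1", lc_params(), cond_sb,
                              n_points = 13, noise_sd = 1, seed = 82)
  sc <- evaluate_fit(sb_data, "model1", fit$estimates, cond_sb)
  truth <- simulate_reactor("model1", lc_params(), cond_sb,
                            t_eval = sb_data$times)$states
  noise_floor <- 100 * 1.0 / colMeans(truth)
  expect_true(all(sc$per_variable < 2 * noise_floor))
})

test_that("predictive bands nest, degenerate correctly, and cover the truth", {
  ds <- make_lc_dataset(seed = 91)
  cfg <- mcmc_config(P0 = lc_params(), N = 1200, w = 0.05, seed = 91)
  chain <- run_mcmc("model1", ds, scenario("LC"), cfg)
  tt <- seq(0, 240, 30)
  b99 <- predictive_band("model1", chain, scenario("LC"), t_eval = tt,
                         level = 0.99, n_draws = 120)
  b90 <- predictive_band("model1", chain, scenario("LC"), t_eval = tt,
                         level = 0.90, n_draws = 120)
  expect_true(all(b99$lower <= b90$lower + 1e-9))
  expect_true(all(b99$upper >= b90$upper - 1e-9))
  # constant chain: zero-width band at that trajectory
  const <- chain
  const$samples <- matrix(rep(as.numeric(lc_params()), each = 50), nrow = 50,
                          dimnames = list(NULL, names(lc_params())))
  bc <- predictive_band("model1", const, scenario("LC"), t_eval = tt,
                        n_draws = 10)
  tr <- simulate_reactor("model1", lc_params(), scenario("LC"), t_eval = tt)
  expect_equal(bc$lower, bc$upper, tolerance = 1e-10)
  expect_equal(unname(bc$lower), unname(tr$states), tolerance = 1e-8)
  expect_error(predictive_band("model1", chain, scenario("LC"), level = 1),
               "level")
})

test_that("the 99% semi-batch band covers nearly all noiseless truth points", {
  cond_sb <- semibatch_scenario()
  tt <- seq(0, 400, 20)
  truth <- simulate_reactor("model1", lc_params(), cond_sb,
                            t_eval = tt)$states
  inside <- 0L; total <- 0L
  for (s in 1:10) {
    ds <- make_lc_dataset(seed = 900 + s)
    cfg <- mcmc_config(P0 = lc_params(), N = 3000, w = 0.05, seed = 900 + s)
    chain <- run_mcmc("model1", ds, scenario("LC"), cfg)
    band <- predictive_band("model1", chain, cond_sb, t_eval = tt,
                            level = 0.99, n_draws = 200)
    ok <- truth >= band$lower - 1e-9 & truth <= band$upper + 1e-9
    inside <- inside + sum(ok); total <- total + length(ok)
  }
  expect_gte(inside / total, 0.95)
})

test_that("mM / g/L conversion uses the molar masses and round-trips", {
  tr <- simulate_reactor("model1", lc_params(), scenario("LC"),
                         t_eval = c(0, 120, 240))
  g <- to_mass_units(tr)
  expect_equal(g$unit, "g_per_L")
  expect_equal(unname(g$states[1, "C_AB"]), 80 * 181.19 / 1000)
  expect_equal(unname(g$states[1, "C_AN"]), 0)
  # 10 mM amoxicillin is 3.654 g/L
  tr2 <- tr; tr2$states[1, "C_AN"] <- 10
  expect_equal(unname(to_mass_units(tr2)$states[1, "C_AN"]), 3.654)
  back <- to_molar_units(g)
  expect_equal(back$states, tr$states, tolerance = 1e-9)
  expect_error(to_molar_units(back), "already")
  ds <- make_lc_dataset(seed = 2, n_points = 5)
  dsg <- to_mass_units(ds)
  expect_equal(dsg$observations[, "C_NH"],
               ds$observations[, "C_NH"] * 216.26 / 1000)
})
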