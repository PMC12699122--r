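# Shared fixtures: reference parameter sets, a fixed-step RK4 integrator
# used as an independent oracle for the adaptive solver, and small
# dataset builders.

lc_params <- function() ref_params_model1("lc_mcmc")
hc_ga_params <- function() ref_params_model1("hc_ga")
m2_params <- function() ref_params_model2()

# Classical fixed-step RK4 on the package's R-level right-hand sides;
# independent of the deSolve integration path.
rk4_integrate <- function(model, p, cez, y0, t_out, h = 0.01) {
  rhs <- switch(model,
                model1 = function(y) unname(rhs_model1_batch(pmax(y, 0), p, cez)),
                model2 = function(y) unname(rhs_model2_batch(pmax(y, 0), p, cez)))
  y <- as.numeric(y0)
  t <- 0
  out <- matrix(NA_real_, length(t_out), 4)
  for (i in seq_along(t_out)) {
    while (t < t_out[i] - 1e-12) {
      step <- min(h, t_out[i] - t)
      k1 <- rhs(y)
      k2 <- rhs(y + step / 2 * k1)
      k3 <- rhs(y + step / 2 * k2)
      k4 <- rhs(y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- y
  }
  colnames(out) <- c("C_AB", "C_AN", "C_NH", "C_AOH")
  out
}

# Random positive parameter vectors for property loops.
random_params <- function(model, rng_scale = 1) {
  base <- if (model == "model1") lc_params() else m2_params()
  p <- as.numeric(base) * exp(stats::runif(length(base), -rng_scale, rng_scale))
  if (model == "model1") p[5] <- min(p[5], 1)
  stats::setNames(p, param_names(model))
}

random_state <- function() stats::runif(4, 0, 120)

empty_dataset <- function(noise_sd = 1) {
  structure(list(times = numeric(0),
                 observations = NULL,
                 noise_sd = noise_sd, provenance = list()),
            class = "amox_dataset")
}

make_lc_dataset <- function(seed, noise_sd = 1, n_points = 13) {
  generate_dataset("model1", lc_params(), scenario("LC"),
                   n_points = n_points, noise_sd = noise_sd, seed = seed)
}
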