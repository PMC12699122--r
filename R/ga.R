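#' Configuration of the real-coded genetic algorithm
#'
#' @param lb,ub Per-parameter lower/upper bounds; `0 < lb < ub`
#'   componentwise.
#' @param Ps Population size, `>= 4` (default 100).
#' @param G Generation count (default `1e4`).
#' @param crossover_rate Fraction of offspring pairs produced by scattered
#'   crossover (default 0.90); the remainder are cloned from their parents.
#' @param mutation_rate Per-gene probability of uniform resampling within
#'   bounds (default 0.10).
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (default 2); guarantees a monotone best fitness.
#' @param seed Integer seed.
#' @return Object of class `amox_ga_config`.
#' @export
ga_config <- function(lb, ub, Ps = 100, G = 1e4, crossover_rate = 0.90,
                      mutation_rate = 0.10, elitism = 2, seed = NULL) {
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != length(ub)) stop("lb and ub must have equal length")
  if (any(!is.finite(lb)) || any(lb <= 0)) stop("lb must be positive")
  if (any(lb >= ub)) stop("lb must be strictly below ub")
  if (Ps < 4) stop("population size must be at least 4")
  if (G < 1) stop("generation count must be at least 1")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop("rates must lie in [0, 1]")
  if (elitism < 0 || elitism >= Ps) stop("elitism must lie in [0, Ps)")
  structure(list(lb = lb, ub = ub, Ps = as.integer(Ps), G = as.integer(G),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), seed = seed),
            class = "amox_ga_config")
}

#' Default GA search bounds around a reference estimate
#'
#' @param center Reference parameter vector (defaults to the literature
#'   initial estimates for the model).
#' @param model Model id, used when `center` is missing.
#' @param factor Half-decade factor: bounds are
#'   `[center / factor, center * factor]` (default 10).
#' @return List with `lb` and `ub`.
#' @export
default_bounds <- function(center = NULL, model = "model1", factor = 10) {
  if (is.null(center))
    center <- switch(model, model1 = ref_params_model1("goncalves"),
                     model2 = ref_params_model2())
  list(lb = as.numeric(center) / factor, ub = as.numeric(center) * factor)
}

#' Data-model deviation objective for the GA
#'
#' Sum over the four state variables of the relative root-mean-squared
#' error (as a fraction, not percent) between the observations and the
#' simulated trajectory at `P`. A failed integration is penalized with
#' `+Inf`.
#'
#' @param P Parameter vector.
#' @param dataset `amox_dataset`.
#' @param model `"model1"` or `"model2"`.
#' @param conditions `amox_conditions`.
#' @return Nonnegative scalar (Inf on simulation failure).
#' @export
ga_fitness <- function(P, dataset, model, conditions) {
  traj <- try(simulate_reactor(model, P, conditions, t_eval = dataset$times),
              silent = TRUE)
  if (inherits(traj, "try-error")) return(Inf)
  f <- sum(vapply(seq_len(4), function(j)
    rrmse(dataset$observations[, j], traj$states[, j]), numeric(1))) / 100
  if (!is.finite(f)) Inf else f
}

#' Initial GA population
#'
#' Each gene drawn uniformly within its bounds.
#'
#' @param config `amox_ga_config`.
#' @param use_seed Set the config seed before drawing (default `TRUE`;
#'   [run_ga()] seeds once itself and passes `FALSE`).
#' @return `Ps x d` matrix of individuals.
#' @export
init_population <- function(config, use_seed = TRUE) {
  draw <- function() {
    d <- length(config$lb)
    t(replicate(config$Ps,
                config$lb + runif(d) * (config$ub - config$lb)))
  }
  if (use_seed) with_seed(config$seed, draw()) else draw()
}

#' Roulette-wheel parent selection under minimization
#'
#' The objective is a deviation to be minimized, so selection probability
#' is proportional to `(f_worst - f) + delta` with `f_worst` the worst
#' finite fitness and `delta = 1e-12`; infeasible (infinite) individuals
#' get weight `delta`. Returns `n` indices sampled with replacement.
#'
#' @param fitnesses Numeric vector of fitness values.
#' @param n Pool size (default `length(fitnesses)`).
#' @return Integer vector of selected indices.
#' @export
select_roulette <- function(fitnesses, n = length(fitnesses)) {
  finite <- is.finite(fitnesses)
  if (!any(finite)) stop("all fitnesses are infinite; nothing selectable")
  delta <- 1e-12
  f_worst <- max(fitnesses[finite])
  w <- rep(delta, length(fitnesses))
  w[finite] <- (f_worst - fitnesses[finite]) + delta
  sample.int(length(fitnesses), n, replace = TRUE, prob = w)
}

#' Scattered (uniform) crossover
#'
#' A random binary mask decides, gene by gene, which parent each offspring
#' gene is inherited from (Bernoulli(0.5) per gene), so offspring stay
#' within bounds automatically.
#'
#' @param parent_a,parent_b Numeric vectors of equal length.
#' @return Offspring vector.
#' @export
crossover_scattered <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b))
    stop("parents must have equal dimension")
  mask <- runif(length(parent_a)) < 0.5
  ifelse(mask, parent_a, parent_b)
}

#' Uniform-resampling mutation
#'
#' Each gene is independently replaced, with probability
#' `config$mutation_rate`, by a fresh uniform draw within its bounds.
#'
#' @param x Individual (numeric vector within bounds).
#' @param config `amox_ga_config`.
#' @return Mutated individual, always within bounds.
#' @export
mutate_genes <- function(x, config) {
  hit <- runif(length(x)) < config$mutation_rate
  if (any(hit))
    x[hit] <- config$lb[hit] + runif(sum(hit)) * (config$ub - config$lb)[hit]
  x
}

#' Run the genetic algorithm on an arbitrary objective
#'
#' Generational loop: roulette selection, scattered crossover on a fraction
#' `crossover_rate` of parent pairs (the rest cloned), per-gene uniform
#' mutation, and elitism. The best-so-far fitness is recorded each
#' generation and is non-increasing by construction.
#'
#' @param objective Function mapping a parameter vector to a scalar to be
#'   minimized (`Inf` allowed as a penalty).
#' @param config `amox_ga_config`.
#' @return Object of class `amox_ga`: list with `best_params`,
#'   `best_fitness`, `fitness_history`, `config`.
#' @export
run_ga <- function(objective, config) {
  with_seed(config$seed, {
    d <- length(config$lb)
    Ps <- config$Ps
    pop <- init_population(config, use_seed = FALSE)
    fit <- apply(pop, 1, objective)
    best_idx <- which.min(fit)
    best_x <- pop[best_idx, ]
    best_f <- fit[best_idx]
    history <- numeric(config$G)
    for (g in seq_len(config$G)) {
      ord <- order(fit)
      n_el <- config$elitism
      elites <- pop[ord[seq_len(n_el)], , drop = FALSE]
      elite_fit <- fit[ord[seq_len(n_el)]]
      parents <- select_roulette(fit)
      n_off <- Ps - n_el
      offspring <- matrix(NA_real_, n_off, d)
      i <- 1L
      while (i <= n_off) {
        pa <- pop[parents[i], ]
        pb <- pop[parents[if (i < n_off) i + 1L else 1L], ]
        if (runif(1) < config$crossover_rate) {
          offspring[i, ] <- crossover_scattered(pa, pb)
          if (i + 1L <= n_off) offspring[i + 1L, ] <- crossover_scattered(pa, pb)
        } else {
          offspring[i, ] <- pa
          if (i + 1L <= n_off) offspring[i + 1L, ] <- pb
        }
        i <- i + 2L
      }
      offspring <- t(apply(offspring, 1, mutate_genes, config = config))
      off_fit <- apply(offspring, 1, objective)
      pop <- rbind(elites, offspring)
      fit <- c(elite_fit, off_fit)
      gen_best <- which.min(fit)
      if (fit[gen_best] < best_f) {
        best_f <- fit[gen_best]
        best_x <- pop[gen_best, ]
      }
      history[g] <- best_f
    }
    structure(list(best_params = best_x, best_fitness = best_f,
                   fitness_history = history, config = config),
              class = "amox_ga")
  })
}

#' Fit a kinetic model to a dataset with the genetic algorithm
#'
#' Wraps [run_ga()] with the rRMSE-sum objective [ga_fitness()] and labels
#' the result with parameter names. For model 1 the search space is
#' intersected with the physical feasibility region: `Tmax` is the fraction
#' of acyl-enzyme-nucleus complex converted to product, so its upper bound
#' is capped at 1. Without the cap, `Tmax` and `KEN` trade off along a
#' ridge (`Tmax * C_NH / (KEN + C_NH)` is what the data constrain) and the
#' returned `Tmax` can wander far above its physical range at equal
#' fitness.
#'
#' @param model `"model1"` or `"model2"`.
#' @param dataset `amox_dataset`.
#' @param conditions `amox_conditions`.
#' @param config `amox_ga_config` with bounds of the model's dimension.
#' @return Object of class `amox_fit` with the GA result attached as
#'   attribute `ga`.
#' @export
fit_ga <- function(model, dataset, conditions, config) {
  model <- match.arg(model, c("model1", "model2"))
  nm <- param_names(model)
  if (length(config$lb) != length(nm))
    stop("bounds dimension does not match ", model)
  if (model == "model1") {
    j <- match("Tmax", nm)
    if (config$lb[j] >= 1) stop("lower bound for Tmax must be below 1")
    config$ub[j] <- min(config$ub[j], 1)
  }
  res <- run_ga(function(P) ga_fitness(P, dataset, model, conditions),
                config)
  fit <- structure(list(estimates = setNames(res$best_params, nm),
                        ci = NULL, sd = NULL, acceptance_rate = NULL,
                        method = "GA", model = model,
                        best_fitness = res$best_fitness),
                   class = "amox_fit")
  attr(fit, "ga") <- res
  fit
}

#' @export
print.amox_ga <- function(x, ...) {
  cat("GA result: best fitness ", format(x$best_fitness), " after ",
      x$config$G, " generations (Ps = ", x$config$Ps, ")\n", sep = "")
  invisible(x)
}

#' Export a GA result: best parameters and fitness history
#'
#' @param result `amox_ga` or `amox_fit` from [fit_ga()].
#' @param path Output file (delimited text); config echoed to
#'   `<path>.json`.
#' @export
write_ga_result <- function(result, path) {
  if (inherits(result, "amox_fit")) result <- attr(result, "ga")
  df <- data.frame(generation = seq_along(result$fitness_history),
                   best_fitness = result$fitness_history)
  con <- file(path, "w")
  writeLines(paste0("# best_params: ",
                    paste(format(result$best_params, digits = 12),
                          collapse = ",")), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  cfg <- result$config
  jsonlite::write_json(
    list(lb = cfg$lb, ub = cfg$ub, Ps = cfg$Ps, G = cfg$G,
         crossover_rate = cfg$crossover_rate,
         mutation_rate = cfg$mutation_rate, elitism = cfg$elitism,
         seed = cfg$seed, best_fitness = result$best_fitness,
         package_version = as.character(utils::packageVersion("amoxkin"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
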