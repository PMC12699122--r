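#' Configuration of the Metropolis-Hastings sampler
#'
#' The sampler targets the posterior of the kinetic parameters under a
#' Gaussian i.i.d. measurement-error likelihood with fixed standard
#' deviation (no hyperparameters are estimated) and an independent Gaussian
#' prior centered at the initial estimate `P0` with relative standard
#' deviation `prior_rel_sd` (component j has prior sd
#' `prior_rel_sd * P0[j]`), truncated to positive values. Proposals are an
#' additive Gaussian random walk with per-component scale `w * P0[j]`;
#' anchoring the scale to `P0` keeps the proposal symmetric so the
#' Metropolis ratio is exact.
#'
#' @param P0 Initial parameter vector (prior mean and chain start).
#' @param N Number of iterations (default `1e5`).
#' @param w Relative step size (default `6e-3`).
#' @param prior_rel_sd Relative prior sd (default 0.6).
#' @param noise_sd Likelihood error sd in mM; `NULL` (default) uses the
#'   dataset's recorded noise level.
#' @param burn_in_frac Fraction of the chain discarded (default 0.2).
#' @param ci_level Credible level for summaries (default 0.99).
#' @param seed Integer seed (required for reproducible runs).
#' @param estimate Optional character vector naming the components to
#'   estimate; the rest stay fixed at `P0`. Default: all.
#' @return Object of class `amox_mcmc_config`.
#' @export
mcmc_config <- function(P0, N = 1e5, w = 6e-3, prior_rel_sd = 0.6,
                        noise_sd = NULL, burn_in_frac = 0.2,
                        ci_level = 0.99, seed = NULL, estimate = NULL) {
  if (N < 1) stop("N must be at least 1")
  if (w < 0) stop("w must be nonnegative")
  if (prior_rel_sd <= 0) stop("prior_rel_sd must be positive")
  if (burn_in_frac < 0 || burn_in_frac >= 1)
    stop("burn_in_frac must lie in [0, 1)")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (any(!is.finite(P0)) || any(P0 <= 0))
    stop("P0 must be finite and strictly positive")
  P0 <- as.numeric(unclass(P0)) |> setNames(names(P0))
  est <- rep(TRUE, length(P0))
  if (!is.null(estimate)) {
    if (!all(estimate %in% names(P0)))
      stop("unknown parameter(s) in 'estimate'")
    est <- names(P0) %in% estimate
  }
  structure(list(P0 = P0, N = as.integer(N), w = w,
                 prior_rel_sd = prior_rel_sd, noise_sd = noise_sd,
                 burn_in_frac = burn_in_frac, ci_level = ci_level,
                 seed = seed, estimate = est),
            class = "amox_mcmc_config")
}

#' Log prior density
#'
#' Independent Gaussian components with mean `P0[j]` and sd
#' `prior_rel_sd * P0[j]`, truncated at zero: any non-positive estimated
#' component yields `-Inf`. The truncation constant is omitted (it cancels
#' in the Metropolis ratio). Fixed components contribute nothing.
#'
#' @param P Parameter vector (same length as `config$P0`).
#' @param config `amox_mcmc_config`.
#' @return Log density (up to an additive constant).
#' @export
log_prior <- function(P, config) {
  P0 <- config$P0
  if (length(P) != length(P0)) stop("parameter dimension mismatch")
  est <- config$estimate
  if (any(P[est] <= 0)) return(-Inf)
  sum(dnorm(P[est], mean = P0[est], sd = config$prior_rel_sd * P0[est],
            log = TRUE))
}

#' Gaussian log likelihood of a dataset given parameters
#'
#' Simulates the model at the dataset's sample times and scores all present
#' (non-missing) observations as i.i.d. Gaussian around the simulated
#' trajectory with standard deviation `noise_sd`. A failed integration is
#' absorbed into `-Inf` (zero likelihood), so the sampler simply rejects
#' pathological parameter values.
#'
#' @param P Parameter vector.
#' @param dataset `amox_dataset` (may contain `NA` cells; a zero-row
#'   dataset gives log-likelihood 0, i.e. a flat likelihood).
#' @param model `"model1"` or `"model2"`.
#' @param conditions `amox_conditions`.
#' @param noise_sd Error sd in mM.
#' @return Log likelihood.
#' @export
log_likelihood <- function(P, dataset, model, conditions, noise_sd) {
  obs <- dataset$observations
  if (is.null(obs) || length(obs) == 0) return(0)
  traj <- try(simulate_reactor(model, P, conditions, t_eval = dataset$times),
              silent = TRUE)
  if (inherits(traj, "try-error")) return(-Inf)
  res <- obs - traj$states
  ll <- sum(dnorm(res[!is.na(res)], sd = noise_sd, log = TRUE))
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Random-walk proposal
#'
#' `P*[j] = P[j] + w * P0[j] * z[j]` with `z[j]` standard normal for
#' estimated components; fixed components are passed through. Candidates
#' with non-positive components are legal outputs and are rejected through
#' the truncated prior.
#'
#' @param P_prev Current parameter vector.
#' @param w Relative step size.
#' @param P0 Anchor vector fixing the per-component scale.
#' @param estimate Logical mask of estimated components (default all).
#' @return Candidate parameter vector.
#' @export
propose_params <- function(P_prev, w, P0, estimate = NULL) {
  if (is.null(estimate)) estimate <- rep(TRUE, length(P0))
  P_new <- P_prev
  n <- sum(estimate)
  P_new[estimate] <- P_prev[estimate] + w * P0[estimate] * rnorm(n)
  P_new
}

#' Run the Metropolis-Hastings sampler
#'
#' Standard Metropolis acceptance `min(1, posterior ratio)` on the
#' log-posterior `log_prior + log_likelihood`, starting from `config$P0`.
#' The first `burn_in_frac` of the `N` states is discarded; the retained
#' states, their log posterior and the overall acceptance rate are
#' returned. Fully reproducible from `config$seed`.
#'
#' @param model `"model1"` or `"model2"`.
#' @param dataset `amox_dataset`; a zero-row dataset yields a flat
#'   likelihood so the chain samples the prior (a useful sampler check).
#' @param conditions `amox_conditions`.
#' @param config `amox_mcmc_config`.
#' @return Object of class `amox_chain`: list with `samples` (matrix,
#'   retained states by parameter), `log_posterior`, `acceptance_rate`,
#'   `config`, `model`.
#' @export
run_mcmc <- function(model, dataset, conditions, config) {
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) noise_sd <- dataset$noise_sd
  if (is.null(noise_sd) || !is.finite(noise_sd) || noise_sd <= 0)
    stop("no valid noise_sd available (set it in the config or dataset)")
  P0 <- config$P0
  est <- config$estimate
  N <- config$N
  n_keep <- max(1L, floor(N * (1 - config$burn_in_frac)))

  with_seed(config$seed, {
    P <- P0
    lp <- log_prior(P, config) +
      log_likelihood(P, dataset, model, conditions, noise_sd)
    if (!is.finite(lp))
      stop("log posterior is not finite at P0; check the starting point")
    samples <- matrix(NA_real_, nrow = n_keep, ncol = length(P0),
                      dimnames = list(NULL, names(P0)))
    lp_trace <- numeric(n_keep)
    accepted <- 0L
    for (i in seq_len(N)) {
      Pc <- propose_params(P, config$w, P0, est)
      lpr <- log_prior(Pc, config)
      lpc <- if (is.finite(lpr))
        lpr + log_likelihood(Pc, dataset, model, conditions, noise_sd)
      else -Inf
      if (is.finite(lpc) && log(runif(1)) < lpc - lp) {
        P <- Pc
        lp <- lpc
        accepted <- accepted + 1L
      }
      k <- i - (N - n_keep)
      if (k >= 1) {
        samples[k, ] <- P
        lp_trace[k] <- lp
      }
    }
    acc <- accepted / N
    if (acc == 0) warning("no proposals were accepted; the chain is frozen")
    structure(list(samples = samples, log_posterior = lp_trace,
                   acceptance_rate = acc, config = config, model = model),
              class = "amox_chain")
  })
}

#' Per-parameter credible interval from a chain
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` of the
#' retained states.
#'
#' @param chain `amox_chain`, or a plain samples matrix.
#' @param level Credible level in (0, 1); defaults to the chain's
#'   configured level (0.99 for a plain matrix).
#' @return Matrix with columns `lower`, `upper`, one row per parameter.
#' @export
credible_interval <- function(chain, level = NULL) {
  samples <- if (inherits(chain, "amox_chain")) chain$samples else as.matrix(chain)
  if (is.null(level))
    level <- if (inherits(chain, "amox_chain")) chain$config$ci_level else 0.99
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  if (nrow(samples) == 0) stop("empty chain")
  a <- (1 - level) / 2
  q <- t(apply(samples, 2, quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(q) <- c("lower", "upper")
  q
}

#' Summarize a chain into point estimates and credible intervals
#'
#' @param chain `amox_chain`.
#' @return Object of class `amox_fit`: list with `estimates` (posterior
#'   means), `ci`, `sd`, `acceptance_rate`, `method = "MCMC"`, `model`.
#' @export
posterior_summary <- function(chain) {
  if (!inherits(chain, "amox_chain")) stop("expected an amox_chain")
  if (nrow(chain$samples) == 0) stop("empty chain")
  structure(list(estimates = colMeans(chain$samples),
                 ci = credible_interval(chain),
                 sd = apply(chain$samples, 2, sd),
                 acceptance_rate = chain$acceptance_rate,
                 method = "MCMC", model = chain$model),
            class = "amox_fit")
}

#' @export
print.amox_fit <- function(x, ...) {
  cat("Parameter fit (", x$model, ", ", x$method, ")\n", sep = "")
  tab <- data.frame(estimate = x$estimates)
  if (!is.null(x$ci)) {
    tab$lower <- x$ci[, "lower"]
    tab$upper <- x$ci[, "upper"]
  }
  print(tab)
  if (!is.null(x$acceptance_rate))
    cat("acceptance rate:", round(x$acceptance_rate, 3), "\n")
  if (!is.null(x$rrmse)) {
    cat("rRMSE (%):\n")
    print(round(x$rrmse, 3))
    cat("rRMSE sum (%):", round(x$rrmse_sum, 3), "\n")
  }
  invisible(x)
}

#' @export
print.amox_chain <- function(x, ...) {
  cat("MCMC chain: ", nrow(x$samples), " retained states, acceptance rate ",
      round(x$acceptance_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Export a chain as delimited text
#'
#' One row per retained state, parameters in canonical order plus the log
#' posterior; the configuration is echoed to a `<path>.json` sidecar.
#'
#' @param chain `amox_chain`.
#' @param path Output file.
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(chain$samples, log_posterior = chain$log_posterior)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- chain$config
  jsonlite::write_json(
    list(P0 = as.list(cfg$P0), N = cfg$N, w = cfg$w,
         prior_rel_sd = cfg$prior_rel_sd, noise_sd = cfg$noise_sd,
         burn_in_frac = cfg$burn_in_frac, ci_level = cfg$ci_level,
         seed = cfg$seed, estimate = names(cfg$P0)[cfg$estimate],
         acceptance_rate = chain$acceptance_rate, model = chain$model,
         package_version = as.character(utils::packageVersion("amoxkin"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Effective sample size from the autocorrelation function (initial
# positive-sum truncation); used for Monte-Carlo standard errors of chain
# means in diagnostics and tests.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}
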