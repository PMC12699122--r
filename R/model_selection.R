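#' Relative root-mean-squared error
#'
#' `100 * sqrt(mean((measured - estimated)^2)) / mean(measured)`: the RMSE
#' normalized by the mean of the measured sequence, in percent. Invariant
#' under common positive rescaling, zero iff the sequences coincide.
#'
#' @param measured Numeric vector of measured values (nonzero mean).
#' @param estimated Numeric vector of the same length.
#' @return rRMSE in percent.
#' @export
rrmse <- function(measured, estimated) {
  if (length(measured) == 0 || length(measured) != length(estimated))
    stop("sequences must have equal, nonzero length")
  keep <- !is.na(measured) & !is.na(estimated)
  m <- mean(measured[keep])
  if (!is.finite(m) || m == 0)
    stop("mean of the measured sequence must be nonzero")
  100 * sqrt(mean((measured[keep] - estimated[keep])^2)) / m
}

#' Per-variable rRMSE of a parameter set against a dataset
#'
#' Simulates the model at the dataset's sample times and reports the rRMSE
#' of each state variable plus their sum, the model-selection score.
#'
#' @param dataset `amox_dataset` covering all four variables.
#' @param model `"model1"` or `"model2"`.
#' @param p Parameter vector.
#' @param conditions `amox_conditions`.
#' @return List with `per_variable` (named percentages) and `total`.
#' @export
evaluate_fit <- function(dataset, model, p, conditions) {
  traj <- simulate_reactor(model, p, conditions, t_eval = dataset$times)
  per <- vapply(seq_len(4), function(j)
    rrmse(dataset$observations[, j], traj$states[, j]), numeric(1))
  names(per) <- STATE_NAMES
  list(per_variable = per, total = sum(per))
}

#' Fit every model x method x condition interaction
#'
#' Runs the eight fits of the study design — two models (semi-empirical and
#' mechanism-based), two estimators (MCMC and GA), two charges (LC and HC)
#' — and scores each by per-variable rRMSE. Priors and GA search-space
#' centers default to the literature reference estimates of each model.
#'
#' @param datasets Named list with elements `LC` and `HC`
#'   (`amox_dataset`s observed under the matching scenario charges).
#' @param seed Integer; per-cell seeds are derived from it.
#' @param mcmc Named list of [mcmc_config()] overrides (e.g. `N`, `w`).
#' @param ga Named list of [ga_config()] overrides (e.g. `G`, `Ps`).
#' @param centers Named list `model1`/`model2` of parameter vectors used as
#'   prior means and bound centers; defaults to the literature estimates.
#' @param cez Named list `model1`/`model2` of enzyme loads; defaults to the
#'   scenario defaults.
#' @param t_end Horizon (min); default 240.
#' @return Data frame with 8 rows (model, method, condition, per-variable
#'   rRMSE in percent, `rrmse_sum`); fitted objects in attribute `fits`.
#' @export
interaction_grid <- function(datasets, seed = 1, mcmc = list(), ga = list(),
                             centers = NULL, cez = NULL, t_end = 240) {
  stopifnot(all(c("LC", "HC") %in% names(datasets)))
  if (is.null(centers))
    centers <- list(model1 = ref_params_model1("goncalves"),
                    model2 = ref_params_model2())
  rows <- list()
  fits <- list()
  cell <- 0L
  for (cond in c("LC", "HC")) for (model in c("model1", "model2"))
    for (method in c("MCMC", "GA")) {
      cell <- cell + 1L
      cond_obj <- scenario(cond, model = model,
                           cez = cez[[model]], t_end = t_end)
      ds <- datasets[[cond]]
      cell_seed <- (seed * 8L + cell) %% .Machine$integer.max
      fit <- try(fit_cell(model, method, ds, cond_obj, centers[[model]],
                          cell_seed, mcmc, ga), silent = TRUE)
      key <- paste(model, method, cond, sep = ".")
      if (inherits(fit, "try-error")) {
        fits[[key]] <- NULL
        rows[[key]] <- data.frame(model = model, method = method,
                                  condition = cond, rrmse_C_AB = NA,
                                  rrmse_C_AN = NA, rrmse_C_NH = NA,
                                  rrmse_C_AOH = NA, rrmse_sum = NA,
                                  failed = TRUE)
        next
      }
      sc <- evaluate_fit(ds, model, fit$estimates, cond_obj)
      fit$rrmse <- sc$per_variable
      fit$rrmse_sum <- sc$total
      fit$condition <- cond
      fits[[key]] <- fit
      rows[[key]] <- data.frame(model = model, method = method,
                                condition = cond,
                                rrmse_C_AB = sc$per_variable[[1]],
                                rrmse_C_AN = sc$per_variable[[2]],
                                rrmse_C_NH = sc$per_variable[[3]],
                                rrmse_C_AOH = sc$per_variable[[4]],
                                rrmse_sum = sc$total, failed = FALSE)
    }
  grid <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(grid, "fits") <- fits
  grid
}

fit_cell <- function(model, method, dataset, conditions, center, seed,
                     mcmc_over, ga_over) {
  center <- setNames(as.numeric(center), param_names(model))
  if (method == "MCMC") {
    args <- utils::modifyList(
      list(P0 = center, N = 2000L, w = 0.05, seed = seed), mcmc_over)
    cfg <- do.call(mcmc_config, args)
    posterior_summary(run_mcmc(model, dataset, conditions, cfg))
  } else {
    b <- default_bounds(center)
    args <- utils::modifyList(
      list(lb = b$lb, ub = b$ub, Ps = 40L, G = 40L, seed = seed), ga_over)
    cfg <- do.call(ga_config, args)
    fit_ga(model, dataset, conditions, cfg)
  }
}

#' Best interaction per condition
#'
#' @param grid Output of [interaction_grid()].
#' @return Data frame with one winning row (minimum `rrmse_sum`) per
#'   condition.
#' @export
grid_winner <- function(grid) {
  do.call(rbind, lapply(split(grid, grid$condition), function(g) {
    g <- g[!g$failed & is.finite(g$rrmse_sum), , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    g[which.min(g$rrmse_sum), ]
  }))
}

#' Write an interaction grid as a delimited table
#'
#' Rows are the four state variables, columns the model x method x
#' condition cells, entries rRMSE in percent.
#'
#' @param grid Output of [interaction_grid()].
#' @param path Output file.
#' @export
write_grid <- function(grid, path) {
  cells <- paste(grid$model, grid$method, grid$condition, sep = ".")
  m <- t(as.matrix(grid[, c("rrmse_C_AB", "rrmse_C_AN",
                            "rrmse_C_NH", "rrmse_C_AOH")]))
  rownames(m) <- STATE_NAMES
  colnames(m) <- cells
  df <- data.frame(variable = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
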