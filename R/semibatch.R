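#' Molar masses of the four species (g/mol)
#'
#' p-hydroxyphenylglycine methyl ester (C9H11NO3, 181.19), amoxicillin
#' (C16H19N3O5S, 365.40), 6-aminopenicillanic acid (C8H12N2O3S, 216.26) and
#' p-hydroxyphenylglycine (C8H9NO3, 167.16).
#'
#' @return Named numeric vector in state order.
#' @export
molar_masses <- function() {
  c(C_AB = 181.19, C_AN = 365.40, C_NH = 216.26, C_AOH = 167.16)
}

#' Default semi-batch validation scenario
#'
#' Low-concentration-level charge and enzyme load with both substrates fed
#' at a constant 0.2 mM/min over the first 120 min, then no feed, on a
#' 400-min horizon. A package default for synthetic validation studies.
#'
#' @param model Model whose enzyme-load convention to use.
#' @param cez Optional enzyme-load override.
#' @return `amox_conditions` in semi-batch mode.
#' @export
semibatch_scenario <- function(model = "model1", cez = NULL) {
  if (is.null(cez)) cez <- if (model == "model1") 2.5 else 0.05
  reactor_conditions(cez = cez, cez_unit = cez_unit_for(model),
                     initial_state = c(80, 0, 60, 0), mode = "semibatch",
                     feed = feed_schedule(c(0, 120), fab = c(0.2, 0),
                                          fnh = c(0.2, 0)),
                     t_end = 400)
}

#' Predict a semi-batch run from batch-estimated parameters
#'
#' Forward-simulates the fed-batch system using parameters calibrated on
#' batch data, with no re-fitting — the transfer test of the modeling
#' workflow.
#'
#' @param model `"model1"` or `"model2"`.
#' @param batch_fit `amox_fit` (its `estimates` are used) or a bare
#'   parameter vector.
#' @param conditions `amox_conditions` with `mode = "semibatch"`.
#' @param t_eval Optional output grid.
#' @return `amox_trajectory`.
#' @export
predict_semibatch <- function(model, batch_fit, conditions, t_eval = NULL) {
  if (conditions$mode != "semibatch")
    stop("conditions must be in semibatch mode")
  p <- if (inherits(batch_fit, "amox_fit")) batch_fit$estimates else batch_fit
  simulate_reactor(model, p, conditions, t_eval = t_eval)
}

#' Pointwise posterior predictive band
#'
#' Simulates the model at a thinned subsample of the posterior chain and
#' returns the pointwise quantile envelope of the resulting trajectories
#' for each species.
#'
#' @param model `"model1"` or `"model2"`.
#' @param chain `amox_chain` from a (batch) calibration.
#' @param conditions `amox_conditions` (batch or semi-batch).
#' @param t_eval Output time grid.
#' @param level Band level in (0, 1) (default 0.99).
#' @param n_draws Posterior draws used (default 500; evenly thinned).
#' @return List with `times`, `lower`, `upper` (matrices, columns per
#'   species), `median`, `level`, `n_draws`.
#' @export
predictive_band <- function(model, chain, conditions, t_eval = NULL,
                            level = 0.99, n_draws = 500) {
  if (!inherits(chain, "amox_chain")) stop("expected an amox_chain")
  n <- nrow(chain$samples)
  if (n == 0) stop("empty chain")
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  if (is.null(t_eval)) t_eval <- seq(0, conditions$t_end, length.out = 101)
  t_eval <- sort(unique(c(0, t_eval)))
  idx <- unique(round(seq(1, n, length.out = min(n_draws, n))))
  sims <- array(NA_real_, dim = c(length(idx), length(t_eval), 4))
  for (k in seq_along(idx)) {
    traj <- simulate_reactor(model, chain$samples[idx[k], ], conditions,
                             t_eval = t_eval)
    sims[k, , ] <- traj$states
  }
  a <- (1 - level) / 2
  qs <- apply(sims, c(2, 3), quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  dn <- list(NULL, STATE_NAMES)
  list(times = t_eval,
       lower = matrix(qs[1, , ], ncol = 4, dimnames = dn),
       median = matrix(qs[2, , ], ncol = 4, dimnames = dn),
       upper = matrix(qs[3, , ], ncol = 4, dimnames = dn),
       level = level, n_draws = length(idx))
}

convert_units <- function(x, to) {
  mm <- molar_masses()
  tab <- if (inherits(x, "amox_trajectory")) "states" else "observations"
  from <- if (!is.null(x$unit)) x$unit else "mM"
  if (from == to) stop("values are already in ", to)
  fac <- if (to == "g_per_L") mm / 1000 else 1000 / mm
  x[[tab]] <- sweep(x[[tab]], 2, fac, `*`)
  x$unit <- to
  x
}

#' Convert concentrations between mM and g/L
#'
#' Multiplies each species column by its molar mass / 1000 (or the inverse)
#' using [molar_masses()]. The two conversions round-trip to within 1e-9.
#'
#' @param x `amox_trajectory` or `amox_dataset`.
#' @return The same structure with converted values and updated `unit`.
#' @export
to_mass_units <- function(x) convert_units(x, "g_per_L")

#' @rdname to_mass_units
#' @export
to_molar_units <- function(x) convert_units(x, "mM")
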