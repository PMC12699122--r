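#' Reactor configuration
#'
#' Bundles enzyme load, operating mode, initial charge, optional feed
#' schedule and time horizon. The enzyme load carries a unit tag: model 1
#' expresses catalytic constants per international unit of immobilized
#' enzyme, so its load is in i.u./mL; model 2 uses first-order rate
#' constants and a molar enzyme concentration (mM). [simulate_reactor()]
#' refuses a unit/model mismatch.
#'
#' @param cez Enzyme load, `>= 0`.
#' @param cez_unit `"iu_per_mL"` (model 1) or `"mM"` (model 2).
#' @param initial_state Length-4 initial concentrations
#'   `(C_AB, C_AN, C_NH, C_AOH)` in mM.
#' @param mode `"batch"` or `"semibatch"`.
#' @param feed `amox_feed` schedule; required iff `mode = "semibatch"`.
#' @param t_end Horizon in min, `> 0`.
#' @return Object of class `amox_conditions`.
#' @export
reactor_conditions <- function(cez, cez_unit = c("iu_per_mL", "mM"),
                               initial_state, mode = c("batch", "semibatch"),
                               feed = NULL, t_end = 240) {
  mode <- match.arg(mode)
  cez_unit <- match.arg(cez_unit)
  check_cez(cez)
  check_state(initial_state)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (mode == "semibatch" && is.null(feed))
    stop("semibatch mode requires a feed schedule")
  if (mode == "batch" && !is.null(feed))
    stop("batch mode must not carry a feed schedule")
  if (!is.null(feed) && !inherits(feed, "amox_feed"))
    stop("feed must be an amox_feed object")
  structure(list(cez = cez, cez_unit = cez_unit,
                 initial_state = setNames(as.numeric(initial_state),
                                          STATE_NAMES),
                 mode = mode, feed = feed, t_end = t_end),
            class = "amox_conditions")
}

cez_unit_for <- function(model) {
  switch(model, model1 = "iu_per_mL", model2 = "mM")
}

#' Integrate a kinetic model over a reactor run
#'
#' Solves the four-species ODE system with `deSolve::lsoda` (stiff-capable,
#' default `rtol = 1e-8`, `atol = 1e-10`). Semi-batch feed schedules are
#' piecewise constant; the integration is restarted at every feed
#' breakpoint so the discontinuities are never stepped across. By default
#' the compiled C right-hand side is used; `compiled = FALSE` integrates
#' the R rate functions instead (slower, used as a cross-check).
#'
#' @param model `"model1"` or `"model2"`.
#' @param p Parameter vector for `model`.
#' @param conditions `amox_conditions`.
#' @param t_eval Output time grid in `[0, t_end]`; default 241 equispaced
#'   points. 0 is always included.
#' @param rtol,atol Solver tolerances.
#' @param compiled Use the compiled right-hand side (default `TRUE`).
#' @return Object of class `amox_trajectory`: list with `times`, `states`
#'   (matrix, columns `C_AB, C_AN, C_NH, C_AOH`, mM), `model`, `conditions`,
#'   `unit`.
#' @export
simulate_reactor <- function(model, p, conditions, t_eval = NULL,
                             rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  model <- match.arg(model, c("model1", "model2"))
  if (!inherits(conditions, "amox_conditions"))
    stop("conditions must be an amox_conditions object")
  if (conditions$cez_unit != cez_unit_for(model))
    stop("enzyme load unit '", conditions$cez_unit,
         "' does not match ", model, " (expects '", cez_unit_for(model), "')")
  np <- length(param_names(model))
  if (length(p) != np) stop("expected ", np, " parameters for ", model)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("parameters must be finite and positive")

  t_end <- conditions$t_end
  if (is.null(t_eval)) t_eval <- seq(0, t_end, length.out = 241)
  t_eval <- sort(unique(c(0, as.numeric(t_eval))))
  if (min(t_eval) < 0 || max(t_eval) > t_end)
    stop("t_eval must lie within [0, t_end]")

  feed <- conditions$feed
  if (conditions$mode == "batch") feed <- feed_schedule(0, 0, 0)
  seg_starts <- feed$breaks[feed$breaks < t_end]
  seg_bounds <- c(seg_starts, t_end)

  y <- conditions$initial_state
  out_t <- 0
  out_y <- matrix(y, nrow = 1)
  for (i in seq_along(seg_starts)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1]
    tt <- sort(unique(c(a, t_eval[t_eval > a & t_eval <= b], b)))
    if (length(tt) < 2) tt <- c(a, b)
    seg <- integrate_segment(model, y, tt, p, conditions$cez,
                             feed$fab[i], feed$fnh[i], rtol, atol, compiled)
    keep <- seg[, 1] > a
    out_t <- c(out_t, seg[keep, 1])
    out_y <- rbind(out_y, seg[keep, 2:5, drop = FALSE])
    y <- seg[nrow(seg), 2:5]
  }
  sel <- out_t %in% t_eval
  states <- out_y[sel, , drop = FALSE]
  colnames(states) <- STATE_NAMES
  structure(list(times = out_t[sel], states = states, model = model,
                 conditions = conditions, unit = "mM"),
            class = "amox_trajectory")
}

integrate_segment <- function(model, y0, times, p, cez, fab, fnh,
                              rtol, atol, compiled) {
  y0 <- as.numeric(y0)
  out <- if (compiled) {
    parms <- c(p, cez, fab, fnh)
    fn <- if (model == "model1") "amox_derivs1" else "amox_derivs2"
    ini <- if (model == "model1") "amox_init1" else "amox_init2"
    try(deSolve::lsoda(y0, times, func = fn, parms = parms,
                       dllname = "amoxkin", initfunc = ini,
                       rtol = rtol, atol = atol), silent = TRUE)
  } else {
    pn <- setNames(p, param_names(model))
    feed <- feed_schedule(0, fab, fnh)
    rhs <- function(t, y, parms)
      list(unname(rhs_semibatch(model, pmax(y, 0), pn, cez, feed, t)))
    try(deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol),
        silent = TRUE)
  }
  if (inherits(out, "try-error"))
    stop("integration failed on [", times[1], ", ", max(times), "] min: ",
         attr(out, "condition")$message)
  out <- unclass(out)
  if (nrow(out) < length(times) || any(!is.finite(out[, 2:5])))
    stop("integration failed near t = ", out[nrow(out), 1], " min")
  out
}

#' Interpolate a trajectory at arbitrary times
#'
#' Monotone cubic (Fritsch-Carlson) interpolation per species; exact at the
#' stored grid nodes.
#'
#' @param traj `amox_trajectory`.
#' @param t Times within the stored range.
#' @return Matrix with one row per `t`, columns as in `traj$states`.
#' @export
trajectory_at <- function(traj, t) {
  if (any(t < traj$times[1] - 1e-12) || any(t > max(traj$times) + 1e-12))
    stop("interpolation time out of range")
  out <- vapply(seq_len(4), function(j) {
    f <- stats::splinefun(traj$times, traj$states[, j], method = "monoH.FC")
    f(t)
  }, numeric(length(t)))
  out <- matrix(out, nrow = length(t), ncol = 4,
                dimnames = list(NULL, STATE_NAMES))
  out
}

#' @export
print.amox_trajectory <- function(x, ...) {
  cat("Reactor trajectory (", x$model, ", ", x$conditions$mode, "), ",
      length(x$times), " points on [0, ", max(x$times), "] min, unit ",
      x$unit, "\n", sep = "")
  print(head(cbind(time_min = x$times, x$states)))
  if (length(x$times) > 6) cat("...\n")
  invisible(x)
}

traj_colnames <- function(unit) {
  suff <- if (unit == "mM") "mM" else "g_per_L"
  c("time_min", paste(STATE_NAMES, suff, sep = "_"))
}

#' Write / read a trajectory as delimited text
#'
#' Comma-separated values with a `# key: value` metadata preamble (unit,
#' model, mode) and a header row
#' `time_min, C_AB_<unit>, C_AN_<unit>, C_NH_<unit>, C_AOH_<unit>`.
#'
#' @param traj `amox_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# unit:", traj$unit),
               paste("# model:", traj$model),
               paste("# mode:", traj$conditions$mode)), con)
  df <- data.frame(traj$times, traj$states)
  names(df) <- traj_colnames(traj$unit)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  meta
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta <- read_meta(path)
  unit <- if (is.null(meta$unit)) "mM" else meta$unit
  if (!unit %in% c("mM", "g_per_L")) stop("unknown unit in header: ", unit)
  df <- read.csv(path, comment.char = "#")
  states <- as.matrix(df[, 2:5])
  colnames(states) <- STATE_NAMES
  structure(list(times = df[[1]], states = states,
                 model = meta$model, conditions = NULL, unit = unit),
            class = "amox_trajectory")
}
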