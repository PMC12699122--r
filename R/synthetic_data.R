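with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Standard batch charge scenarios
#'
#' The two initial-concentration conditions of the batch study: low
#' concentration (`"LC"`, 80 mM ester + 60 mM 6-APA) and high concentration
#' (`"HC"`, 120 mM ester + 30 mM 6-APA), both with no product or by-product
#' initially present, 240-min horizon and the default enzyme load of the
#' requested model: 2.5 i.u./mL for model 1 and 0.05 mM for model 2, each
#' chosen so that well over half the ester converts within the horizon
#' while the transient still spans most of it (informative data for
#' estimation).
#'
#' @param name `"LC"` or `"HC"`.
#' @param model Model whose enzyme-load convention to use.
#' @param cez Optional enzyme-load override.
#' @param t_end Horizon in min (default 240).
#' @return `amox_conditions` in batch mode.
#' @export
scenario <- function(name, model = "model1", cez = NULL, t_end = 240) {
  model <- match.arg(model, c("model1", "model2"))
  y0 <- switch(match.arg(name, c("LC", "HC")),
               LC = c(80, 0, 60, 0),
               HC = c(120, 0, 30, 0))
  if (is.null(cez)) cez <- if (model == "model1") 2.5 else 0.05
  reactor_conditions(cez = cez, cez_unit = cez_unit_for(model),
                     initial_state = y0, mode = "batch", t_end = t_end)
}

#' Generate a noisy synthetic concentration dataset
#'
#' Simulates the chosen model under `conditions`, samples the trajectory at
#' `n_points` equispaced times on `[0, t_end]` (or at user-supplied
#' `times`), and adds i.i.d. additive Gaussian measurement noise of
#' standard deviation `noise_sd`, independently per species and time point.
#' Noisy values are deliberately not truncated at zero, which keeps the
#' Gaussian likelihood of the estimators unbiased. Provenance (model,
#' parameters, conditions, seed, noise level) is recorded on the object.
#'
#' @param model `"model1"` or `"model2"`.
#' @param p Generating parameter vector.
#' @param conditions `amox_conditions`.
#' @param n_points Number of sample times, `>= 4` (default 13).
#' @param noise_sd Measurement noise sd in mM, `> 0` (default 1.0).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param times Optional explicit sample times (overrides `n_points`).
#' @return Object of class `amox_dataset`: list with `times`,
#'   `observations` (matrix, mM), `noise_sd`, `provenance`.
#' @export
generate_dataset <- function(model, p, conditions, n_points = 13,
                             noise_sd = 1.0, seed = NULL, times = NULL) {
  if (is.null(times)) {
    if (n_points < 4) stop("n_points must be at least 4")
    times <- seq(0, conditions$t_end, length.out = n_points)
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  traj <- simulate_reactor(model, p, conditions, t_eval = times)
  truth <- traj$states
  obs <- with_seed(seed,
    truth + matrix(rnorm(length(truth), sd = noise_sd),
                   nrow = nrow(truth)))
  colnames(obs) <- STATE_NAMES
  structure(list(times = traj$times, observations = obs,
                 noise_sd = noise_sd,
                 provenance = list(model = model,
                                   params = setNames(as.numeric(p),
                                                     param_names(model)),
                                   conditions = conditions, seed = seed)),
            class = "amox_dataset")
}

#' @export
print.amox_dataset <- function(x, ...) {
  cat("Concentration dataset: ", length(x$times), " time points, noise sd ",
      x$noise_sd, " mM", sep = "")
  if (!is.null(x$provenance$model))
    cat(" (synthetic, ", x$provenance$model, ")", sep = "")
  cat("\n")
  print(head(cbind(time_min = x$times, x$observations)))
  if (length(x$times) > 6) cat("...\n")
  invisible(x)
}

#' Write / read a dataset as delimited text with a provenance sidecar
#'
#' The main file uses the trajectory format; a `<path>.json` sidecar stores
#' noise level, generating model, parameters and seed so a synthetic
#' dataset can be regenerated exactly.
#'
#' @param ds `amox_dataset`.
#' @param path Output file; sidecar written to `paste0(path, ".json")`.
#' @export
write_dataset <- function(ds, path) {
  con <- file(path, "w")
  writeLines("# unit: mM", con)
  df <- data.frame(ds$times, ds$observations)
  names(df) <- traj_colnames("mM")
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  prov <- ds$provenance
  side <- list(noise_sd = ds$noise_sd, model = prov$model,
               params = as.list(prov$params), seed = prov$seed,
               package_version = as.character(utils::packageVersion("amoxkin")))
  if (!is.null(prov$conditions))
    side$conditions <- list(cez = prov$conditions$cez,
                            cez_unit = prov$conditions$cez_unit,
                            mode = prov$conditions$mode,
                            initial_state = as.numeric(prov$conditions$initial_state),
                            t_end = prov$conditions$t_end)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, comment.char = "#")
  obs <- as.matrix(df[, 2:5])
  colnames(obs) <- STATE_NAMES
  side_path <- paste0(path, ".json")
  noise_sd <- NA_real_
  prov <- list()
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    noise_sd <- side$noise_sd
    prov <- list(model = side$model, params = unlist(side$params),
                 seed = side$seed)
    if (!is.null(side$conditions))
      prov$conditions <- reactor_conditions(
        cez = side$conditions$cez, cez_unit = side$conditions$cez_unit,
        initial_state = side$conditions$initial_state,
        mode = side$conditions$mode, t_end = side$conditions$t_end)
  }
  structure(list(times = df[[1]], observations = obs, noise_sd = noise_sd,
                 provenance = prov),
            class = "amox_dataset")
}
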