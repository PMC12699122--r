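#' Canonical parameter names for a kinetic model
#'
#' Model 1 is the semi-empirical Michaelis-Menten model with competitive
#' inhibition by products and by-product; model 2 is the mechanism-based
#' model built from reaction and equilibrium constants of the acyl-enzyme
#' cycle. Parameter vectors are always kept in this canonical order.
#'
#' @param model `"model1"` or `"model2"`.
#' @return Character vector of parameter names.
#' @export
param_names <- function(model) {
  switch(match.arg(model, c("model1", "model2")),
    model1 = c("Kcat1", "Kcat2", "KM1", "KM2", "Tmax",
               "KEN", "kAB", "kAN", "kAOH", "kNH"),
    model2 = c("k2", "k3", "k4", "km4", "k5", "KN", "KS", "KP"))
}

#' Construct a parameter vector for model 1
#'
#' The ten parameters of the semi-empirical model: catalytic constants for
#' ester consumption (`Kcat1`) and amoxicillin hydrolysis (`Kcat2`), both in
#' umol/(i.u. min); Michaelis constants `KM1`, `KM2` (mM); the maximum
#' fraction `Tmax` of acyl-enzyme-nucleus complex converted to product
#' (dimensionless, in (0, 1]); the 6-APA adsorption constant `KEN` (mM); and
#' the competitive inhibition constants `kAB`, `kAN`, `kAOH`, `kNH` (mM) of
#' ester, amoxicillin, POHPG and 6-APA respectively.
#'
#' @param Kcat1,Kcat2,KM1,KM2,Tmax,KEN,kAB,kAN,kAOH,kNH Numeric scalars,
#'   all strictly positive.
#' @param validate If `TRUE` (default), enforce positivity and `Tmax <= 1`.
#' @return Named numeric vector of class `amox_params`.
#' @export
params_model1 <- function(Kcat1, Kcat2, KM1, KM2, Tmax, KEN,
                          kAB, kAN, kAOH, kNH, validate = TRUE) {
  p <- c(Kcat1 = Kcat1, Kcat2 = Kcat2, KM1 = KM1, KM2 = KM2, Tmax = Tmax,
         KEN = KEN, kAB = kAB, kAN = kAN, kAOH = kAOH, kNH = kNH)
  if (validate) validate_params(p, "model1")
  structure(p, class = c("amox_params"), model = "model1")
}

#' Construct a parameter vector for model 2
#'
#' The eight parameters of the mechanism-based model: first-order rate
#' constants (min^-1) for acyl-enzyme formation (`k2`), ester hydrolysis
#' (`k3`), amoxicillin synthesis (`k4`), its reverse (`km4`, i.e. k_-4) and
#' by-product formation through the product route (`k5`); the nucleophile
#' association constant `KN` (mM); and the enzyme-substrate and product
#' equilibrium constants `KS` and `KP` (mM).
#'
#' @param k2,k3,k4,km4,k5,KN,KS,KP Numeric scalars, all strictly positive.
#' @param validate If `TRUE` (default), enforce positivity.
#' @return Named numeric vector of class `amox_params`.
#' @export
params_model2 <- function(k2, k3, k4, km4, k5, KN, KS, KP, validate = TRUE) {
  p <- c(k2 = k2, k3 = k3, k4 = k4, km4 = km4, k5 = k5,
         KN = KN, KS = KS, KP = KP)
  if (validate) validate_params(p, "model2")
  structure(p, class = c("amox_params"), model = "model2")
}

#' Coerce a named vector or list to a canonical parameter vector
#'
#' @param x Named numeric vector or list containing every parameter of the
#'   model; extra names are an error.
#' @param model `"model1"` or `"model2"`.
#' @param validate Enforce invariants (default `TRUE`).
#' @return Named numeric vector of class `amox_params` in canonical order.
#' @export
as_params <- function(x, model, validate = TRUE) {
  nm <- param_names(model)
  x <- unlist(x)
  if (!all(nm %in% names(x)))
    stop("missing parameter(s): ", paste(setdiff(nm, names(x)), collapse = ", "))
  if (!all(names(x) %in% nm))
    stop("unknown parameter(s): ", paste(setdiff(names(x), nm), collapse = ", "))
  p <- as.numeric(x[nm])
  names(p) <- nm
  if (validate) validate_params(p, model)
  structure(p, class = "amox_params", model = model)
}

validate_params <- function(p, model) {
  nm <- param_names(model)
  if (length(p) != length(nm))
    stop("expected ", length(nm), " parameters for ", model,
         ", got ", length(p))
  bad <- !is.finite(p) | p <= 0
  if (any(bad))
    stop("parameter(s) must be finite and strictly positive: ",
         paste(nm[bad], collapse = ", "))
  if (model == "model1" && p[["Tmax"]] > 1)
    stop("Tmax must lie in (0, 1]")
  invisible(TRUE)
}

#' Literature and published estimates for model 1
#'
#' Point estimates used as priors, GA search-space centers and as generating
#' values for synthetic recovery studies: `"lc_mcmc"` are posterior means
#' from a Bayesian batch calibration at the low-concentration charge,
#' `"hc_ga"` are genetic-algorithm estimates at the high-concentration
#' charge, and `"goncalves"` are the earlier deterministic literature
#' estimates used as initial guesses.
#'
#' @param which One of `"lc_mcmc"`, `"hc_ga"`, `"goncalves"`.
#' @return `amox_params` vector for model 1.
#' @export
ref_params_model1 <- function(which = c("lc_mcmc", "hc_ga", "goncalves")) {
  v <- switch(match.arg(which),
    lc_mcmc   = c(0.181, 0.39, 5.45, 1.69, 0.82, 7.94, 0.68, 1.98, 9.85, 9.76),
    hc_ga     = c(1.159, 1.785, 43.48, 49.22, 0.98, 32.48,
                  645.03, 815.80, 21.21, 273.67),
    goncalves = c(0.18, 0.33, 7.91, 12.5, 0.61, 14.4, 3.78, 9.17, 10.9, 62.04))
  names(v) <- param_names("model1")
  structure(v, class = "amox_params", model = "model1")
}

#' Reference parameter set for model 2
#'
#' Published high-concentration posterior means are available for `k3`
#' (0.95 min^-1), `k4` (0.06 min^-1) and `KP` (0.23 mM); the remaining five
#' parameters are nominal values documented with the package (k2 = 1,
#' km4 = 0.05, k5 = 0.5 min^-1; KN = 10, KS = 5 mM), chosen to give
#' realistic conversion on a 240-min horizon.
#'
#' @return `amox_params` vector for model 2.
#' @export
ref_params_model2 <- function() {
  v <- c(k2 = 1, k3 = 0.95, k4 = 0.06, km4 = 0.05, k5 = 0.5,
         KN = 10, KS = 5, KP = 0.23)
  structure(v, class = "amox_params", model = "model2")
}

#' @export
print.amox_params <- function(x, ...) {
  cat("Kinetic parameters (", attr(x, "model"), ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Write / read a parameter vector as a flat YAML mapping
#'
#' @param p `amox_params` vector.
#' @param path File path.
#' @export
write_params <- function(p, path) {
  yaml::write_yaml(c(list(model = attr(p, "model")),
                     as.list(stats::setNames(as.numeric(p), names(p)))), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  model <- x$model
  x$model <- NULL
  as_params(x, model)
}
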