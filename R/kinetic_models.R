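#' @useDynLib amoxkin
#' @importFrom stats approx dnorm quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

STATE_NAMES <- c("C_AB", "C_AN", "C_NH", "C_AOH")

check_state <- function(state) {
  if (length(state) != 4)
    stop("state must have 4 components (C_AB, C_AN, C_NH, C_AOH)")
  nm <- if (!is.null(names(state))) names(state) else STATE_NAMES
  bad <- !is.finite(state) | state < 0
  if (any(bad))
    stop("invalid state: ", paste(nm[bad], collapse = ", "),
         " must be finite and nonnegative")
  unname(state)
}

check_cez <- function(cez) {
  if (!is.finite(cez) || cez < 0)
    stop("invalid enzyme load CEZ: must be finite and nonnegative")
  cez
}

#' Reaction rates of the semi-empirical model (model 1)
#'
#' Computes the three rates of the kinetically controlled network:
#' ester consumption `vAB`, amoxicillin synthesis `vS` and amoxicillin
#' hydrolysis `vAN`, all in mM/min. Ester consumption follows
#' Michaelis-Menten kinetics with competitive inhibition by amoxicillin and
#' POHPG; the fraction of consumed ester routed to synthesis is
#' `Tmax * C_NH / (KEN + C_NH)`, reflecting 6-APA adsorption on the
#' acyl-enzyme complex; amoxicillin hydrolysis is Michaelis-Menten with
#' competitive inhibition by ester, 6-APA and POHPG.
#'
#' @param state Numeric length-4 state `(C_AB, C_AN, C_NH, C_AOH)` in mM.
#' @param p Model 1 parameter vector (see [params_model1()]).
#' @param cez Enzyme load in i.u./mL.
#' @return Named numeric vector `c(vAB, vS, vAN)` (mM/min), all nonnegative.
#' @export
rates_model1 <- function(state, p, cez) {
  state <- check_state(state)
  cez <- check_cez(cez)
  CAB <- state[1]; CAN <- state[2]; CNH <- state[3]; CAOH <- state[4]
  vAB <- p[["Kcat1"]] * CAB * cez /
    (p[["KM1"]] * (1 + CAN / p[["kAN"]] + CAOH / p[["kAOH"]]) + CAB)
  vS <- vAB * p[["Tmax"]] * CNH / (p[["KEN"]] + CNH)
  vAN <- p[["Kcat2"]] * CAN * cez /
    (p[["KM2"]] * (1 + CAB / p[["kAB"]] + CNH / p[["kNH"]] +
                     CAOH / p[["kAOH"]]) + CAN)
  c(vAB = vAB, vS = vS, vAN = vAN)
}

#' Batch right-hand side of model 1
#'
#' Assembles the time-derivatives of the four concentrations from the
#' model 1 rates: the ester feeds both hydrolysis (to POHPG) and synthesis
#' (to amoxicillin), and amoxicillin hydrolysis returns the 6-APA nucleus
#' and releases POHPG. The ester-moiety sum `C_AB + C_AN + C_AOH` and the
#' nucleus sum `C_AN + C_NH` are conserved exactly.
#'
#' @inheritParams rates_model1
#' @return Named derivative vector (mM/min) in state order.
#' @export
rhs_model1_batch <- function(state, p, cez) {
  v <- rates_model1(state, p, cez)
  d <- c(-v[["vAB"]],
         v[["vS"]] - v[["vAN"]],
         v[["vAN"]] - v[["vS"]],
         v[["vAB"]] - v[["vS"]] + v[["vAN"]])
  setNames(d, STATE_NAMES)
}

#' Batch right-hand side of model 2
#'
#' Mechanism-based rates built from the acyl-enzyme cycle: with
#' `D = k3*KN + k4*C_NH + k5*C_NH`, the amoxicillin production rate is
#' `RP = CEZ * (k2*k4*C_AB*C_NH/KS - km4*C_AN*(k3*KN + k5*C_NH)/KP) / D`
#' and the by-product rate is
#' `RB = CEZ * (k3*KN + k5*C_NH) * (k2*C_AB/KS - km4*C_AN/KP) / D`.
#' Ester consumption is `-(RP + RB)` and nucleus consumption `-RP`, so both
#' moiety sums are conserved by construction. `RP` may be negative (net
#' amoxicillin hydrolysis) only when amoxicillin is present.
#'
#' @param state Numeric length-4 state (mM).
#' @param p Model 2 parameter vector (see [params_model2()]).
#' @param cez Enzyme concentration in mM.
#' @return Named derivative vector (mM/min) in state order.
#' @export
rhs_model2_batch <- function(state, p, cez) {
  state <- check_state(state)
  cez <- check_cez(cez)
  CAB <- state[1]; CAN <- state[2]; CNH <- state[3]
  D <- p[["k3"]] * p[["KN"]] + p[["k4"]] * CNH + p[["k5"]] * CNH
  if (!is.finite(D) || D <= 0)
    stop("model 2 rate denominator is not positive")
  hyd <- p[["k3"]] * p[["KN"]] + p[["k5"]] * CNH
  RP <- cez * (p[["k2"]] * p[["k4"]] * CAB * CNH / p[["KS"]] -
                 p[["km4"]] * CAN * hyd / p[["KP"]]) / D
  RB <- cez * hyd * (p[["k2"]] * CAB / p[["KS"]] -
                       p[["km4"]] * CAN / p[["KP"]]) / D
  setNames(c(-(RP + RB), RP, -RP, RB), STATE_NAMES)
}

#' Piecewise-constant substrate feed schedule
#'
#' Semi-batch operation is represented by volumetric molar feed rates of
#' ester (`fab`) and 6-APA (`fnh`), constant on right-closed intervals
#' between breakpoints (right-continuous step functions). Solid substrate
#' addition is modeled as an equivalent molar feed at constant working
#' volume.
#'
#' @param breaks Nondecreasing numeric vector of interval start times (min),
#'   beginning at 0.
#' @param fab,fnh Nonnegative feed rates (mM/min), one per interval; scalars
#'   are recycled.
#' @return Object of class `amox_feed`.
#' @export
feed_schedule <- function(breaks = 0, fab = 0, fnh = 0) {
  breaks <- as.numeric(breaks)
  n <- length(breaks)
  fab <- rep_len(as.numeric(fab), n)
  fnh <- rep_len(as.numeric(fnh), n)
  if (breaks[1] != 0) stop("feed breakpoints must start at 0")
  if (is.unsorted(breaks, strictly = TRUE) && n > 1)
    stop("feed breakpoints must be strictly increasing")
  if (any(!is.finite(c(fab, fnh))) || any(c(fab, fnh) < 0))
    stop("feed rates must be finite and nonnegative")
  structure(list(breaks = breaks, fab = fab, fnh = fnh),
            class = "amox_feed")
}

#' Evaluate a feed schedule at a time point
#'
#' @param feed `amox_feed` object.
#' @param t Time (min), `t >= 0`.
#' @return Named vector `c(fab, fnh)` in mM/min.
#' @export
feed_rate <- function(feed, t) {
  if (!is.finite(t) || t < 0) stop("feed undefined at t = ", t)
  i <- findInterval(t, feed$breaks)
  c(fab = feed$fab[i], fnh = feed$fnh[i])
}

#' Semi-batch right-hand side for either model
#'
#' The batch derivative with the feed rates added to the ester and 6-APA
#' equations, so the moiety-sum derivatives equal `fab(t)` and `fnh(t)`.
#'
#' @param model `"model1"` or `"model2"`.
#' @param state Numeric length-4 state (mM).
#' @param p Parameter vector for `model`.
#' @param cez Enzyme load (i.u./mL for model 1, mM for model 2).
#' @param feed `amox_feed` schedule.
#' @param t Time (min).
#' @return Named derivative vector (mM/min).
#' @export
rhs_semibatch <- function(model, state, p, cez, feed, t) {
  d <- switch(match.arg(model, c("model1", "model2")),
              model1 = rhs_model1_batch(state, p, cez),
              model2 = rhs_model2_batch(state, p, cez))
  f <- feed_rate(feed, t)
  d[["C_AB"]] <- d[["C_AB"]] + f[["fab"]]
  d[["C_NH"]] <- d[["C_NH"]] + f[["fnh"]]
  d
}
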