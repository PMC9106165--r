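## The coupled right-hand side. .rhsCore is the performance path (plain
## doubles, branch on the hypothesis indices); evaluateRHS is the validated
## user surface. The C implementation in src/ mirrors .rhsCore for the
## integrator; tests cross-check all three against buildRateFunctions.

.rhsCore <- function(y, pr, a, b, cc) {
  Mo <- y[1L]; M <- y[2L]; M1 <- y[3L]; M2 <- y[4L]; Mo1 <- y[5L]
  OB <- y[6L]; OC <- y[7L]; B <- y[8L]; D <- y[9L]
  P <- M1 + Mo1

  if (cc == 1L) {
    p1 <- pr[["p_11"]] * D + pr[["p_12"]] * D * P
    depol1 <- pr[["depol_1"]] * M2
    p21 <- 0; p22 <- pr[["p_2"]] * D
    depol21 <- pr[["depol_2"]]; depol22 <- 0
    p3 <- pr[["p_31"]] * D + pr[["p_32"]] * D * P
    depol3 <- pr[["depol_3"]] * M2
  } else if (cc == 2L) {
    p1 <- pr[["p_11"]] * D + pr[["p_12"]] * D * P
    depol1 <- pr[["depol_1"]] * M2
    p21 <- pr[["p_2"]] * P; p22 <- 0
    depol21 <- pr[["depol_2"]]; depol22 <- 0
    p3 <- pr[["p_31"]] * D + pr[["p_32"]] * D * P
    depol3 <- pr[["depol_3"]] * M2
  } else {
    p1 <- pr[["p_11"]] * D
    depol1 <- 0
    p21 <- 0; p22 <- pr[["p_2"]] * D
    depol21 <- 0; depol22 <- pr[["depol_2"]]
    p3 <- pr[["p_32"]] * M1
    depol3 <- pr[["depol_3"]]
  }

  if (a == 1L) {
    dOCr <- (pr[["d_OC"]] + pr[["d_OC2"]] * P) / (1 + pr[["Inhib_OC"]] * M2)
    deltaOCr <- pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * M2)
  } else if (a == 2L) {
    dOCr <- (pr[["d_OC"]] + pr[["d_OC2"]] * P) / (1 + pr[["Inhib_OC"]] * OB)
    deltaOCr <- pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * OB)
  } else {
    dOCr <- pr[["d_OC"]] * OB / (1 + pr[["Inhib_OC"]] * M2)
    deltaOCr <- pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * M2)
  }

  gammaOBr <- if (b == 1L) pr[["gamma_OB"]] * M2 else pr[["gamma_OB"]] * D

  c(pr[["H_Mo"]] - pr[["delta_Mo"]] * Mo + pr[["I_1"]] * P +
      pr[["I_2"]] * D - p3 * Mo + depol3 * Mo1,
    pr[["H_M"]] - pr[["delta_M"]] * M - dOCr * M - p1 * M - p21 * M +
      depol1 * M1 + depol21 * M2,
    p1 * M - depol1 * M1 - p22 * M1 + depol22 * M2 - pr[["delta_M"]] * M1,
    p21 * M + p22 * M1 - depol21 * M2 - depol22 * M2 - pr[["delta_M"]] * M2,
    p3 * Mo - depol3 * Mo1 - pr[["delta_Mo"]] * Mo1,
    pr[["H_OB"]] * OC + gammaOBr - pr[["delta_OB"]] * OB * B,
    dOCr * M - deltaOCr * OC,
    pr[["Pi_B"]] * (1 + pr[["beta"]] * M2) * OB -
      pr[["delta_B"]] * (1 + pr[["alpha"]] * P) * OC * B,
    -pr[["delta_D"]] * P * D)
}

#' Time derivatives of the coupled model
#'
#' Evaluates the nine coupled equations at a state: monocyte/macrophage
#' replenishment, death, infiltration and polarization; osteoblast
#' replenishment by osteoclast-derived signals plus the injury-phase
#' expansion term; osteoclast formation from naive macrophages and
#' modulated death; bone formation/resorption proportional to osteoblast and
#' osteoclast numbers; exponential-type injury-factor decay driven by
#' pro-inflammatory cells.
#'
#' @param state named numeric state vector (see \code{\link{modelState}});
#'   all components must be non-negative.
#' @param params a \code{ParameterSet}.
#' @param combo a \code{HypothesisCombo}.
#' @return named numeric vector of time derivatives (variable units per day).
#' @examples
#' combo <- parseCombo("a3b2c2")
#' evaluateRHS(baselineState(), defaultParameters(combo), combo)
#' @export
evaluateRHS <- function(state, params, combo) {
  stopifnot(is(params, "ParameterSet"), is(combo, "HypothesisCombo"))
  validObject(params)
  validObject(combo)
  .checkState(state)
  setNames(.rhsCore(unname(state), params@values, combo@a, combo@b, combo@c),
           stateVariables())
}

#' Homeostasis-constrained replenishment parameters
#'
#' Solves the steady-state condition at the uninjured baseline (polarized
#' populations and injury factors at zero) for the replenishment and
#' formation parameters, so that the baseline is an exact fixed point of the
#' system:
#' \itemize{
#'   \item \code{H_Mo = delta_Mo * Mo0};
#'   \item \code{d_OC} from the osteoclast balance
#'     \code{dOC(baseline) * M0 = deltaOC(baseline) * OC0} (under a3 this is
#'     \code{delta_OC * OC0 / (OB0 * M0)}; under a1 \code{delta_OC * OC0 / M0};
#'     under a2 the osteoblast-dependent inhibition factors, nonzero at
#'     baseline, enter the balance);
#'   \item \code{H_M = delta_M * M0 + dOC(baseline) * M0} (death plus the
#'     osteoclastogenic drain);
#'   \item \code{H_OB = delta_OB * OB0 * B0 / OC0};
#'   \item \code{Pi_B = delta_B * OC0 * B0 / OB0}.
#' }
#'
#' @param params a \code{ParameterSet} supplying the lifespans and inhibition
#'   constants.
#' @param combo a \code{HypothesisCombo}.
#' @param baseline uninjured baseline state (M1 = M2 = Mo1 = 0, D = 0, cell
#'   counts > 0).
#' @param derive character, which of the five constrained parameters to fill
#'   (default all). Parameters excluded here keep their current values and
#'   the remaining ones are derived around them (e.g. with \code{d_OC}
#'   treated as free under a1/a2, \code{H_M} still balances the drain its
#'   current value implies).
#' @return a new \code{ParameterSet} with the derived entries replaced.
#' @examples
#' ps <- deriveHomeostaticParameters(parameterSet(), parseCombo("a3b2c2"))
#' parameterValues(ps)[c("H_Mo", "H_M", "H_OB", "d_OC", "Pi_B")]
#' @export
deriveHomeostaticParameters <- function(params, combo,
                                        baseline = baselineState(),
                                        derive = c("H_Mo", "H_M", "H_OB",
                                                   "d_OC", "Pi_B")) {
  stopifnot(is(params, "ParameterSet"), is(combo, "HypothesisCombo"))
  derive <- match.arg(derive, several.ok = TRUE)
  .checkState(baseline)
  if (any(baseline[c("M1", "M2", "Mo1", "D")] != 0))
    stop("baseline must have M1 = M2 = Mo1 = 0 and D = 0")
  Mo0 <- baseline[["Mo"]]; M0 <- baseline[["M"]]
  OB0 <- baseline[["OB"]]; OC0 <- baseline[["OC"]]; B0 <- baseline[["B"]]
  if (any(c(Mo0, M0, OB0, OC0, B0) <= 0))
    stop("homeostasis underdetermined: every baseline divisor must be > 0")

  pr <- params@values
  if ("H_Mo" %in% derive) pr[["H_Mo"]] <- pr[["delta_Mo"]] * Mo0
  if ("d_OC" %in% derive) {
    ## Balance dOC(baseline) * M0 = deltaOC(baseline) * OC0 for d_OC.
    ## At baseline M2 = 0; under a2 the inhibition terms involve OB0.
    kForm <- switch(combo@a, 1, 1 / (1 + pr[["Inhib_OC"]] * OB0), OB0)
    kDeath <- switch(combo@a, 1, 1 + pr[["Inhib_OC2"]] * OB0, 1)
    pr[["d_OC"]] <- pr[["delta_OC"]] * kDeath * OC0 / (kForm * M0)
  }
  if ("H_M" %in% derive) {
    bundle <- buildRateFunctions(combo, new("ParameterSet", values = pr))
    pr[["H_M"]] <- pr[["delta_M"]] * M0 + bundle$dOC(baseline) * M0
  }
  if ("H_OB" %in% derive) pr[["H_OB"]] <- pr[["delta_OB"]] * OB0 * B0 / OC0
  if ("Pi_B" %in% derive) pr[["Pi_B"]] <- pr[["delta_B"]] * OC0 * B0 / OB0
  new("ParameterSet", values = pr)
}
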