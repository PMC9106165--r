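#' Concrete rate functions for a hypothesis combination
#'
#' Instantiates the functional forms selected by the combination as evaluable
#' maps from a model state to a rate. The polarization block (c) supplies the
#' monocyte/macrophage transition rates, the osteoclast block (a) the
#' formation and death rates, and the osteoblast block (b) the injury-phase
#' expansion term.
#'
#' Forms, with P = M1 + Mo1 the pro-inflammatory pool:
#' \describe{
#'   \item{c1}{p1 = p_11 D + p_12 D P; depol1 = depol_1 M2; p21 = 0;
#'     p22 = p_2 D; depol21 = depol_2; depol22 = 0;
#'     p3 = p_31 D + p_32 D P; depol3 = depol_3 M2.}
#'   \item{c2}{as c1 except p21 = p_2 P and p22 = 0.}
#'   \item{c3}{p1 = p_11 D; depol1 = 0; p21 = 0; p22 = p_2 D; depol21 = 0;
#'     depol22 = depol_2; p3 = p_32 M1; depol3 = depol_3 (constant).}
#'   \item{a1}{dOC = (d_OC + d_OC2 P) / (1 + Inhib_OC M2);
#'     deltaOC = delta_OC (1 + Inhib_OC2 M2).}
#'   \item{a2}{as a1 with OB in place of M2 in both inhibition terms.}
#'   \item{a3}{dOC = d_OC OB / (1 + Inhib_OC M2);
#'     deltaOC = delta_OC (1 + Inhib_OC2 M2).}
#'   \item{b1}{gammaOB = gamma_OB M2.}
#'   \item{b2}{gammaOB = gamma_OB D.}
#' }
#'
#' @param combo a \code{HypothesisCombo}.
#' @param params a \code{ParameterSet} (all values >= 0).
#' @return named list of functions, each taking a full named state vector:
#'   \code{p1}, \code{p21}, \code{p22}, \code{p3}, \code{depol1},
#'   \code{depol21}, \code{depol22}, \code{depol3}, \code{dOC},
#'   \code{deltaOC}, \code{gammaOB}.
#' @examples
#' bundle <- buildRateFunctions(parseCombo("a3b2c2"), defaultParameters())
#' bundle$dOC(baselineState())  # = d_OC * OB at M2 = 0
#' @export
buildRateFunctions <- function(combo, params) {
  stopifnot(is(combo, "HypothesisCombo"), is(params, "ParameterSet"))
  validObject(combo)
  validObject(params)
  pr <- params@values

  pool <- function(state) state[["M1"]] + state[["Mo1"]]

  cForms <- switch(combo@c,
    list(  # c1: injury drives both polarization arms
      p1      = function(state) pr[["p_11"]] * state[["D"]] +
                                pr[["p_12"]] * state[["D"]] * pool(state),
      depol1  = function(state) pr[["depol_1"]] * state[["M2"]],
      p21     = function(state) 0,
      p22     = function(state) pr[["p_2"]] * state[["D"]],
      depol21 = function(state) pr[["depol_2"]],
      depol22 = function(state) 0,
      p3      = function(state) pr[["p_31"]] * state[["D"]] +
                                pr[["p_32"]] * state[["D"]] * pool(state),
      depol3  = function(state) pr[["depol_3"]] * state[["M2"]]),
    list(  # c2: pro-inflammatory cells drive anti-inflammatory polarization
      p1      = function(state) pr[["p_11"]] * state[["D"]] +
                                pr[["p_12"]] * state[["D"]] * pool(state),
      depol1  = function(state) pr[["depol_1"]] * state[["M2"]],
      p21     = function(state) pr[["p_2"]] * pool(state),
      p22     = function(state) 0,
      depol21 = function(state) pr[["depol_2"]],
      depol22 = function(state) 0,
      p3      = function(state) pr[["p_31"]] * state[["D"]] +
                                pr[["p_32"]] * state[["D"]] * pool(state),
      depol3  = function(state) pr[["depol_3"]] * state[["M2"]]),
    list(  # c3: resident macrophage polarization, repolarization by uptake
      p1      = function(state) pr[["p_11"]] * state[["D"]],
      depol1  = function(state) 0,
      p21     = function(state) 0,
      p22     = function(state) pr[["p_2"]] * state[["D"]],
      depol21 = function(state) 0,
      depol22 = function(state) pr[["depol_2"]],
      p3      = function(state) pr[["p_32"]] * state[["M1"]],
      depol3  = function(state) pr[["depol_3"]]))

  aForms <- switch(combo@a,
    list(  # a1: constant + pro-inflammatory formation, M2 inhibition
      dOC = function(state)
        (pr[["d_OC"]] + pr[["d_OC2"]] * pool(state)) /
          (1 + pr[["Inhib_OC"]] * state[["M2"]]),
      deltaOC = function(state)
        pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * state[["M2"]])),
    list(  # a2: as a1 with osteoblast (OPG) inhibition
      dOC = function(state)
        (pr[["d_OC"]] + pr[["d_OC2"]] * pool(state)) /
          (1 + pr[["Inhib_OC"]] * state[["OB"]]),
      deltaOC = function(state)
        pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * state[["OB"]])),
    list(  # a3: osteoblast-proportional (RANKL) formation, M2 inhibition
      dOC = function(state)
        pr[["d_OC"]] * state[["OB"]] /
          (1 + pr[["Inhib_OC"]] * state[["M2"]]),
      deltaOC = function(state)
        pr[["delta_OC"]] * (1 + pr[["Inhib_OC2"]] * state[["M2"]])))

  gammaOB <- if (combo@b == 1L)
    function(state) pr[["gamma_OB"]] * state[["M2"]]
  else
    function(state) pr[["gamma_OB"]] * state[["D"]]

  c(cForms, aForms, list(gammaOB = gammaOB))
}
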