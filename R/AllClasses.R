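## S4 classes for the model space, parameters, datasets, fits and
## perturbations. Validity methods enforce the structural invariants; user
## code goes through the constructors and accessors, never the slots.

#' HypothesisCombo: one combination of mechanistic hypotheses
#'
#' A triple (a, b, c) selecting one functional-form variant for each of the
#' three ambiguous aspects of the biology: osteoclast regulation
#' (a in 1..3), osteoblast expansion (b in 1..2) and monocyte/macrophage
#' polarization (c in 1..3). Exactly 18 distinct combinations exist.
#'
#' @slot a integer, osteoclast-regulation variant (1, 2 or 3).
#' @slot b integer, osteoblast-expansion variant (1 or 2).
#' @slot c integer, polarization variant (1, 2 or 3).
#' @seealso \code{\link{hypothesisCombo}}, \code{\link{enumerateCombos}}
#' @export
setClass("HypothesisCombo",
  representation(a = "integer", b = "integer", c = "integer"))

setValidity("HypothesisCombo", function(object) {
  msg <- character()
  if (length(object@a) != 1L || is.na(object@a) || !object@a %in% 1:3)
    msg <- c(msg, "'a' must be 1, 2 or 3")
  if (length(object@b) != 1L || is.na(object@b) || !object@b %in% 1:2)
    msg <- c(msg, "'b' must be 1 or 2")
  if (length(object@c) != 1L || is.na(object@c) || !object@c %in% 1:3)
    msg <- c(msg, "'c' must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' ParameterSet: the rate constants of the coupled model
#'
#' Holds one value per model parameter (see \code{\link{parameterNames}});
#' all values are non-negative. Units follow the model equations: lifespans
#' in 1/day, replenishment rates in cells/day, polarization and modulation
#' rates per cell or per mm^3 per day.
#'
#' @slot values named numeric vector, one entry per parameter in canonical
#'   order.
#' @seealso \code{\link{parameterSet}}, \code{\link{defaultParameters}}
#' @export
setClass("ParameterSet", representation(values = "numeric"))

setValidity("ParameterSet", function(object) {
  msg <- character()
  pn <- parameterNames()
  if (!identical(names(object@values), pn))
    msg <- c(msg, "values must be named exactly by parameterNames(), in order")
  if (anyNA(object@values) || any(object@values < 0))
    msg <- c(msg, "all parameter values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' ParameterManifest: parameter roles and the AIC parameter count
#'
#' For one hypothesis combination, partitions every parameter its rate
#' functions reference into three exclusive roles: fixed from literature,
#' derived from the homeostasis (steady-state) constraint, or free (fitted).
#' The AIC penalty p is the number of free parameters.
#'
#' @slot combo the \code{HypothesisCombo}.
#' @slot free character, parameters fitted by the optimizer.
#' @slot fixed character, literature-valued parameters.
#' @slot derived character, parameters produced by the homeostasis constraint.
#' @seealso \code{\link{parameterManifest}}
#' @export
setClass("ParameterManifest",
  representation(combo = "HypothesisCombo", free = "character",
                 fixed = "character", derived = "character"))

setValidity("ParameterManifest", function(object) {
  msg <- character()
  roles <- c(object@free, object@fixed, object@derived)
  if (anyDuplicated(roles))
    msg <- c(msg, "free, fixed and derived must be disjoint")
  if (!all(roles %in% parameterNames()))
    msg <- c(msg, "unknown parameter name in role lists")
  if (length(msg)) msg else TRUE
})

#' TimeCourseExperiment: longitudinal cell-population measurements
#'
#' A \code{SummarizedExperiment} with observed variables as rows and
#' measurement times as columns. Assays \code{"mean"} and \code{"sd"} hold
#' per-cell means and standard deviations; \code{colData} carries
#' \code{time_days} and the replicate count \code{n}. When built from
#' replicate-level data the long-form replicate table is kept in the
#' \code{replicates} slot (columns time_days, variable, replicate, value).
#' The baseline column (t = 0) supplies initial conditions; residuals are
#' computed over the post-baseline columns only.
#'
#' @slot replicates data.frame of replicate-level observations (possibly
#'   0-row when only summary data are available).
#' @seealso \code{\link{timeCourseExperiment}}, \code{\link{generateReplicates}}
#' @export
setClass("TimeCourseExperiment",
  contains = "SummarizedExperiment",
  representation(replicates = "data.frame"))

setValidity("TimeCourseExperiment", function(object) {
  msg <- character()
  if (!all(c("mean", "sd") %in% names(SummarizedExperiment::assays(object))))
    msg <- c(msg, "assays 'mean' and 'sd' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time_days", "n") %in% names(cd)))
    msg <- c(msg, "colData must carry 'time_days' and 'n'")
  else {
    tt <- cd$time_days
    if (length(tt) && (tt[1] != 0 || is.unsorted(tt, strictly = TRUE)))
      msg <- c(msg, "time_days must start at 0 and be strictly increasing")
  }
  if (!all(rownames(object) %in% observedVariables()))
    msg <- c(msg, "row names must come from observedVariables()")
  sds <- SummarizedExperiment::assays(object)[["sd"]]
  if (length(sds) && ncol(object) > 1 &&
      any(!is.finite(sds[, -1, drop = FALSE]) | sds[, -1, drop = FALSE] <= 0))
    msg <- c(msg, "post-baseline standard deviations must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' StudyDesign: the longitudinal sampling and noise design
#'
#' Defaults emulate the in vivo study layout: measurements at days
#' 0, 1, 2, 3, 7, 14 with 5 animals per time point, eight observed variables,
#' multiplicative Gaussian measurement noise with a 20 percent coefficient of
#' variation, truncated at zero.
#'
#' @slot times numeric, measurement times in days, starting at 0.
#' @slot replicates integer, replicates per time point.
#' @slot variables character, observed variables.
#' @slot noiseModel \code{"gaussian_cv"} (per-variable CV) or
#'   \code{"gaussian_sd"} (per-variable absolute SD).
#' @slot noise named numeric, CV (dimensionless) or SD (variable units) per
#'   observed variable.
#' @seealso \code{\link{studyDesign}}, \code{\link{generateReplicates}}
#' @export
setClass("StudyDesign",
  representation(times = "numeric", replicates = "integer",
                 variables = "character", noiseModel = "character",
                 noise = "numeric"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@times) < 2 || object@times[1] != 0 ||
      is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must start at 0 and be strictly increasing")
  if (object@replicates < 2L)
    msg <- c(msg, "at least 2 replicates are needed to estimate SDs")
  if (!all(object@variables %in% observedVariables()))
    msg <- c(msg, "variables must come from observedVariables()")
  if (!object@noiseModel %in% c("gaussian_cv", "gaussian_sd"))
    msg <- c(msg, "noiseModel must be 'gaussian_cv' or 'gaussian_sd'")
  if (!identical(names(object@noise), object@variables))
    msg <- c(msg, "noise must be named by the observed variables")
  if (anyNA(object@noise) || any(object@noise < 0))
    msg <- c(msg, "noise levels must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FitResult: one fitted model and its goodness-of-fit summaries
#'
#' @slot combo the fitted \code{HypothesisCombo}.
#' @slot params the fitted \code{ParameterSet} (free parameters at their
#'   optimum, derived parameters re-derived, the rest untouched).
#' @slot residuals matrix of standardized residuals, variables x
#'   post-baseline times.
#' @slot J2 weighted least-squares objective (max over variables of the sum
#'   of squared standardized residuals).
#' @slot Jinf Chebyshev objective (largest squared standardized residual).
#' @slot p integer, number of free parameters (the AIC penalty).
#' @slot AIC_J2,AIC_Jinf the criterion 2p + 2J under each objective.
#' @slot nBelowOne integer, residual cells with squared residual < 1.
#' @slot trace numeric, best objective value seen up to each evaluation.
#' @slot objective which objective was minimized ("J2" or "Jinf").
#' @slot seed integer seed that reproduces the fit.
#' @export
setClass("FitResult",
  representation(combo = "HypothesisCombo", params = "ParameterSet",
                 residuals = "matrix", J2 = "numeric", Jinf = "numeric",
                 p = "integer", AIC_J2 = "numeric", AIC_Jinf = "numeric",
                 nBelowOne = "integer", trace = "numeric",
                 objective = "character", seed = "integer"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (object@J2 < object@Jinf - 1e-12)
    msg <- c(msg, "J2 must be >= Jinf")
  if (abs(object@AIC_J2 - (2 * object@p + 2 * object@J2)) > 1e-9 ||
      abs(object@AIC_Jinf - (2 * object@p + 2 * object@Jinf)) > 1e-9)
    msg <- c(msg, "AIC must equal 2p + 2J exactly")
  if (object@nBelowOne < 0L || object@nBelowOne > length(object@residuals))
    msg <- c(msg, "nBelowOne out of range")
  if (length(msg)) msg else TRUE
})

#' PerturbationSpec: in-silico oncostatin-M depletion
#'
#' Scale factors applied to the anti-inflammatory-macrophage effects: the
#' contribution to osteoblast expansion, the mineralization modulation (beta),
#' and osteoclast inhibition (Inhib_OC and Inhib_OC2). The published
#' OSM-depletion experiment reduces these effects by 50, 50 and 80 percent,
#' i.e. factors 0.5, 0.5, 0.2; factors of 1 are the identity.
#'
#' @slot obExpansion numeric scale on the M2-mediated osteoblast formation
#'   channel (gamma_OB under hypothesis b1; no-op under b2, whose expansion
#'   term is injury-driven).
#' @slot mineralization numeric scale on beta.
#' @slot ocInhibition numeric scale on Inhib_OC and Inhib_OC2.
#' @seealso \code{\link{perturbationSpec}}, \code{\link{applyOsmDepletion}}
#' @export
setClass("PerturbationSpec",
  representation(obExpansion = "numeric", mineralization = "numeric",
                 ocInhibition = "numeric"))

setValidity("PerturbationSpec", function(object) {
  f <- c(object@obExpansion, object@mineralization, object@ocInhibition)
  if (length(f) != 3L || anyNA(f) || any(f < 0))
    "all scale factors must be single non-negative numbers"
  else TRUE
})
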