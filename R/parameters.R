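#' Construct a parameter set
#'
#' @param ... named parameter values overriding the published defaults of the
#'   best-fitting model (the a3b2c2 column of the parameter table), or a
#'   single named numeric vector / list.
#' @return a \code{\linkS4class{ParameterSet}}.
#' @examples
#' parameterSet(delta_D = 2e-5)
#' @export
parameterSet <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.numeric(dots[[1]]) || is.list(dots[[1]])))
    dots <- as.list(dots[[1]])
  vals <- .tableDefaults()
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(vals))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    vals[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  new("ParameterSet", values = vals)
}

## Published values for the best-fitting model a3b2c2. d_OC2 (the
## pro-inflammatory contribution to osteoclast formation, used only by the
## a1/a2 variants) has no published value and defaults to 0.
.tableDefaults <- function() {
  c(delta_Mo = 0.45, delta_M = 0.1, delta_OB = 0.32, delta_OC = 0.53,
    gamma_OB = 4.33e4, delta_B = 5.99e-7, Pi_B = 6.018e-7,
    alpha = 0.0022, beta = 0.012,
    H_Mo = 1.5e4, H_M = 1.8e4, H_OB = 0.014,
    d_OC = 5.35e-5, d_OC2 = 0,
    Inhib_OC = 0.016, Inhib_OC2 = 0.052,
    delta_D = 1.71e-5, I_1 = 1.21e-22, I_2 = 6.15e3,
    p_31 = 6.094e-73, p_32 = 3.42e-5, p_11 = 5.86e-9, p_12 = 4.69e-4,
    p_2 = 2.34e-6, depol_1 = 0.37, depol_2 = 1.47e-39, depol_3 = 0.029)
}

#' Default model parameters
#'
#' With \code{combo = NULL}, returns the published parameter values of the
#' best-fitting model verbatim. Given a combination, the replenishment and
#' formation parameters tied to the steady state (H_Mo, H_M, H_OB, d_OC,
#' Pi_B) are replaced by their homeostasis-derived values for that
#' combination, so that the uninjured baseline is an exact fixed point
#' (see \code{\link{deriveHomeostaticParameters}}).
#'
#' @param combo optional \code{HypothesisCombo}.
#' @param baseline baseline state used for the derivation (default
#'   \code{baselineState()}).
#' @return a \code{\linkS4class{ParameterSet}}.
#' @examples
#' parameterValues(defaultParameters())[c("d_OC", "Pi_B")]
#' parameterValues(defaultParameters(parseCombo("a3b2c2")))[c("d_OC", "Pi_B")]
#' @export
defaultParameters <- function(combo = NULL, baseline = baselineState()) {
  ps <- parameterSet()
  if (is.null(combo)) return(ps)
  deriveHomeostaticParameters(ps, combo, baseline = baseline)
}

#' Access the numeric values of a parameter set
#'
#' @param object a \code{ParameterSet} or \code{FitResult}.
#' @return named numeric vector in canonical parameter order.
#' @export
setGeneric("parameterValues", function(object) standardGeneric("parameterValues"))

#' @rdname parameterValues
#' @export
setMethod("parameterValues", "ParameterSet", function(object) object@values)

#' @rdname parameterValues
#' @export
setMethod("parameterValues", "FitResult", function(object)
  object@params@values)

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet with", length(object@values), "parameters\n")
  print(signif(object@values, 4))
})

#' Construct a model state
#'
#' @param ... named state values overriding the data-derived baseline, or a
#'   single named numeric vector. Variables: Mo, M, M1, M2, Mo1, OB, OC
#'   (cells), B, D (mm^3).
#' @return named numeric vector of length 9 in canonical state order.
#' @examples
#' modelState(D = 0)
#' @export
modelState <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.numeric(dots[[1]]))
    dots <- as.list(dots[[1]])
  st <- baselineState(injured = TRUE)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(st))
    if (length(unknown))
      stop("unknown state variable(s): ", paste(unknown, collapse = ", "))
    st[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  .checkState(st)
  st
}

#' Data-derived baseline state
#'
#' The measured day-0 state: Mo = 1.4e4, M = 2.8e4, OB = 3.1e4, OC = 8.8e4
#' cells, B = 0.3530 mm^3, polarized populations at 0. The injury factor D is
#' 2.8 mm^3 immediately after injury and 0 in homeostatic runs.
#'
#' @param injured logical; if \code{TRUE}, D = 2.8, otherwise D = 0.
#' @return named numeric vector of length 9.
#' @export
baselineState <- function(injured = FALSE) {
  c(Mo = 1.4e4, M = 2.8e4, M1 = 0, M2 = 0, Mo1 = 0,
    OB = 3.1e4, OC = 8.8e4, B = 0.3530, D = if (injured) 2.8 else 0)
}

.checkState <- function(state) {
  if (!identical(names(state), stateVariables()))
    stop("state must be named exactly by stateVariables(), in order")
  if (anyNA(state) || any(state < 0))
    stop("all state variables must be finite and >= 0")
  invisible(state)
}
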