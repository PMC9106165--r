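## Per-combination parameter roles. Role assignment follows the provenance of
## the published values: lifespans with literature sources are fixed
## (delta_Mo, delta_M, delta_OC); parameters tied to the baseline steady
## state are derived (H_Mo, H_M, H_OB, Pi_B, and d_OC under a3, where the
## derivation also pins the formation magnitude); everything else the
## combination's rate functions reference is free. Parameters of unused
## hypothesis branches are excluded entirely, so the AIC penalty p counts
## only parameters that can influence the fit.

.usedParameters <- function(combo) {
  common <- c("delta_Mo", "delta_M", "delta_OB", "delta_OC",
              "gamma_OB", "delta_B", "Pi_B", "alpha", "beta",
              "H_Mo", "H_M", "H_OB", "delta_D", "I_1", "I_2")
  aPars <- if (combo@a %in% 1:2)
    c("d_OC", "d_OC2", "Inhib_OC", "Inhib_OC2")
  else
    c("d_OC", "Inhib_OC", "Inhib_OC2")
  cPars <- if (combo@c %in% 1:2)
    c("p_11", "p_12", "p_2", "depol_1", "depol_2", "p_31", "p_32", "depol_3")
  else
    c("p_11", "p_2", "depol_2", "p_32", "depol_3")
  intersect(parameterNames(), c(common, aPars, cPars))
}

#' Parameter manifest of a hypothesis combination
#'
#' Partitions every parameter the combination's rate functions reference into
#' fixed (literature), derived (homeostasis constraint) and free (fitted)
#' roles. The number of free parameters is the AIC penalty p. Under a1/a2 the
#' osteoclast formation magnitude \code{d_OC} is free (the formation term is
#' not osteoblast-proportional there, so homeostasis only sets its starting
#' value) and the pro-inflammatory formation contribution \code{d_OC2}
#' appears as an additional free parameter.
#'
#' @param combo a \code{HypothesisCombo}.
#' @param replenishment \code{"derived"} (default): H_Mo and H_M are set by
#'   the homeostasis constraint, as the model construction describes;
#'   \code{"free"}: they are fitted, matching the provenance labels of the
#'   published parameter table.
#' @return a \code{\linkS4class{ParameterManifest}}.
#' @examples
#' m <- parameterManifest(parseCombo("a3b2c2"))
#' parameterCount(m)  # 18
#' @export
parameterManifest <- function(combo, replenishment = c("derived", "free")) {
  stopifnot(is(combo, "HypothesisCombo"))
  validObject(combo)
  replenishment <- match.arg(replenishment)
  used <- .usedParameters(combo)
  fixed <- c("delta_Mo", "delta_M", "delta_OC")
  derived <- c("H_OB", "Pi_B")
  if (replenishment == "derived") derived <- c(derived, "H_Mo", "H_M")
  if (combo@a == 3L) derived <- c(derived, "d_OC")
  derived <- intersect(parameterNames(), derived)
  free <- setdiff(used, c(fixed, derived))
  new("ParameterManifest", combo = combo,
      free = intersect(parameterNames(), free),
      fixed = fixed, derived = derived)
}

#' @rdname manifest-accessors
#' @export
setGeneric("freeParameters", function(object) standardGeneric("freeParameters"))

#' @rdname manifest-accessors
#' @export
setGeneric("fixedParameters", function(object) standardGeneric("fixedParameters"))

#' @rdname manifest-accessors
#' @export
setGeneric("derivedParameters",
           function(object) standardGeneric("derivedParameters"))

#' @rdname manifest-accessors
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

#' Manifest accessors
#'
#' Role lists and the AIC parameter count p of a
#' \code{\linkS4class{ParameterManifest}}.
#'
#' @param object a \code{ParameterManifest}.
#' @return character vectors of parameter names; \code{parameterCount}
#'   returns the integer number of free parameters.
#' @name manifest-accessors
NULL

#' @rdname manifest-accessors
#' @export
setMethod("freeParameters", "ParameterManifest", function(object) object@free)

#' @rdname manifest-accessors
#' @export
setMethod("fixedParameters", "ParameterManifest", function(object)
  object@fixed)

#' @rdname manifest-accessors
#' @export
setMethod("derivedParameters", "ParameterManifest", function(object)
  object@derived)

#' @rdname manifest-accessors
#' @export
setMethod("parameterCount", "ParameterManifest", function(object)
  length(object@free))

setMethod("show", "ParameterManifest", function(object) {
  cat("ParameterManifest for", comboName(object@combo), "\n")
  cat("  free (p =", length(object@free), "):",
      paste(object@free, collapse = ", "), "\n")
  cat("  fixed:", paste(object@fixed, collapse = ", "), "\n")
  cat("  derived:", paste(object@derived, collapse = ", "), "\n")
})

#' Export a manifest as a table
#'
#' One row per parameter with its role, default value and fitting bounds.
#'
#' @param manifest a \code{ParameterManifest}.
#' @param params parameter set supplying default values (default
#'   \code{defaultParameters(combo)}).
#' @return data.frame with columns combo, parameter, role, default, lower,
#'   upper (bounds are NA for non-free parameters).
#' @export
manifestTable <- function(manifest,
                          params = defaultParameters(manifest@combo)) {
  stopifnot(is(manifest, "ParameterManifest"))
  roles <- c(setNames(rep("free", length(manifest@free)), manifest@free),
             setNames(rep("fixed_literature", length(manifest@fixed)),
                      manifest@fixed),
             setNames(rep("derived_homeostasis", length(manifest@derived)),
                      manifest@derived))
  pn <- intersect(parameterNames(), names(roles))
  bounds <- defaultBounds(params, manifest@free)
  df <- data.frame(combo = comboName(manifest@combo), parameter = pn,
                   role = unname(roles[pn]),
                   default = unname(params@values[pn]),
                   lower = NA_real_, upper = NA_real_)
  df$lower[match(manifest@free, df$parameter)] <- bounds["lower", ]
  df$upper[match(manifest@free, df$parameter)] <- bounds["upper", ]
  df
}
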