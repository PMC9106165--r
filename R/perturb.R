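#' Construct an oncostatin-M depletion specification
#'
#' OSM is an osteogenic cytokine produced by anti-inflammatory macrophages;
#' its genetic depletion is emulated in silico by scaling down the
#' anti-inflammatory-macrophage effects. The defaults reproduce the
#' published experiment: osteoblast expansion reduced by 50 percent,
#' mineralization activity by 50 percent, osteoclast inhibition by 80
#' percent (factors 0.5, 0.5, 0.2).
#'
#' @param obExpansion scale on the M2-mediated osteoblast expansion channel
#'   (gamma_OB under hypothesis b1; under b2 the expansion term is
#'   injury-driven, so this factor is a no-op there).
#' @param mineralization scale on beta, the M2 modulation of bone apposition.
#' @param ocInhibition scale on Inhib_OC and Inhib_OC2 (formation and
#'   lifespan inhibition are both reduced; the published description does not
#'   distinguish them).
#' @return a \code{\linkS4class{PerturbationSpec}}.
#' @export
perturbationSpec <- function(obExpansion = 0.5, mineralization = 0.5,
                             ocInhibition = 0.2) {
  new("PerturbationSpec", obExpansion = as.numeric(obExpansion),
      mineralization = as.numeric(mineralization),
      ocInhibition = as.numeric(ocInhibition))
}

setMethod("show", "PerturbationSpec", function(object) {
  cat(sprintf(paste0("PerturbationSpec: OB expansion x%g, ",
                     "mineralization x%g, OC inhibition x%g\n"),
              object@obExpansion, object@mineralization,
              object@ocInhibition))
})

#' Apply the OSM-depletion perturbation to a parameter set
#'
#' Returns a scaled copy: \code{beta} is multiplied by the mineralization
#' factor, \code{Inhib_OC} and \code{Inhib_OC2} by the osteoclast-inhibition
#' factor, and, under hypothesis b1 only, \code{gamma_OB} by the
#' osteoblast-expansion factor (the b2 expansion term gamma_OB * D carries
#' no M2 contribution to scale). The input is untouched; repeated
#' application composes multiplicatively.
#'
#' @param params a \code{ParameterSet}.
#' @param spec a \code{PerturbationSpec}.
#' @param combo the \code{HypothesisCombo} whose osteoblast-expansion form
#'   decides whether \code{gamma_OB} is scaled.
#' @return a new \code{ParameterSet}.
#' @examples
#' combo <- parseCombo("a3b2c2")
#' osm <- applyOsmDepletion(defaultParameters(combo), perturbationSpec(),
#'                          combo)
#' parameterValues(osm)[c("beta", "Inhib_OC", "Inhib_OC2")]
#' @export
applyOsmDepletion <- function(params, spec = perturbationSpec(), combo) {
  stopifnot(is(params, "ParameterSet"), is(spec, "PerturbationSpec"),
            is(combo, "HypothesisCombo"))
  validObject(spec)
  pr <- params@values
  pr[["beta"]] <- spec@mineralization * pr[["beta"]]
  pr[["Inhib_OC"]] <- spec@ocInhibition * pr[["Inhib_OC"]]
  pr[["Inhib_OC2"]] <- spec@ocInhibition * pr[["Inhib_OC2"]]
  if (combo@b == 1L)
    pr[["gamma_OB"]] <- spec@obExpansion * pr[["gamma_OB"]]
  new("ParameterSet", values = pr)
}

#' Compare two trajectories variable by variable
#'
#' For each state variable and each run, reports the peak value, the time of
#' the peak and the terminal value -- the summaries used to contrast the
#' perturbed and unperturbed injury-repair courses.
#'
#' @param baseline,perturbed trajectories from
#'   \code{\link{simulateTrajectory}} on the same time grid.
#' @return data.frame with columns run, variable, peak, peak_time_days,
#'   terminal (9 variables x 2 runs = 18 rows).
#' @export
compareTrajectories <- function(baseline, perturbed) {
  cols <- c("time_days", stateVariables())
  stopifnot(identical(names(baseline), cols),
            identical(names(perturbed), cols))
  if (!isTRUE(all.equal(baseline$time_days, perturbed$time_days)))
    stop("trajectories must share the same time grid")
  summarizeRun <- function(traj, label) {
    do.call(rbind, lapply(stateVariables(), function(v) {
      x <- traj[[v]]
      k <- which.max(x)
      data.frame(run = label, variable = v, peak = x[k],
                 peak_time_days = traj$time_days[k],
                 terminal = x[length(x)])
    }))
  }
  out <- rbind(summarizeRun(baseline, "baseline"),
               summarizeRun(perturbed, "perturbed"))
  rownames(out) <- NULL
  out
}
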