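#' Construct a study design
#'
#' Defaults emulate the in vivo layout: eight observed variables measured at
#' days 0, 1, 2, 3, 7 and 14 with 5 replicates per time point, and
#' multiplicative Gaussian measurement noise with a coefficient of variation
#' of 0.2 (matching the spread of the published error bars), truncated at
#' zero.
#'
#' @param times measurement times in days, starting at 0.
#' @param replicates replicates per time point (>= 2 so that SDs can be
#'   estimated).
#' @param variables observed variables.
#' @param noiseModel \code{"gaussian_cv"} (noise levels are per-variable CVs)
#'   or \code{"gaussian_sd"} (absolute SDs in variable units).
#' @param noise scalar or per-variable noise level.
#' @return a \code{\linkS4class{StudyDesign}}.
#' @examples
#' studyDesign(noise = 0.1)
#' @export
studyDesign <- function(times = c(0, 1, 2, 3, 7, 14), replicates = 5,
                        variables = observedVariables(),
                        noiseModel = c("gaussian_cv", "gaussian_sd"),
                        noise = 0.2) {
  noiseModel <- match.arg(noiseModel)
  if (anyNA(noise) || any(noise < 0))
    stop("noise levels must be >= 0")
  noise <- setNames(rep(noise, length.out = length(variables)), variables)
  new("StudyDesign", times = as.numeric(times),
      replicates = as.integer(replicates), variables = variables,
      noiseModel = noiseModel, noise = noise)
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@variables), "variables, days",
      paste(object@times, collapse = ", "), "with", object@replicates,
      "replicates/time point\n")
  cat("  noise:", object@noiseModel, "at",
      paste(unique(signif(object@noise, 3)), collapse = "/"), "\n")
})

#' Generate a replicate-level synthetic dataset
#'
#' Simulates the chosen model over the design's time grid and draws each
#' observation as \code{max(0, truth * (1 + cv * eps))} with standard normal
#' \code{eps} under the CV noise model, or \code{max(0, truth + sd * eps)}
#' under the absolute-SD model. Per-cell means and SDs are computed across
#' replicates; the baseline column supplies initial-condition estimates, not
#' residuals. Reproducible for a given seed.
#'
#' @param combo a \code{HypothesisCombo} (the generating model).
#' @param params a \code{ParameterSet}.
#' @param initial initial state (default: injured baseline, D = 2.8).
#' @param design a \code{StudyDesign}.
#' @param seed integer seed.
#' @param sdFloor floor substituted for zero sample SDs (relevant in the
#'   zero-noise limit).
#' @return a \code{\linkS4class{TimeCourseExperiment}} with replicate-level
#'   data attached and the generating trajectory in
#'   \code{metadata()$trajectory}.
#' @examples
#' combo <- parseCombo("a3b2c2")
#' ds <- generateReplicates(combo, defaultParameters(combo),
#'                          design = studyDesign(noise = 0.1), seed = 42)
#' datasetMeans(ds)["OB", ]
#' @export
generateReplicates <- function(combo, params,
                               initial = baselineState(injured = TRUE),
                               design = studyDesign(), seed = 1L,
                               sdFloor = 1e-8) {
  stopifnot(is(combo, "HypothesisCombo"), is(params, "ParameterSet"),
            is(design, "StudyDesign"))
  validObject(design)
  traj <- simulateTrajectory(initial, params, combo, times = design@times)
  truth <- t(as.matrix(traj[, design@variables, drop = FALSE]))
  rownames(truth) <- design@variables

  set.seed(as.integer(seed))
  nRep <- design@replicates
  rows <- vector("list", length(design@times))
  for (k in seq_along(design@times)) {
    eps <- matrix(stats::rnorm(length(design@variables) * nRep),
                  nrow = length(design@variables))
    obs <- if (design@noiseModel == "gaussian_cv")
      truth[, k] * (1 + design@noise * eps)
    else
      truth[, k] + design@noise * eps
    obs <- pmax(obs, 0)
    rows[[k]] <- data.frame(
      time_days = design@times[k],
      variable = rep(design@variables, nRep),
      replicate = rep(seq_len(nRep), each = length(design@variables)),
      value = as.vector(obs))
  }
  reps <- do.call(rbind, rows)
  ds <- summarizeReplicates(reps, sdFloor = sdFloor)
  S4Vectors::metadata(ds)$trajectory <- traj
  S4Vectors::metadata(ds)$combo <- comboName(combo)
  S4Vectors::metadata(ds)$seed <- as.integer(seed)
  ds
}
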