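#' Default fitting bounds for free parameters
#'
#' Published parameter values span roughly seventy orders of magnitude, so a
#' single global box is uninformative; each free parameter instead gets a
#' window of four decades either side of its current value. Parameters whose
#' current value is zero get the wide fallback box [1e-12, 1e6].
#'
#' @param params a \code{ParameterSet} supplying the centre values.
#' @param free character vector of free parameter names.
#' @return numeric matrix with rows \code{lower} and \code{upper}, one
#'   column per free parameter.
#' @export
defaultBounds <- function(params, free) {
  stopifnot(is(params, "ParameterSet"), all(free %in% parameterNames()))
  v <- params@values[free]
  lower <- ifelse(v > 0, v * 1e-4, 1e-12)
  upper <- ifelse(v > 0, v * 1e4, 1e6)
  rbind(lower = setNames(lower, free), upper = setNames(upper, free))
}

#' Optimizer settings for model fitting
#'
#' @param restarts number of Nelder-Mead starts: the first starts from the
#'   supplied parameter values, the rest from log-uniform draws within the
#'   bounds.
#' @param maxit maximum simplex iterations per start.
#' @param seed integer seed making the restart draws (and hence the whole
#'   fit) reproducible.
#' @param penaltyWeight weight of the quadratic exterior penalty that keeps
#'   the search inside the bounds (applied in log10 space, where the search
#'   runs).
#' @param method,rtol integrator used inside the objective. The default is
#'   the stiff-switching LSODA at rtol 1e-6: candidate parameter sets
#'   visited by the search routinely make the osteoclast turnover stiff
#'   (notably under the a2 variants), where an explicit pair slows by two
#'   orders of magnitude, and objective values are far less precise than
#'   even 1e-4 trajectory error.
#' @return list of settings for \code{\link{fitModel}}.
#' @export
fitSettings <- function(restarts = 20L, maxit = 2000L, seed = 1L,
                        penaltyWeight = 1e6, method = "lsoda",
                        rtol = 1e-6) {
  stopifnot(restarts >= 1, maxit >= 1, penaltyWeight > 0, rtol > 0)
  list(restarts = as.integer(restarts), maxit = as.integer(maxit),
       seed = as.integer(seed), penaltyWeight = penaltyWeight,
       method = method, rtol = rtol)
}

.boundsPenalty <- function(thetaLog, logLower, logUpper, w) {
  over <- pmax(0, thetaLog - logUpper, logLower - thetaLog)
  w * sum(over^2)
}

#' Fit one hypothesis combination to a time-course dataset
#'
#' Minimizes the chosen objective (J2 or Jinf) of the standardized residuals
#' over the free parameters, in log10 space, with a derivative-free
#' Nelder-Mead simplex, multiple seeded restarts and a quadratic exterior
#' penalty enforcing the bounds. Homeostasis-derived parameters are
#' re-derived at every candidate so the uninjured baseline stays a fixed
#' point throughout the search. The dataset's baseline means supply the
#' initial conditions; the injury factor, which is not observed, starts at
#' \code{D0}.
#'
#' @param combo a \code{HypothesisCombo}.
#' @param dataset a \code{TimeCourseExperiment}.
#' @param manifest parameter roles (default \code{parameterManifest(combo)}).
#' @param params starting parameter values (default
#'   \code{defaultParameters(combo)}).
#' @param objective \code{"Jinf"} (default, as in the published ranking) or
#'   \code{"J2"}.
#' @param free free parameters to fit; defaults to the manifest's free list.
#'   A subset restricts the search (remaining free parameters stay at their
#'   values in \code{params}).
#' @param bounds bounds matrix as returned by \code{\link{defaultBounds}}.
#' @param settings optimizer settings from \code{\link{fitSettings}}.
#' @param D0 initial injury-factor level in mm^3.
#' @return a \code{\linkS4class{FitResult}}.
#' @examples
#' \donttest{
#' combo <- parseCombo("a3b2c2")
#' ds <- generateReplicates(combo, defaultParameters(combo),
#'                          design = studyDesign(noise = 0.1), seed = 1)
#' fit <- fitModel(combo, ds, free = c("gamma_OB", "delta_D"),
#'                 settings = fitSettings(restarts = 2, maxit = 200))
#' }
#' @export
fitModel <- function(combo, dataset, manifest = parameterManifest(combo),
                     params = defaultParameters(combo),
                     objective = c("Jinf", "J2"),
                     free = freeParameters(manifest),
                     bounds = defaultBounds(params, free),
                     settings = fitSettings(), D0 = 2.8) {
  stopifnot(is(combo, "HypothesisCombo"),
            is(dataset, "TimeCourseExperiment"),
            is(manifest, "ParameterManifest"),
            is(params, "ParameterSet"))
  objective <- match.arg(objective)
  if (!identical(comboName(manifest@combo), comboName(combo)))
    stop("manifest was built for ", comboName(manifest@combo))
  if (!all(free %in% parameterNames()))
    stop("unknown free parameter(s)")
  objFun <- if (objective == "J2") objectiveJ2 else objectiveJinf

  initial <- baselineState(injured = TRUE)
  obs <- rownames(dataset)
  initial[obs] <- datasetMeans(dataset)[, 1]
  initial[["D"]] <- D0
  homeoBase <- initial
  homeoBase[c("M1", "M2", "Mo1", "D")] <- 0
  deriveSet <- setdiff(manifest@derived, free)
  times <- datasetTimes(dataset)

  buildParams <- function(thetaLog) {
    pr <- params@values
    pr[free] <- 10^thetaLog
    ps <- new("ParameterSet", values = pr)
    if (length(deriveSet))
      ps <- deriveHomeostaticParameters(ps, combo, baseline = homeoBase,
                                        derive = deriveSet)
    ps
  }
  rawObjective <- function(ps) {
    ## any failure mode (step-size collapse, truncated output, non-finite
    ## states) rejects the candidate
    tryCatch(suppressWarnings({
      traj <- simulateTrajectory(initial, ps, combo, times = times,
                                 method = settings$method,
                                 rtol = settings$rtol,
                                 atol = settings$rtol * 1e-2 * .stateScales())
      objFun(residualMatrix(traj, dataset))
    }), error = function(e) NA_real_)
  }

  p <- length(free)
  if (p == 0L) {
    ps <- if (length(deriveSet))
      deriveHomeostaticParameters(params, combo, baseline = homeoBase,
                                  derive = deriveSet)
    else params
    J <- rawObjective(ps)
    if (is.na(J)) stop("integration failed at the supplied parameters")
    return(.makeFitResult(combo, ps, dataset, initial, times, p = 0L,
                          trace = J, objective = objective,
                          seed = settings$seed, settings = settings))
  }

  logLower <- log10(bounds["lower", free])
  logUpper <- log10(bounds["upper", free])
  w <- settings$penaltyWeight
  trace <- numeric(0)
  bestSoFar <- Inf
  penalized <- function(thetaLog) {
    J <- rawObjective(buildParams(thetaLog))
    val <- if (is.na(J)) 1e12 else
      J + .boundsPenalty(thetaLog, logLower, logUpper, w)
    bestSoFar <<- min(bestSoFar, val)
    trace <<- c(trace, bestSoFar)
    val
  }

  start0 <- params@values[free]
  theta0 <- ifelse(start0 > 0, log10(start0), logLower)
  theta0 <- pmin(pmax(theta0, logLower), logUpper)
  set.seed(settings$seed)
  starts <- vector("list", settings$restarts)
  starts[[1]] <- theta0
  for (k in seq_len(settings$restarts - 1L))
    starts[[k + 1L]] <- runif(p, logLower, logUpper)

  bestVal <- Inf
  bestTheta <- theta0
  for (st in starts) {
    res <- if (p == 1L) {
      opt <- stats::optimize(function(x) penalized(x),
                             lower = logLower, upper = logUpper,
                             tol = 1e-8)
      list(par = opt$minimum, value = opt$objective)
    } else {
      stats::optim(st, penalized, method = "Nelder-Mead",
                   control = list(maxit = settings$maxit,
                                  reltol = 1e-10))
    }
    if (res$value < bestVal) {
      bestVal <- res$value
      bestTheta <- res$par
    }
  }
  if (!is.finite(bestVal) || bestVal >= 1e12)
    stop("all optimizer starts failed to integrate; check parameters/bounds")

  psBest <- buildParams(bestTheta)
  .makeFitResult(combo, psBest, dataset, initial, times, p = p,
                 trace = trace, objective = objective, seed = settings$seed,
                 settings = settings)
}

.makeFitResult <- function(combo, params, dataset, initial, times, p,
                           trace, objective, seed, settings = fitSettings()) {
  traj <- simulateTrajectory(initial, params, combo, times = times,
                             method = settings$method, rtol = settings$rtol,
                             atol = settings$rtol * 1e-2 * .stateScales())
  r <- residualMatrix(traj, dataset)
  J2 <- objectiveJ2(r)
  Jinf <- objectiveJinf(r)
  new("FitResult", combo = combo, params = params, residuals = r,
      J2 = J2, Jinf = Jinf, p = as.integer(p),
      AIC_J2 = computeAIC(J2, p), AIC_Jinf = computeAIC(Jinf, p),
      nBelowOne = countResidualsBelowOne(r),
      trace = trace, objective = objective, seed = as.integer(seed))
}

setMethod("show", "FitResult", function(object) {
  cat("FitResult", comboName(object@combo),
      sprintf("(objective %s, p = %d)\n", object@objective, object@p))
  cat(sprintf("  J2 = %.4g, Jinf = %.4g, AIC_J2 = %.4g, AIC_Jinf = %.4g\n",
              object@J2, object@Jinf, object@AIC_J2, object@AIC_Jinf))
  cat(sprintf("  residuals < 1: %d/%d\n", object@nBelowOne,
              length(object@residuals)))
})

#' One-row goodness-of-fit summary of a fit
#'
#' @param fit a \code{FitResult}.
#' @return data.frame with columns combo, p, J2, J_inf, AIC_J2, AIC_Jinf,
#'   n_below_one, objective.
#' @export
fitSummary <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  data.frame(combo = comboName(fit@combo), p = fit@p, J2 = fit@J2,
             J_inf = fit@Jinf, AIC_J2 = fit@AIC_J2,
             AIC_Jinf = fit@AIC_Jinf, n_below_one = fit@nBelowOne,
             objective = fit@objective)
}

#' Residual matrix of a fit
#'
#' @param fit a \code{FitResult}.
#' @return standardized residual matrix, variables x post-baseline times.
#' @export
fitResiduals <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  fit@residuals
}

#' Best-so-far objective trace of a fit
#'
#' @param fit a \code{FitResult}.
#' @return numeric vector, non-increasing across evaluations.
#' @export
fitTrace <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  fit@trace
}

#' Rank fitted models by AIC
#'
#' Ascending by the chosen AIC; ties broken by descending count of residuals
#' within the error bar, then by combination name.
#'
#' @param fits list of \code{FitResult} objects, one per combination.
#' @param by ranking criterion, \code{"AIC_Jinf"} (default) or
#'   \code{"AIC_J2"}.
#' @return data.frame (one row per model) sorted best first.
#' @export
rankModels <- function(fits, by = c("AIC_Jinf", "AIC_J2")) {
  by <- match.arg(by)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, is, logical(1), "FitResult")))
  tab <- do.call(rbind, lapply(fits, fitSummary))
  rownames(tab) <- NULL
  if (anyDuplicated(tab$combo))
    stop("duplicate combination(s) in fits: ",
         paste(unique(tab$combo[duplicated(tab$combo)]), collapse = ", "))
  ord <- order(tab[[by]], -tab$n_below_one, tab$combo)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a ranking table to a tab-separated file
#'
#' @param ranking data.frame from \code{\link{rankModels}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
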