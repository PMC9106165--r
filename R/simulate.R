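## Trajectory integration. Default engine is the compiled RHS via deSolve's
## Dormand-Prince 4(5) pair ("ode45"); the pure-R engine integrates the same
## equations through .rhsCore and exists as a reference path for testing.

.solverParms <- function(params, combo) {
  c(a = combo@a, b = combo@b, c = combo@c, params@values)
}

.defaultAtol <- function(rtol) {
  ## absolute tolerance scaled per variable by its baseline magnitude
  1e-10 * .stateScales()
}

#' Integrate the coupled model
#'
#' Adaptive embedded Runge-Kutta 4(5) (Dormand-Prince) integration of the
#' nine coupled equations. The equations are structurally non-negative
#' (every loss term is proportional to the variable it depletes), so states
#' are integrated unclipped; output values inside the solver's error band
#' below zero are clamped to 0, and anything more negative raises an error.
#'
#' The injury transient couples fast polarization/turnover rates (up to
#' hundreds per day) to the two-week healing window, so local solver error
#' is amplified by roughly three orders of magnitude along the trajectory;
#' the tight default tolerances keep the global error near 1e-5 relative
#' (verified against converged fixed-step integration).
#'
#' @param initial named numeric initial state (see \code{\link{modelState}});
#'   returned exactly at t = 0.
#' @param params a \code{ParameterSet}.
#' @param combo a \code{HypothesisCombo}.
#' @param times numeric vector of output times in days, starting at 0,
#'   strictly increasing.
#' @param rtol relative solver tolerance (default 1e-8).
#' @param atol absolute tolerance per variable; default 1e-10 scaled by each
#'   variable's baseline magnitude.
#' @param engine \code{"compiled"} (C right-hand side, default) or
#'   \code{"R"}.
#' @param method any \code{deSolve} method name; default \code{"ode45"}.
#' @param maxsteps maximum solver steps between output times; the default
#'   accommodates the stiffest hypothesis variants (osteoblast-proportional
#'   osteoclast inhibition under a2).
#' @return data.frame with columns \code{time_days} and the nine state
#'   variables.
#' @examples
#' combo <- parseCombo("a3b2c2")
#' traj <- simulateTrajectory(baselineState(injured = TRUE),
#'                            defaultParameters(combo), combo,
#'                            times = c(0, 1, 2, 3, 7, 14))
#' traj$B
#' @export
simulateTrajectory <- function(initial, params, combo,
                               times = c(0, 1, 2, 3, 7, 14),
                               rtol = 1e-8, atol = NULL,
                               engine = c("compiled", "R"),
                               method = "ode45", maxsteps = 1e6) {
  stopifnot(is(params, "ParameterSet"), is(combo, "HypothesisCombo"))
  engine <- match.arg(engine)
  .checkState(initial)
  if (length(times) < 2 || times[1] != 0 ||
      is.unsorted(times, strictly = TRUE))
    stop("times must start at 0 and be strictly increasing")
  if (is.null(atol)) atol <- .defaultAtol(rtol)

  parms <- .solverParms(params, combo)
  y0 <- unname(initial)
  out <- if (engine == "compiled") {
    deSolve::ode(y = y0, times = times, func = "osteomac_derivs",
                 parms = parms, dllname = "osteomac",
                 initfunc = "osteomac_initmod",
                 method = method, rtol = rtol, atol = unname(atol),
                 maxsteps = maxsteps)
  } else {
    pr <- params@values
    a <- combo@a; b <- combo@b; cc <- combo@c
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, p) list(.rhsCore(y, pr, a, b, cc)),
                 parms = NULL, method = method, rtol = rtol,
                 atol = unname(atol), maxsteps = maxsteps)
  }

  if (nrow(out) < length(times) || anyNA(out) || any(!is.finite(out)) ||
      !isTRUE(all.equal(out[, 1], times)))
    stop("integration failed near t = ",
         signif(out[max(1, nrow(out)), 1], 6), " days")

  states <- out[, -1, drop = FALSE]
  negTol <- unname(atol + rtol * .stateScales())
  tooNegative <- sweep(states, 2, -negTol, `<`)
  if (any(tooNegative)) {
    bad <- which(tooNegative, arr.ind = TRUE)[1, ]
    stop("state '", stateVariables()[bad[2]],
         "' fell below the non-negativity band at t = ",
         signif(out[bad[1], 1], 6), " days")
  }
  states[states < 0] <- 0
  states[1, ] <- y0  # t = 0 row is the initial condition, exactly

  traj <- data.frame(time_days = out[, 1], states)
  names(traj) <- c("time_days", stateVariables())
  traj
}

#' Write a trajectory to CSV
#'
#' Columns \code{time_days, Mo, M, M1, M2, Mo1, OB, OC, B, D}, full
#' precision.
#'
#' @param trajectory data.frame from \code{\link{simulateTrajectory}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(identical(names(trajectory), c("time_days", stateVariables())))
  write.csv(format(trajectory, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
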