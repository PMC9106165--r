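#' Standardized residual matrix
#'
#' \code{r_ij = (f_j(t_i) - D_ij) / sigma_ij} over the eight observed
#' variables at the post-baseline time points; the baseline column supplies
#' initial conditions, not residuals (8 variables x 5 post-baseline times =
#' 40 cells under the default design). The printed objective writes a
#' time-indexed sigma; this implementation uses the per-variable per-time
#' SD across replicates, the only reading consistent with the mixed units of
#' the observed variables.
#'
#' @param trajectory data.frame from \code{\link{simulateTrajectory}},
#'   evaluated at (at least) the dataset's times.
#' @param dataset a \code{TimeCourseExperiment} with positive post-baseline
#'   SDs.
#' @return numeric matrix, variables x post-baseline times (dimensionless).
#' @export
residualMatrix <- function(trajectory, dataset) {
  stopifnot(is(dataset, "TimeCourseExperiment"))
  vars <- rownames(dataset)
  missing <- setdiff(vars, names(trajectory))
  if (length(missing))
    stop("trajectory lacks variable(s): ", paste(missing, collapse = ", "))
  times <- datasetTimes(dataset)
  post <- times[times > 0]
  idx <- match(post, trajectory$time_days)
  if (anyNA(idx))
    stop("trajectory not evaluated at day(s): ",
         paste(post[is.na(idx)], collapse = ", "))
  f <- t(as.matrix(trajectory[idx, vars, drop = FALSE]))
  keep <- times > 0
  D <- datasetMeans(dataset)[, keep, drop = FALSE]
  S <- datasetSDs(dataset)[, keep, drop = FALSE]
  if (any(S <= 0)) stop("post-baseline SDs must be > 0")
  r <- (f - D) / S
  dimnames(r) <- dimnames(D)
  r
}

#' Weighted least-squares objective J2
#'
#' The maximum over observed variables of the per-variable sum of squared
#' standardized residuals. Taking the max (rather than the total sum)
#' ensures every variable is fitted with equal relative importance.
#'
#' @param r residual matrix (variables x times), finite.
#' @return scalar >= 0.
#' @examples
#' objectiveJ2(rbind(c(1, 2, 3), c(0, 1, 0)))  # max(14, 1) = 14
#' @export
objectiveJ2 <- function(r) {
  stopifnot(all(is.finite(r)))
  max(rowSums(r^2))
}

#' Chebyshev objective Jinf
#'
#' The largest squared standardized residual over all variables and time
#' points, guarding against fits that sacrifice individual time points.
#'
#' @param r residual matrix (variables x times), finite.
#' @return scalar >= 0.
#' @examples
#' objectiveJinf(rbind(c(1, 2, 3), c(0, 1, 0)))  # 9
#' @export
objectiveJinf <- function(r) {
  stopifnot(all(is.finite(r)))
  max(r^2)
}

#' Akaike information criterion, 2p + 2J
#'
#' @param J objective value (J2 or Jinf), >= 0.
#' @param p number of free parameters, >= 0.
#' @return scalar, \code{2 * p + 2 * J}.
#' @export
computeAIC <- function(J, p) {
  stopifnot(J >= 0, p >= 0, p == round(p))
  2 * p + 2 * J
}

#' Count residuals within the experimental error bar
#'
#' The number of residual cells with squared standardized residual strictly
#' below 1, i.e. time points where the model lies within one SD of the data.
#'
#' @param r residual matrix, finite.
#' @return integer in [0, number of cells].
#' @examples
#' countResidualsBelowOne(c(0.5, 1.0, 1.5, 0.99))  # 2
#' @export
countResidualsBelowOne <- function(r) {
  stopifnot(all(is.finite(r)))
  sum(r^2 < 1)
}
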