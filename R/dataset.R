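#' Construct a time-course experiment
#'
#' @param mean,sd numeric matrices, observed variables x times. Row names
#'   must come from \code{\link{observedVariables}}; the first column is the
#'   baseline (t = 0).
#' @param times numeric measurement times in days, starting at 0.
#' @param n replicate count per time point (scalar or vector).
#' @param replicates optional long-form replicate table (columns time_days,
#'   variable, replicate, value).
#' @return a \code{\linkS4class{TimeCourseExperiment}}.
#' @seealso \code{\link{generateReplicates}}, \code{\link{summarizeReplicates}}
#' @export
timeCourseExperiment <- function(mean, sd, times, n,
                                 replicates = data.frame()) {
  stopifnot(is.matrix(mean), is.matrix(sd),
            identical(dim(mean), dim(sd)),
            ncol(mean) == length(times))
  n <- as.integer(rep(n, length.out = length(times)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(mean = mean, sd = sd),
    colData = S4Vectors::DataFrame(time_days = times, n = n,
                                   row.names = paste0("d", times)))
  new("TimeCourseExperiment", se, replicates = replicates)
}

#' @rdname dataset-accessors
#' @export
setGeneric("datasetMeans", function(object) standardGeneric("datasetMeans"))

#' @rdname dataset-accessors
#' @export
setGeneric("datasetSDs", function(object) standardGeneric("datasetSDs"))

#' @rdname dataset-accessors
#' @export
setGeneric("datasetTimes", function(object) standardGeneric("datasetTimes"))

#' @rdname dataset-accessors
#' @export
setGeneric("datasetReplicates",
           function(object) standardGeneric("datasetReplicates"))

#' Dataset accessors
#'
#' Means, standard deviations, measurement times and the replicate-level
#' table of a \code{\linkS4class{TimeCourseExperiment}}.
#'
#' @param object a \code{TimeCourseExperiment}.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
setMethod("datasetMeans", "TimeCourseExperiment", function(object)
  SummarizedExperiment::assays(object)[["mean"]])

#' @rdname dataset-accessors
#' @export
setMethod("datasetSDs", "TimeCourseExperiment", function(object)
  SummarizedExperiment::assays(object)[["sd"]])

#' @rdname dataset-accessors
#' @export
setMethod("datasetTimes", "TimeCourseExperiment", function(object)
  SummarizedExperiment::colData(object)$time_days)

#' @rdname dataset-accessors
#' @export
setMethod("datasetReplicates", "TimeCourseExperiment", function(object)
  object@replicates)

setMethod("show", "TimeCourseExperiment", function(object) {
  cat("TimeCourseExperiment:", nrow(object), "variables x",
      ncol(object), "time points (days",
      paste(datasetTimes(object), collapse = ", "), ")\n")
  cat("  replicate-level observations:", nrow(object@replicates), "\n")
})

#' Summarize replicate-level observations into means and SDs
#'
#' Per (variable, time) cell: sample mean and sample standard deviation
#' (n - 1 denominator). Cells whose SD is zero (e.g. noise-free synthetic
#' data) are replaced by \code{sdFloor} with a warning, since the fitting
#' objectives divide by the SD.
#'
#' @param replicates long-form data.frame with columns time_days, variable,
#'   replicate, value; at least 2 replicates per cell.
#' @param sdFloor positive floor substituted for zero SDs.
#' @return a \code{\linkS4class{TimeCourseExperiment}} carrying the
#'   replicate table.
#' @examples
#' reps <- data.frame(time_days = 0, variable = "OB",
#'                    replicate = 1:3, value = c(1, 2, 3))
#' # means/SDs of a single-variable design: mean 2, sd 1
#' @export
summarizeReplicates <- function(replicates, sdFloor = 1e-8) {
  req <- c("time_days", "variable", "replicate", "value")
  if (!all(req %in% names(replicates)))
    stop("replicate table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(replicates[, c("time_days", "variable", "replicate")]))
    stop("duplicate (time_days, variable, replicate) keys")
  if (!all(replicates$variable %in% observedVariables()))
    stop("unknown variable(s): ",
         paste(setdiff(unique(replicates$variable), observedVariables()),
               collapse = ", "))
  stopifnot(sdFloor > 0)

  times <- sort(unique(replicates$time_days))
  vars <- intersect(observedVariables(), unique(replicates$variable))
  counts <- table(replicates$variable, replicates$time_days)
  if (any(counts < 2))
    stop("every (variable, time) cell needs at least 2 replicates")

  meanM <- matrix(NA_real_, length(vars), length(times),
                  dimnames = list(vars, paste0("d", times)))
  sdM <- meanM
  for (v in vars) for (k in seq_along(times)) {
    x <- replicates$value[replicates$variable == v &
                            replicates$time_days == times[k]]
    meanM[v, k] <- mean(x)
    sdM[v, k] <- stats::sd(x)
  }
  if (any(sdM == 0)) {
    warning("zero standard deviation in ", sum(sdM == 0),
            " cell(s); replaced by the floor ", sdFloor)
    sdM[sdM == 0] <- sdFloor
  }
  nRep <- vapply(times, function(tt)
    max(counts[, as.character(tt)]), numeric(1))
  timeCourseExperiment(meanM, sdM, times, nRep, replicates = replicates)
}

#' Read a time-course dataset from CSV
#'
#' Accepts the long replicate-level dialect (columns time_days, variable,
#' replicate, value) or the summary dialect (time_days, variable, mean, sd).
#'
#' @param path CSV file path.
#' @param sdFloor floor for zero SDs when summarizing replicate-level input.
#' @return a \code{\linkS4class{TimeCourseExperiment}}.
#' @export
readDataset <- function(path, sdFloor = 1e-8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("time_days", "variable", "replicate", "value") %in% names(df)))
    return(summarizeReplicates(df, sdFloor = sdFloor))
  if (!all(c("time_days", "variable", "mean", "sd") %in% names(df)))
    stop("unrecognized dataset dialect: need columns ",
         "(time_days, variable, replicate, value) or ",
         "(time_days, variable, mean, sd)")
  if (anyDuplicated(df[, c("time_days", "variable")]))
    stop("duplicate (time_days, variable) keys")
  if (!all(df$variable %in% observedVariables()))
    stop("unknown variable(s): ",
         paste(setdiff(unique(df$variable), observedVariables()),
               collapse = ", "))
  bad <- df$sd <= 0 & df$time_days > 0
  if (any(bad))
    stop("non-positive SD for variable '", df$variable[bad][1],
         "' at day ", df$time_days[bad][1])
  times <- sort(unique(df$time_days))
  vars <- intersect(observedVariables(), unique(df$variable))
  meanM <- matrix(NA_real_, length(vars), length(times),
                  dimnames = list(vars, paste0("d", times)))
  sdM <- meanM
  idx <- cbind(match(df$variable, vars), match(df$time_days, times))
  meanM[idx] <- df$mean
  sdM[idx] <- df$sd
  if (anyNA(meanM) || anyNA(sdM))
    stop("incomplete summary table: every (variable, time) cell is required")
  nRep <- if ("n" %in% names(df)) df$n[match(times, df$time_days)] else 0L
  timeCourseExperiment(meanM, sdM, times, nRep)
}

#' Write a time-course dataset to CSV
#'
#' @param dataset a \code{TimeCourseExperiment}.
#' @param path output CSV path.
#' @param form \code{"long"} (replicate-level; requires replicate data) or
#'   \code{"summary"} (means and SDs).
#' @return the path, invisibly.
#' @export
writeDataset <- function(dataset, path, form = c("summary", "long")) {
  stopifnot(is(dataset, "TimeCourseExperiment"))
  form <- match.arg(form)
  df <- if (form == "long") {
    if (!nrow(dataset@replicates))
      stop("dataset carries no replicate-level data")
    dataset@replicates
  } else {
    times <- datasetTimes(dataset)
    data.frame(
      time_days = rep(times, each = nrow(dataset)),
      variable = rep(rownames(dataset), length(times)),
      mean = as.vector(datasetMeans(dataset)),
      sd = as.vector(datasetSDs(dataset)),
      n = rep(SummarizedExperiment::colData(dataset)$n, each = nrow(dataset)))
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
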