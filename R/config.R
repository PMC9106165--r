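## Run configuration: a validated, JSON-serializable bundle of every knob a
## pipeline run needs. Unknown keys are rejected so typos fail loudly.

.configDefaults <- function() {
  list(
    combo = "a3b2c2",
    parameters = list(),          # named overrides of the published defaults
    replenishment = "derived",    # or "free": H_Mo/H_M fitted
    freeOverride = character(),   # optional replacement free-parameter list
    D0 = 2.8,
    solver = list(rtol = 1e-6, method = "ode45"),
    optimizer = list(objective = "Jinf", restarts = 20L, maxit = 2000L,
                     seed = 1L, penaltyWeight = 1e6),
    design = list(times = c(0, 1, 2, 3, 7, 14), replicates = 5L,
                  noiseModel = "gaussian_cv", noise = 0.2, seed = 1L),
    perturbation = list(obExpansion = 0.5, mineralization = 0.5,
                        ocInhibition = 0.2),
    outputDir = ".")
}

.validateConfig <- function(cfg) {
  defaults <- .configDefaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("solver", "optimizer", "design", "perturbation")) {
    extra <- setdiff(names(cfg[[key]]), names(defaults[[key]]))
    if (length(extra))
      stop("unknown config key(s) under '", key, "': ",
           paste(extra, collapse = ", "))
  }
  full <- utils::modifyList(defaults, cfg)
  parseCombo(full$combo)  # errors on invalid combination
  if (length(full$parameters)) {
    bad <- setdiff(names(full$parameters), parameterNames())
    if (length(bad))
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    if (any(unlist(full$parameters) < 0))
      stop("parameter overrides must be >= 0")
  }
  if (!full$replenishment %in% c("derived", "free"))
    stop("replenishment must be 'derived' or 'free'")
  if (length(full$freeOverride) &&
      !all(full$freeOverride %in% parameterNames()))
    stop("unknown parameter in freeOverride")
  if (full$D0 < 0) stop("D0 must be >= 0")
  if (full$solver$rtol <= 0) stop("solver rtol must be > 0")
  if (!full$optimizer$objective %in% c("J2", "Jinf"))
    stop("optimizer objective must be 'J2' or 'Jinf'")
  if (full$optimizer$restarts < 1) stop("optimizer restarts must be >= 1")
  if (full$design$replicates < 2) stop("design replicates must be >= 2")
  if (any(unlist(full$design$noise) < 0)) stop("design noise must be >= 0")
  if (any(unlist(full$perturbation) < 0))
    stop("perturbation factors must be >= 0")
  full$optimizer$restarts <- as.integer(full$optimizer$restarts)
  full$optimizer$maxit <- as.integer(full$optimizer$maxit)
  full$optimizer$seed <- as.integer(full$optimizer$seed)
  full$design$replicates <- as.integer(full$design$replicates)
  full$design$seed <- as.integer(full$design$seed)
  structure(full, class = "osteomacConfig")
}

#' Build a run configuration
#'
#' @param ... configuration entries overriding the defaults (the published
#'   best-fitting model a3b2c2, its parameter table, the in vivo study
#'   design, the default solver and optimizer settings). Unknown keys are
#'   rejected.
#' @return a validated config (list with class \code{osteomacConfig}).
#' @examples
#' cfg <- runConfig(combo = "a2b1c3")
#' cfg$combo
#' @export
runConfig <- function(...) {
  .validateConfig(list(...))
}

#' Load a run configuration from JSON
#'
#' Missing entries are filled with defaults; unknown keys, malformed
#' combination names and out-of-range values raise errors naming the
#' offending key.
#'
#' @param path JSON file path.
#' @return a validated config.
#' @export
loadConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .validateConfig(cfg)
}

#' Save a run configuration to JSON
#'
#' @param config a config from \code{\link{runConfig}} or
#'   \code{\link{loadConfig}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "osteomacConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Materialize the model objects a config describes
#'
#' @param config a validated config.
#' @return list with elements \code{combo}, \code{params} (overrides applied,
#'   homeostasis derivation applied for the combo), \code{manifest},
#'   \code{design}, \code{settings} and \code{spec} (the perturbation).
#' @export
configObjects <- function(config) {
  stopifnot(inherits(config, "osteomacConfig"))
  combo <- parseCombo(config$combo)
  manifest <- parameterManifest(combo, replenishment = config$replenishment)
  params <- do.call(parameterSet, config$parameters)
  params <- deriveHomeostaticParameters(params, combo,
                                        derive = manifest@derived)
  design <- studyDesign(times = config$design$times,
                        replicates = config$design$replicates,
                        noiseModel = config$design$noiseModel,
                        noise = config$design$noise)
  settings <- fitSettings(restarts = config$optimizer$restarts,
                          maxit = config$optimizer$maxit,
                          seed = config$optimizer$seed,
                          penaltyWeight = config$optimizer$penaltyWeight)
  spec <- perturbationSpec(config$perturbation$obExpansion,
                           config$perturbation$mineralization,
                           config$perturbation$ocInhibition)
  list(combo = combo, params = params, manifest = manifest, design = design,
       settings = settings, spec = spec)
}
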