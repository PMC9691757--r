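CONFIG_SECTIONS <- c("scenario", "sensitivity", "simulation", "output")

#' Default run configuration
#'
#' The configuration a run uses when no config file (or an empty one) is
#' supplied: the reference clinic parameters, both adoption scenarios, the
#' standard 50%-up/50%-down sensitivity multipliers, and a Bernoulli demand
#' simulation whose per-period capacity equals the capacity-neutral
#' scenario's freed contacts per period.
#'
#' @return A `run_config` list with elements `clinic`
#'   ([clinic_parameters()]), `scenario`, `sensitivity`, `simulation`,
#'   `output`.
#' @export
default_run_config <- function() {
  structure(
    list(clinic = clinic_parameters(),
         scenario = "all",
         sensitivity = list(parameters = NULL, multipliers = c(0.5, 1.5)),
         simulation = list(model = "bernoulli", flag_prob = 0.5,
                           tir = NULL, wear = NULL, seed = 1L,
                           capacity_per_period = NULL, periods = NULL),
         output = list(dir = ".", formats = c("csv", "md"))),
    class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a structured-text (`key: value`) configuration whose top-level keys
#' mirror the [clinic_parameters()] field names, plus optional `scenario`,
#' `sensitivity`, `simulation`, and `output` sections. Omitted keys keep the
#' model defaults; unknown keys are rejected by name; the assembled clinic
#' parameters are validated before anything is computed.
#'
#' @param path Path to a YAML file. An empty file yields
#'   [default_run_config()].
#' @return A validated `run_config`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("routine_rate: 84", f)
#' load_config(f)$clinic$routine_rate  # 84
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("config file must contain key: value mappings", call. = FALSE)
  cfg <- default_run_config()
  clinic_fields <- names(unclass(cfg$clinic))
  unknown <- setdiff(names(raw), c(clinic_fields, CONFIG_SECTIONS))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste0("'", unknown, "'", collapse = ", "),
         call. = FALSE)
  clinic <- unclass(cfg$clinic)
  for (nm in intersect(names(raw), clinic_fields)) clinic[[nm]] <- raw[[nm]]
  cfg$clinic <- validate_clinic_parameters(clinic)
  if (!is.null(raw$scenario)) cfg$scenario <- raw$scenario
  for (sec in c("sensitivity", "simulation", "output")) {
    if (is.null(raw[[sec]])) next
    bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
    if (length(bad) > 0L)
      stop("unknown key(s) in '", sec, "' section: ",
           paste0("'", bad, "'", collapse = ", "), call. = FALSE)
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  cfg
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [load_config()]: the written file reloads to an identical
#' configuration.
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config$clinic)
  out$scenario <- config$scenario
  for (sec in c("sensitivity", "simulation", "output")) {
    kept <- config[[sec]][!vapply(config[[sec]], is.null, logical(1))]
    if (length(kept) > 0L) out[[sec]] <- kept
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Path to the packaged default configuration
#'
#' A YAML fixture shipping the reference clinic's parameter values, usable as
#' a template for site-specific configs.
#'
#' @return File path within the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "rpmecon",
              mustWork = TRUE)
}
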