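## File formats binding the modules together: YAML/JSON hardware configs and
## domain specs, CSV job lists and kinetic data, JSON schedules and fit
## results, plus a run manifest for provenance. Times are serialized in
## seconds, temperatures in degC; kelvin is internal to the Eyring fit.

.read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use YAML or JSON)",
         call. = FALSE))
  obj
}

#' Load and validate a hardware configuration file
#'
#' Stage durations are deployment properties with no universal default, so
#' the six of them are required in every config file; counts, bounds and
#' ramp rates fall back to the [hardware_config()] defaults. Validation
#' errors name the offending field.
#'
#' @param path YAML or JSON file.
#' @return A validated [hardware_config()].
#' @export
load_hardware_config <- function(path) {
  obj <- .read_structured(path)
  required <- c("t_prep", "t_transit_in", "t_rinse_a", "t_transit_out",
                "t_rinse_b", "t_hplc")
  if (is.null(obj) || !length(obj))
    stop("empty hardware config; required fields: ",
         paste(required, collapse = ", "), call. = FALSE)
  miss <- setdiff(required, names(obj))
  if (length(miss))
    stop("hardware config missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  known <- names(formals(hardware_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown hardware config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(hardware_config, obj)
}

#' Write a hardware configuration to YAML
#' @param cfg A [hardware_config()].
#' @param path Output path (`.yaml`).
#' @export
write_hardware_config <- function(cfg, path) {
  yaml::write_yaml(unclass(validate_hardware_config(cfg)), path)
  invisible(path)
}

#' Read a job list
#'
#' CSV columns: `job_id`, `temperature_C`, `residence_time_s`, `mode`,
#' optional `led_power`, plus any payload columns. JSON: an array of
#' objects with the same fields.
#'
#' @param path CSV or JSON file.
#' @param cfg Optional [hardware_config()] for temperature validation.
#' @return A validated job table (see [reaction_jobs()]).
#' @export
read_jobs <- function(path, cfg = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") read.csv(path, stringsAsFactors = FALSE)
        else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  need <- c("job_id", "temperature_C", "residence_time_s", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("job file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  names(df)[names(df) == "temperature_C"] <- "temperature"
  names(df)[names(df) == "residence_time_s"] <- "residence_time"
  validate_jobs(df, cfg = cfg)
}

#' Write a job list as CSV
#' @param jobs Job table.
#' @param path Output `.csv` path.
#' @export
write_jobs <- function(jobs, path) {
  out <- jobs
  names(out)[names(out) == "temperature"] <- "temperature_C"
  names(out)[names(out) == "residence_time"] <- "residence_time_s"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.valid_resources <- function(n_reactors) {
  c("liquid_handler", "main_flowpath", "hplc",
    paste0("reactor_", seq_len(n_reactors)))
}

#' Write a schedule to JSON
#'
#' Allocations are serialized as `{job_id, stage, resource, start_s, end_s}`
#' records sorted by start time, with times in seconds at fixed (1e-6 s)
#' precision; the config and job table ride along so the file round-trips
#' into an identical schedule.
#'
#' @param s A `droplet_schedule`.
#' @param path Output `.json` path.
#' @export
write_schedule <- function(s, path) {
  a <- s$allocations[order(s$allocations$start, s$allocations$resource,
                           s$allocations$job_id), ]
  jobs <- s$jobs
  names(jobs)[names(jobs) == "temperature"] <- "temperature_C"
  names(jobs)[names(jobs) == "residence_time"] <- "residence_time_s"
  obj <- list(
    config = unclass(s$cfg),
    jobs = jobs,
    allocations = data.frame(job_id = a$job_id, stage = a$stage,
                             resource = a$resource,
                             start_s = round(a$start, 6),
                             end_s = round(a$end, 6),
                             stringsAsFactors = FALSE),
    reactor_of = as.list(s$reactor_of),
    prep_start = as.list(round(s$prep_start, 6)),
    n_shifts = s$n_shifts,
    total_shift_time = s$total_shift_time)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a schedule from JSON
#'
#' @param path A [write_schedule()] file.
#' @return A `droplet_schedule`; errors on malformed records or unknown
#'   resource names.
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("config", "jobs", "allocations", "reactor_of", "prep_start"))
    if (is.null(obj[[f]]))
      stop("malformed schedule file: missing '", f, "'", call. = FALSE)
  cfg <- do.call(hardware_config, obj$config)
  jobs <- obj$jobs
  names(jobs)[names(jobs) == "temperature_C"] <- "temperature"
  names(jobs)[names(jobs) == "residence_time_s"] <- "residence_time"
  jobs <- validate_jobs(jobs, cfg = cfg)
  bad <- setdiff(unique(obj$allocations$resource),
                 .valid_resources(cfg$n_reactors))
  if (length(bad))
    stop("unknown resource name(s) in schedule: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(obj$allocations$start_s >= obj$allocations$end_s))
    stop("malformed schedule: interval with start >= end", call. = FALSE)
  s <- .new_schedule(jobs, cfg,
                     prep_start = unlist(obj$prep_start)[jobs$job_id],
                     reactor_of = unlist(obj$reactor_of)[jobs$job_id],
                     n_shifts = obj$n_shifts %||% 0,
                     total_shift_time = obj$total_shift_time %||% 0)
  ## the rebuilt allocations must agree with the serialized records
  a <- s$allocations[order(s$allocations$start, s$allocations$resource,
                           s$allocations$job_id), ]
  if (nrow(a) != nrow(obj$allocations) ||
      max(abs(a$start - obj$allocations$start_s)) > 1e-5)
    stop("schedule file allocations are inconsistent with its jobs/config",
         call. = FALSE)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a schedule as a Gantt-style CSV
#'
#' @param s A `droplet_schedule`.
#' @param path Output `.csv` path.
#' @export
write_gantt_csv <- function(s, path) {
  a <- s$allocations[order(s$allocations$start), ]
  write.csv(data.frame(job_id = a$job_id, stage = a$stage,
                       resource = a$resource, start_s = a$start,
                       end_s = a$end),
            path, row.names = FALSE)
  invisible(path)
}

#' Load an optimization domain from YAML/JSON
#'
#' Expected layout: a `continuous` map of `name: [low, high]` and a
#' `categorical` map of `name: [levels...]`.
#'
#' @param path YAML or JSON file.
#' @return A [domain_spec()].
#' @export
load_domain_spec <- function(path) {
  obj <- .read_structured(path)
  if (is.null(obj$continuous) && is.null(obj$categorical))
    stop("domain file needs a 'continuous' and/or 'categorical' section",
         call. = FALSE)
  cont <- lapply(obj$continuous, function(b) as.numeric(unlist(b)))
  cats <- lapply(obj$categorical, function(l) as.character(unlist(l)))
  domain_spec(continuous = cont %||% list(), categorical = cats %||% list())
}

#' Read a kinetic dataset CSV
#'
#' Columns: `temperature_C`, `arf0_M`, `amine0_M`, `time_s`, `arf_M`.
#'
#' @param path CSV file.
#' @return Validated `data.frame`.
#' @export
read_kinetic_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "arf0_M", "amine0_M", "time_s", "arf_M")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("kinetic data file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$arf_M < 0) || any(df$time_s < 0))
    stop("kinetic data: negative times or concentrations", call. = FALSE)
  df
}

#' Write a kinetics fit to JSON
#' @param fit A [fit_kinetics()] result.
#' @param path Output `.json` path.
#' @export
write_kinetics_fit <- function(fit, path) {
  ey <- fit$eyring
  obj <- list(
    rate_constants = fit$rate_constants,
    eyring = list(slope = ey$slope, intercept = ey$intercept,
                  dH_kJ_mol = ey$dH, dS_J_mol_K = ey$dS,
                  se_dH = ey$se_dH, se_dS = ey$se_dS, n = ey$n))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a run manifest
#'
#' Every command-line run emits one manifest: what ran, with which seed,
#' on which inputs (md5-hashed), producing which outputs.
#'
#' @param command Subcommand name.
#' @param seed Integer seed used.
#' @param inputs,outputs Character vectors of file paths (existing inputs
#'   are hashed).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(command, seed = NA_integer_,
                         inputs = character(), outputs = character()) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  out <- list(command = command, seed = seed,
              inputs = as.list(inputs), input_md5 = hashes,
              outputs = as.list(outputs),
              package_version = as.character(utils::packageVersion("dropletlab")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(out) <- "run_manifest"
  out
}

#' Write a run manifest next to an output file
#' @param manifest A [run_manifest()].
#' @param path Output `.json` path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
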