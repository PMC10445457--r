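## Hardware abstraction: shared resources, stage durations, reactor bank.
## The scheduler and the discrete-event simulator both consume this model.

#' Hardware timing configuration for a parallel droplet platform
#'
#' Describes the platform as a bank of `n_reactors` independent reactors
#' book-ended by shared bottleneck hardware: a liquid handler that prepares
#' droplets, a main flowpath used by all droplet transits and rinse/vent
#' operations, and an HPLC for analysis. Stage durations are platform
#' properties supplied by the operator; the defaults here are representative
#' values for a bench-top system and are meant to be overridden from a config
#' file for any real deployment (see [load_hardware_config()]).
#'
#' @param n_reactors Number of parallel reactor channels (default 10).
#' @param t_prep Liquid-handler droplet preparation time, s.
#' @param t_transit_in Transit time liquid handler -> reactor (occupies the
#'   main flowpath), s.
#' @param t_rinse_a Duration of the post-inbound rinse/vent, which cleans the
#'   main flowpath only (no reactor in the flowpath), s.
#' @param t_transit_out Transit time reactor -> HPLC sampling valve (occupies
#'   the main flowpath), s.
#' @param t_rinse_b Duration of the post-outbound rinse/vent, which cleans the
#'   main flowpath *and* the droplet's reactor, s. The reactor only becomes
#'   available for a new droplet once this rinse has finished.
#' @param t_hplc HPLC analysis time, s.
#' @param time_unit Granularity of scheduler shifts, s (default 1).
#' @param temp_min,temp_max Admissible reactor temperature range, degrees C.
#' @param heat_rate,cool_rate Reactor temperature ramp rates, degrees C per s
#'   (used by the simulator only; heating via cartridge heaters is fast,
#'   cooling through the heat sink is slow).
#' @param ambient_temp Initial reactor temperature, degrees C.
#'
#' @return An object of class `hardware_config` (a validated named list).
#' @seealso [job_stage_chain()], [initial_schedule()], [simulate_schedule()]
#' @export
#' @examples
#' cfg <- hardware_config(n_reactors = 4, t_prep = 120)
#' cfg$n_reactors
hardware_config <- function(n_reactors = 10,
                            t_prep = 300, t_transit_in = 30, t_rinse_a = 60,
                            t_transit_out = 30, t_rinse_b = 60, t_hplc = 240,
                            time_unit = 1, temp_min = 0, temp_max = 200,
                            heat_rate = 1.0, cool_rate = 0.1,
                            ambient_temp = 25) {
  cfg <- list(n_reactors = n_reactors, t_prep = t_prep,
              t_transit_in = t_transit_in, t_rinse_a = t_rinse_a,
              t_transit_out = t_transit_out, t_rinse_b = t_rinse_b,
              t_hplc = t_hplc, time_unit = time_unit,
              temp_min = temp_min, temp_max = temp_max,
              heat_rate = heat_rate, cool_rate = cool_rate,
              ambient_temp = ambient_temp)
  class(cfg) <- "hardware_config"
  validate_hardware_config(cfg)
}

#' Validate a hardware configuration
#'
#' @param cfg A `hardware_config` or plain named list.
#' @return The validated `hardware_config`, invisibly usable in pipelines.
#' @export
validate_hardware_config <- function(cfg) {
  num1 <- function(field) {
    v <- cfg[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("hardware config field '%s' must be a single finite number", field),
           call. = FALSE)
    v
  }
  for (f in c("t_prep", "t_transit_in", "t_rinse_a", "t_transit_out",
              "t_rinse_b", "t_hplc", "time_unit", "heat_rate", "cool_rate"))
    if (num1(f) <= 0)
      stop(sprintf("hardware config field '%s' must be > 0 (got %g)", f, cfg[[f]]),
           call. = FALSE)
  if (num1("n_reactors") < 1 || cfg$n_reactors != round(cfg$n_reactors))
    stop("hardware config field 'n_reactors' must be an integer >= 1", call. = FALSE)
  if (num1("temp_min") >= num1("temp_max"))
    stop("hardware config: 'temp_min' must be < 'temp_max'", call. = FALSE)
  if (cfg$temp_min < 0 || cfg$temp_max > 200)
    stop(sprintf("hardware config: temperature bounds [%g, %g] outside the supported 0-200 degC envelope",
                 cfg$temp_min, cfg$temp_max), call. = FALSE)
  num1("ambient_temp")
  class(cfg) <- "hardware_config"
  cfg
}

#' @export
print.hardware_config <- function(x, ...) {
  cat(sprintf("<hardware_config> %d reactors, %g-%g degC\n",
              x$n_reactors, x$temp_min, x$temp_max))
  cat(sprintf("  prep %gs | transit in %gs | rinse A %gs | transit out %gs | rinse B %gs | HPLC %gs\n",
              x$t_prep, x$t_transit_in, x$t_rinse_a, x$t_transit_out,
              x$t_rinse_b, x$t_hplc))
  cat(sprintf("  time unit %gs, ramps +%g/-%g degC/s\n",
              x$time_unit, x$heat_rate, x$cool_rate))
  invisible(x)
}

#' Construct and validate a table of reaction jobs
#'
#' A job is one droplet: its reactor temperature, residence time, and
#' operating mode. Extra columns (concentrations, catalyst, base, ...) are
#' carried through untouched as the condition payload.
#'
#' @param job_id Character or integer identifiers (unique).
#' @param temperature Target reactor temperature, degrees C.
#' @param residence_time Residence time in the reactor, s (> 0).
#' @param mode `"thermal"` or `"photochemical"`.
#' @param led_power LED power fraction in `[0, 1]`; required (non-`NA`) for
#'   photochemical jobs, ignored for thermal ones.
#' @param ... Additional payload columns, recycled to the number of jobs.
#' @param cfg Optional [hardware_config()] to validate temperatures against.
#'
#' @return A `data.frame` of jobs (one row per droplet).
#' @export
#' @examples
#' reaction_jobs(job_id = c("a", "b"), temperature = 70,
#'               residence_time = c(600, 300))
reaction_jobs <- function(job_id, temperature, residence_time,
                          mode = "thermal", led_power = NA_real_, ...,
                          cfg = NULL) {
  jobs <- data.frame(job_id = as.character(job_id),
                     temperature = temperature,
                     residence_time = residence_time,
                     mode = mode, led_power = led_power,
                     stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) jobs[[nm]] <- extra[[nm]]
  validate_jobs(jobs, cfg = cfg)
}

#' Validate a job table
#'
#' @param jobs `data.frame` with columns `job_id`, `temperature`,
#'   `residence_time`, `mode` and optionally `led_power`.
#' @param cfg Optional [hardware_config()]; when given, temperatures must lie
#'   within its `[temp_min, temp_max]`.
#' @return The validated job table.
#' @export
validate_jobs <- function(jobs, cfg = NULL) {
  need <- c("job_id", "temperature", "residence_time", "mode")
  miss <- setdiff(need, names(jobs))
  if (length(miss))
    stop("job table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(jobs) == 0) stop("job table is empty", call. = FALSE)
  jobs$job_id <- as.character(jobs$job_id)
  if (anyDuplicated(jobs$job_id))
    stop("job_id values must be unique", call. = FALSE)
  if (!all(jobs$mode %in% c("thermal", "photochemical")))
    stop("unknown mode: ", paste(setdiff(unique(jobs$mode),
                                         c("thermal", "photochemical")),
                                 collapse = ", "), call. = FALSE)
  if (any(!is.finite(jobs$residence_time)) || any(jobs$residence_time <= 0))
    stop("residence_time must be finite and > 0 for every job", call. = FALSE)
  if (!is.null(cfg)) {
    cfg <- validate_hardware_config(cfg)
    bad <- jobs$temperature < cfg$temp_min | jobs$temperature > cfg$temp_max
    if (any(bad))
      stop(sprintf("job temperature outside config bounds [%g, %g]: %s",
                   cfg$temp_min, cfg$temp_max,
                   paste(jobs$job_id[bad], collapse = ", ")), call. = FALSE)
  }
  if (!"led_power" %in% names(jobs)) jobs$led_power <- NA_real_
  photo <- jobs$mode == "photochemical"
  if (any(photo)) {
    lp <- jobs$led_power[photo]
    if (any(is.na(lp)) || any(lp < 0 | lp > 1))
      stop("photochemical jobs need led_power in [0, 1]", call. = FALSE)
  }
  jobs
}

#' Canonical stage chain of one droplet
#'
#' Every droplet passes through the same seven-stage lifecycle:
#' preparation on the liquid handler, transit to the assigned reactor along
#' the main flowpath, a flowpath-only rinse/vent (running while the reaction
#' proceeds), the residence in the reactor, transit out to the HPLC sampling
#' valve, a second rinse/vent that also cleans the reactor, and HPLC
#' analysis. Immediacy constraints tie the stages together rigidly: transit
#' in starts the instant prep ends, the residence clock starts on arrival,
#' transit out starts the instant the residence ends, each rinse starts the
#' instant its transit ends, and analysis starts when transit out ends
#' (overlapping the reactor rinse, which uses disjoint hardware).
#'
#' Intervals are half-open `[start, end)`: back-to-back stages on a shared
#' resource are legal. The reactor-side rinse interval starts at transit-out
#' start so the reactor is blocked without gaps from droplet arrival until
#' its rinse completes.
#'
#' @param job One job: a one-row `data.frame` or named list with at least
#'   `residence_time` and `mode`.
#' @param cfg A [hardware_config()].
#' @return `data.frame` with columns `stage`, `resource` (the placeholder
#'   `"reactor"` is replaced by `reactor_<i>` at assignment), `offset` (start
#'   relative to prep start, s) and `duration` (s). The reactor rinse
#'   appears twice because it occupies two resources.
#' @export
#' @examples
#' job_stage_chain(list(residence_time = 300, mode = "thermal"),
#'                 hardware_config(t_prep = 60, t_transit_in = 60,
#'                                 t_rinse_a = 60, t_transit_out = 60,
#'                                 t_rinse_b = 60, t_hplc = 60))
job_stage_chain <- function(job, cfg) {
  cfg <- validate_hardware_config(cfg)
  res <- job$residence_time
  if (is.null(res) || !is.finite(res) || res <= 0)
    stop("residence_time must be > 0", call. = FALSE)
  if (!is.null(job$mode) && !job$mode %in% c("thermal", "photochemical"))
    stop("unknown mode: ", job$mode, call. = FALSE)
  p <- cfg$t_prep; ti <- cfg$t_transit_in; ra <- cfg$t_rinse_a
  to <- cfg$t_transit_out; rb <- cfg$t_rinse_b; hp <- cfg$t_hplc
  arrive <- p + ti          # droplet reaches its reactor
  depart <- arrive + res    # residence over, transit out begins
  data.frame(
    stage = c("prep", "transit_in", "rinse_a", "residence",
              "transit_out", "rinse_b", "rinse_b", "analysis"),
    resource = c("liquid_handler", "main_flowpath", "main_flowpath",
                 "reactor", "main_flowpath", "main_flowpath", "reactor",
                 "hplc"),
    offset = c(0, p, p + ti, arrive, depart, depart + to, depart, depart + to),
    duration = c(p, ti, ra, res, to, rb, to + rb, hp),
    stringsAsFactors = FALSE)
}

## internal: stage-chain bounds for one job (span from prep start to last end)
.chain_span <- function(job, cfg) {
  ch <- job_stage_chain(job, cfg)
  max(ch$offset + ch$duration)
}
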