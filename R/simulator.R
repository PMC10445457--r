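## Discrete-event execution of a schedule against the resource model.
##
## The simulator replays a schedule as acquire/release events on exclusive
## resources, which makes it an independent oracle for the scheduler's
## collision detection: any double-acquire is recorded as a conflict. It
## also reproduces the control-software behavior the scheduler ignores:
## droplet production pauses until the assigned reactor has ramped to the
## droplet's target temperature.

## internal: occupancy replay on a set of intervals -> conflicts
## (mechanism deliberately different from pairwise interval intersection)
.occupancy_conflicts <- function(alloc) {
  conflicts <- list()
  for (res in unique(alloc$resource)) {
    sub <- alloc[alloc$resource == res, ]
    ev <- data.frame(time = c(sub$start, sub$end),
                     type = rep(c(1L, -1L), each = nrow(sub)),  # 1=acquire
                     job = c(sub$job_id, sub$job_id),
                     other_end = c(sub$end, sub$end),
                     stringsAsFactors = FALSE)
    ## releases sort before acquires at equal times: [a,b) and [b,c) coexist
    ev <- ev[order(ev$time, ev$type), ]
    active <- character(0); active_end <- numeric(0)
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == 1L) {
        occ <- active != ev$job[i]
        if (any(occ)) {
          for (k in which(occ))
            conflicts[[length(conflicts) + 1L]] <- data.frame(
              resource = res, job_a = active[k], job_b = ev$job[i],
              overlap_start = ev$time[i],
              overlap_end = min(active_end[k], ev$other_end[i]),
              stringsAsFactors = FALSE)
        }
        active <- c(active, ev$job[i])
        active_end <- c(active_end, ev$other_end[i])
      } else {
        drop <- which(active == ev$job[i] & active_end == ev$time[i])[1]
        if (!is.na(drop)) { active <- active[-drop]; active_end <- active_end[-drop] }
      }
    }
  }
  if (!length(conflicts))
    return(data.frame(resource = character(), job_a = character(),
                      job_b = character(), overlap_start = numeric(),
                      overlap_end = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, conflicts)
  out[order(out$overlap_start, out$resource), , drop = FALSE]
}

## internal: reactor temperature trajectory bookkeeping
.ramp_time <- function(from, to, cfg) {
  if (to == from) return(0)
  rate <- if (to > from) cfg$heat_rate else cfg$cool_rate
  abs(to - from) / rate
}

#' Simulate a schedule as discrete events
#'
#' Executes the schedule on exclusive-occupancy resources. Without the
#' temperature pause the schedule is replayed verbatim and every
#' double-acquire is collected as a conflict (the run is not aborted), so
#' the simulator serves as an independent feasibility oracle for
#' [detect_collisions()]. With `pause_for_temperature = TRUE`, a droplet's
#' preparation is additionally delayed until its assigned reactor -- ramping
#' linearly at the config's `heat_rate`/`cool_rate` from its previous
#' setpoint -- has reached the droplet's target temperature. A paused prep
#' delays the droplet's whole chain rigidly, and any downstream contention
#' this creates is resolved by further delaying the later-prepared droplet
#' (first-come-first-served per resource), so pauses only ever delay
#' acquisition and the executed timeline stays conflict-free.
#'
#' @param s A `droplet_schedule`.
#' @param pause_for_temperature Logical; emulate the control-software
#'   temperature pause (default `FALSE`).
#' @param initial_temps Optional numeric vector of starting reactor
#'   temperatures, degrees C (default: config `ambient_temp` everywhere).
#' @return An object of class `droplet_eventlog`: `events` (time-ordered
#'   acquire/release records), `conflicts` (empty iff execution succeeded),
#'   `temp_traces` (piecewise-linear reactor temperature series),
#'   `job_delays` (scheduled vs actual prep start per job) and `makespan`.
#' @export
simulate_schedule <- function(s, pause_for_temperature = FALSE,
                              initial_temps = NULL) {
  cfg <- s$cfg
  jobs <- s$jobs
  if (nrow(jobs) == 0) stop("empty schedule", call. = FALSE)
  need <- c("prep", "transit_in", "rinse_a", "residence", "transit_out",
            "rinse_b", "analysis")
  have <- split(s$allocations$stage, s$allocations$job_id)
  for (jid in jobs$job_id)
    if (!all(need %in% have[[jid]]))
      stop("malformed schedule: job ", jid, " is missing stages", call. = FALSE)

  n <- nrow(jobs)
  ord <- order(unname(s$prep_start))      # prep (execution) order
  if (is.null(initial_temps)) initial_temps <- rep(cfg$ambient_temp, cfg$n_reactors)
  if (length(initial_temps) != cfg$n_reactors)
    stop("initial_temps must have one entry per reactor", call. = FALSE)

  reactor_temp <- initial_temps           # setpoint reached/held
  reactor_release <- numeric(cfg$n_reactors)  # time reactor frees (actual)
  traces <- vector("list", cfg$n_reactors)
  for (r in seq_len(cfg$n_reactors))
    traces[[r]] <- data.frame(time = 0, temp = initial_temps[r])

  delay <- numeric(n)                     # actual prep delay per job (s)
  placed <- NULL                          # intervals placed so far
  for (ii in ord) {
    jid <- jobs$job_id[ii]
    sub <- s$allocations[s$allocations$job_id == jid, , drop = FALSE]
    d <- 0
    r <- unname(s$reactor_of[jid])
    if (pause_for_temperature) {
      target <- jobs$temperature[ii]
      ramp_start <- reactor_release[r]
      ready <- ramp_start + .ramp_time(reactor_temp[r], target, cfg)
      d <- max(0, ready - unname(s$prep_start[jid]))
      ## ramp segment for the trace (even if no pause was needed)
      if (reactor_temp[r] != target) {
        traces[[r]] <- rbind(traces[[r]],
                             data.frame(time = c(ramp_start, ready),
                                        temp = c(reactor_temp[r], target)))
        reactor_temp[r] <- target
      }
      ## FIFO contention against already-placed droplets: bump the whole
      ## chain until no shared-resource overlap remains
      if (!is.null(placed)) {
        repeat {
          st <- sub$start + d; en <- sub$end + d
          clash_delay <- 0
          for (q in seq_len(nrow(sub))) {
            hit <- placed$resource == sub$resource[q] &
              placed$start < en[q] & st[q] < placed$end
            if (any(hit))
              clash_delay <- max(clash_delay, max(placed$end[hit]) - st[q])
          }
          if (clash_delay <= 0) break
          d <- d + clash_delay
        }
      }
    }
    delay[ii] <- d
    sub$start <- sub$start + d
    sub$end <- sub$end + d
    placed <- if (is.null(placed)) sub else rbind(placed, sub)
    hold_until <- max(sub$end[sub$resource == paste0("reactor_", r)])
    reactor_release[r] <- hold_until
    if (pause_for_temperature)
      traces[[r]] <- rbind(traces[[r]],
                           data.frame(time = hold_until, temp = reactor_temp[r]))
  }

  conflicts <- .occupancy_conflicts(placed)
  events <- rbind(
    data.frame(time = placed$start, job_id = placed$job_id,
               stage = placed$stage, resource = placed$resource,
               event = "acquire", stringsAsFactors = FALSE),
    data.frame(time = placed$end, job_id = placed$job_id,
               stage = placed$stage, resource = placed$resource,
               event = "release", stringsAsFactors = FALSE))
  events <- events[order(events$time, events$event == "acquire"), ]
  rownames(events) <- NULL

  temp_traces <- do.call(rbind, lapply(seq_along(traces), function(r) {
    tr <- traces[[r]]
    tr <- tr[order(tr$time), , drop = FALSE]
    data.frame(reactor = r, time = tr$time, temp = tr$temp)
  }))

  log <- list(events = events, conflicts = conflicts,
              temp_traces = temp_traces,
              job_delays = data.frame(
                job_id = jobs$job_id,
                scheduled_prep = unname(s$prep_start[jobs$job_id]),
                actual_prep = unname(s$prep_start[jobs$job_id]) + delay,
                delta = delay, stringsAsFactors = FALSE),
              ## wall-clock span from the schedule's time origin (ramps and
              ## pauses run from t = 0), so pauses can only inflate it
              makespan = max(placed$end) - min(s$allocations$start),
              pause_for_temperature = pause_for_temperature)
  class(log) <- "droplet_eventlog"
  log
}

#' @export
print.droplet_eventlog <- function(x, ...) {
  cat(sprintf("<droplet_eventlog> %d events, %d conflict(s), makespan %g s\n",
              nrow(x$events), nrow(x$conflicts), x$makespan))
  if (any(x$job_delays$delta > 0))
    cat(sprintf("  %d job(s) delayed, max delay %g s\n",
                sum(x$job_delays$delta > 0), max(x$job_delays$delta)))
  invisible(x)
}

#' Compare a schedule with its simulated execution
#'
#' @param s The `droplet_schedule` the log was produced from.
#' @param log The [simulate_schedule()] event log.
#' @return List with `job_deltas` (per-job prep start differences, s),
#'   `makespan_schedule`, `makespan_simulated` and `makespan_inflation`
#'   (extra time attributable to pauses, s).
#' @export
compare_schedule <- function(s, log) {
  if (!setequal(log$job_delays$job_id, s$jobs$job_id))
    stop("schedule and event log refer to different jobs", call. = FALSE)
  sched_span <- max(s$allocations$end) - min(s$allocations$start)
  list(job_deltas = log$job_delays,
       makespan_schedule = sched_span,
       makespan_simulated = log$makespan,
       makespan_inflation = log$makespan - sched_span)
}
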