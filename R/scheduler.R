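## Collision-free scheduling of droplet jobs on the parallel reactor bank.
##
## A "collision" is any positive-measure overlap of two distinct droplets'
## intervals on the same piece of shared hardware (liquid handler, main
## flowpath, one reactor, HPLC). The scheduler lays jobs out back-to-back in
## longest-processing-time order and then iteratively delays the preparation
## of colliding droplets until the schedule is feasible.

#' Order jobs by the longest-processing-time (LPT) rule
#'
#' Sorts jobs from longest target residence time to shortest. The sort is
#' stable: ties keep their original input order.
#'
#' @param jobs Job table (see [reaction_jobs()]).
#' @return The job table reordered for execution.
#' @export
#' @examples
#' j <- reaction_jobs(job_id = c("a", "b", "c"), temperature = 70,
#'                    residence_time = c(5, 40, 15) * 60)
#' lpt_order(j)$job_id  # "b", "c", "a"
lpt_order <- function(jobs) {
  if (is.null(jobs) || nrow(jobs) == 0) stop("empty job list", call. = FALSE)
  jobs[order(-jobs$residence_time), , drop = FALSE]
}

## internal: per-job chain template (offsets relative to prep start), cached
## as one data.frame with a job index column
.chain_table <- function(jobs, cfg) {
  n <- nrow(jobs)
  chains <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- job_stage_chain(jobs[i, , drop = FALSE], cfg)
    ch$job_idx <- i
    chains[[i]] <- ch
  }
  do.call(rbind, chains)
}

## internal: materialize allocations from prep starts + reactor assignment
.build_allocations <- function(chains, jobs, prep_start, reactor_of) {
  res <- chains$resource
  is_reactor <- res == "reactor"
  res[is_reactor] <- paste0("reactor_", reactor_of[chains$job_idx[is_reactor]])
  start <- chains$offset + prep_start[chains$job_idx]
  data.frame(job_id = jobs$job_id[chains$job_idx],
             stage = chains$stage, resource = res,
             start = start, end = start + chains$duration,
             job_idx = chains$job_idx, stringsAsFactors = FALSE)
}

.new_schedule <- function(jobs, cfg, prep_start, reactor_of, chains = NULL,
                          n_shifts = 0, total_shift_time = 0) {
  if (is.null(chains)) chains <- .chain_table(jobs, cfg)
  s <- list(jobs = jobs, cfg = cfg,
            prep_start = setNames(prep_start, jobs$job_id),
            reactor_of = setNames(reactor_of, jobs$job_id),
            allocations = .build_allocations(chains, jobs, prep_start, reactor_of),
            chains = chains,
            n_shifts = n_shifts, total_shift_time = total_shift_time)
  class(s) <- "droplet_schedule"
  s
}

#' Initial back-to-back schedule
#'
#' Lays out jobs assuming droplet preparation can be back-to-back: job *i*'s
#' prep starts the moment the liquid handler frees from job *i - 1*. Each job
#' is assigned the reactor that frees earliest (ties go to the lowest reactor
#' index), and its whole stage chain is placed rigidly from its prep start.
#' The result may contain collisions; pass it to [resolve_schedule()].
#'
#' @param jobs Job table, already in execution order (normally
#'   [lpt_order()] output).
#' @param cfg A [hardware_config()].
#' @return A `droplet_schedule`: jobs, per-job `prep_start` and `reactor_of`,
#'   and an `allocations` data frame of half-open resource intervals.
#' @export
initial_schedule <- function(jobs, cfg) {
  cfg <- validate_hardware_config(cfg)
  jobs <- validate_jobs(jobs, cfg = cfg)
  n <- nrow(jobs)
  chains <- .chain_table(jobs, cfg)
  prep_start <- (seq_len(n) - 1) * cfg$t_prep
  ## earliest-free reactor heuristic; reactor blocked until rinse B ends
  reactor_free <- numeric(cfg$n_reactors)
  reactor_of <- integer(n)
  for (i in seq_len(n)) {
    r <- which.min(reactor_free)           # lowest index wins ties
    reactor_of[i] <- r
    ch <- chains[chains$job_idx == i & chains$resource == "reactor", ]
    reactor_free[r] <- prep_start[i] + max(ch$offset + ch$duration)
  }
  .new_schedule(jobs, cfg, prep_start, reactor_of, chains)
}

#' @export
print.droplet_schedule <- function(x, ...) {
  cat(sprintf("<droplet_schedule> %d job(s) on %d reactor(s)\n",
              nrow(x$jobs), x$cfg$n_reactors))
  cat(sprintf("  span %g s, %d collision(s), %g shift unit(s)\n",
              max(x$allocations$end) - min(x$allocations$start),
              nrow(detect_collisions(x)), x$n_shifts))
  invisible(x)
}

#' Detect droplet collisions in a schedule
#'
#' Finds every pair of intervals belonging to *distinct* jobs that overlap
#' with positive measure on the same resource. Intervals are half-open, so
#' back-to-back stages do not collide.
#'
#' @param s A `droplet_schedule`.
#' @return `data.frame` with columns `resource`, `job_a`, `job_b` (job_a is
#'   the earlier-starting interval's job), `overlap_start`, `overlap_end`,
#'   sorted by `overlap_start` then resource; zero rows iff the schedule is
#'   feasible. Internal columns carry the colliding interval bounds.
#' @export
detect_collisions <- function(s) {
  a <- s$allocations
  out <- vector("list", 8L); nout <- 0L
  for (res in unique(a$resource)) {
    idx <- which(a$resource == res)
    if (length(idx) < 2) next
    sub <- a[idx, ]
    o <- order(sub$start, sub$end)
    st <- sub$start[o]; en <- sub$end[o]; jid <- sub$job_id[o]
    m <- length(o)
    for (i in seq_len(m - 1)) {
      j <- i + 1L
      while (j <= m && st[j] < en[i]) {
        if (jid[j] != jid[i]) {
          nout <- nout + 1L
          if (nout > length(out)) out <- c(out, vector("list", length(out)))
          out[[nout]] <- data.frame(
            resource = res, job_a = jid[i], job_b = jid[j],
            overlap_start = st[j], overlap_end = min(en[i], en[j]),
            end_a = en[i], end_b = en[j], start_a = st[i], start_b = st[j],
            stringsAsFactors = FALSE)
        }
        j <- j + 1L
      }
    }
  }
  if (nout == 0L)
    return(data.frame(resource = character(), job_a = character(),
                      job_b = character(), overlap_start = numeric(),
                      overlap_end = numeric(), end_a = numeric(),
                      end_b = numeric(), start_a = numeric(),
                      start_b = numeric(), stringsAsFactors = FALSE))
  coll <- do.call(rbind, out[seq_len(nout)])
  coll[order(coll$overlap_start, coll$resource), , drop = FALSE]
}

## internal: earliest positive-measure overlap between distinct jobs.
## Vectorized sweep used inside the resolve loop; detect_collisions() is the
## full pairwise enumeration and doubles as its correctness check.
## Returns NULL or list(job_i, job_j, start_i, start_j, end_i, end_j) where
## interval i starts no later than interval j.
.earliest_collision <- function(st, en, rid, jidx) {
  o <- order(rid, st, en)
  r_o <- rid[o]; st_o <- st[o]; en_o <- en[o]; j_o <- jidx[o]
  N <- length(o)
  g <- cumsum(c(TRUE, r_o[-1] != r_o[-N]))
  cm <- unlist(lapply(split(en_o, g), cummax), use.names = FALSE)
  prev_cm <- c(-Inf, cm[-N])
  prev_cm[c(TRUE, g[-1] != g[-N])] <- -Inf
  cand <- which(st_o < prev_cm)
  if (!length(cand)) return(NULL)
  ## rid is assigned in resource-name order, so (overlap_start, rid) sorting
  ## matches detect_collisions()'s (overlap_start, resource) sorting
  cand <- cand[order(st_o[cand], r_o[cand])]
  gstart <- which(c(TRUE, g[-1] != g[-N]))
  for (j in cand) {
    lo <- gstart[g[j]]
    ii <- lo:(j - 1L)
    hit <- ii[en_o[ii] > st_o[j] & j_o[ii] != j_o[j]]
    if (length(hit)) {
      i <- hit[1L]   # earliest-starting partner
      return(list(job_i = j_o[i], job_j = j_o[j],
                  start_i = st_o[i], start_j = st_o[j],
                  end_i = en_o[i], end_j = en_o[j]))
    }
  }
  NULL
}

#' Resolve collisions by iteratively shifting droplet preparation
#'
#' Scans the schedule for the earliest collision and delays the preparation
#' of the *later-prepared* droplet of the colliding pair (delaying the
#' earlier one could never clear the overlap) in multiples of the config's
#' `time_unit` until no collisions remain. Each shift moves the droplet's
#' whole stage chain rigidly, and preparation order is preserved: a shifted
#' droplet pushes any later droplet's prep so preps never reorder. Prep
#' starts are only ever delayed, never advanced.
#'
#' Shifts are applied in aggregated multiples of `time_unit` (the minimal
#' multiple that clears the current collision) rather than literally one
#' unit per scan, which reaches the same fixed point with far fewer passes.
#'
#' @param s A `droplet_schedule` (typically from [initial_schedule()]).
#' @param max_shift_units Abort guard: total shift budget in time units
#'   before the configuration is declared infeasible.
#' @return A collision-free `droplet_schedule` with `n_shifts` (unit shifts
#'   applied) and `total_shift_time` (total prep delay, s) filled in.
#' @export
resolve_schedule <- function(s, max_shift_units = 1e7) {
  cfg <- s$cfg
  unit <- cfg$time_unit
  jobs <- s$jobs
  n <- nrow(jobs)
  prep <- unname(s$prep_start)
  chains <- s$chains
  n_units <- s$n_shifts
  base_prep <- unname(s$prep_start)

  ## flat interval table; resource ids assigned in name order so the sweep
  ## breaks ties exactly like detect_collisions()
  reactor_of <- unname(s$reactor_of)
  res_name <- chains$resource
  is_r <- res_name == "reactor"
  res_name[is_r] <- paste0("reactor_", reactor_of[chains$job_idx[is_r]])
  rid <- match(res_name, sort(unique(res_name)))
  off <- chains$offset; dur <- chains$duration; cj <- chains$job_idx

  repeat {
    st <- off + prep[cj]
    hit <- .earliest_collision(st, st + dur, rid, cj)
    if (is.null(hit))
      return(.new_schedule(jobs, cfg, prep, reactor_of, chains,
                           n_shifts = n_units,
                           total_shift_time = sum(prep - base_prep) +
                             s$total_shift_time))
    ia <- hit$job_i; ib <- hit$job_j
    ## later-prepared droplet of the pair; ties -> later in execution order
    if (prep[ia] > prep[ib] || (prep[ia] == prep[ib] && ia > ib)) {
      j <- ia; s_j <- hit$start_i; e_o <- hit$end_j
    } else {
      j <- ib; s_j <- hit$start_j; e_o <- hit$end_i
    }
    d <- max(unit, ceiling((e_o - s_j) / unit - 1e-9) * unit)
    prep[j] <- prep[j] + d
    n_units <- n_units + d / unit
    if (n_units > max_shift_units)
      stop("shift budget exhausted: hardware configuration appears infeasible",
           call. = FALSE)
    ## order-preserving cascade: preps stay in execution order and never
    ## overlap on the liquid handler
    if (j < n) for (k in (j + 1):n)
      prep[k] <- max(prep[k], prep[k - 1] + cfg$t_prep)
  }
}

#' Makespan and utilization of a feasible schedule
#'
#' @param s A feasible `droplet_schedule` (no collisions).
#' @return List of class `schedule_metrics`: `makespan` (s), `utilization`
#'   (named fraction per resource: busy time / makespan), `n_shifts`,
#'   `total_shift_time` (s).
#' @export
schedule_metrics <- function(s) {
  if (nrow(s$jobs) == 0) stop("empty schedule", call. = FALSE)
  if (nrow(detect_collisions(s)) > 0)
    stop("schedule is infeasible (collisions present); resolve it first",
         call. = FALSE)
  a <- s$allocations
  makespan <- max(a$end) - min(a$start)
  busy <- tapply(a$end - a$start, a$resource, sum)
  m <- list(makespan = makespan,
            utilization = busy / makespan,
            n_shifts = s$n_shifts,
            total_shift_time = s$total_shift_time)
  class(m) <- "schedule_metrics"
  m
}

#' @export
print.schedule_metrics <- function(x, ...) {
  cat(sprintf("<schedule_metrics> makespan %g s, %g shift unit(s) (%g s total)\n",
              x$makespan, x$n_shifts, x$total_shift_time))
  u <- sort(x$utilization, decreasing = TRUE)
  for (nm in names(u)) cat(sprintf("  %-16s %5.1f%%\n", nm, 100 * u[[nm]]))
  invisible(x)
}

#' One-call scheduling pipeline
#'
#' Convenience wrapper: LPT ordering, back-to-back initial layout, then
#' iterative shifting to feasibility.
#'
#' @inheritParams initial_schedule
#' @param ... Passed to [resolve_schedule()].
#' @return A feasible `droplet_schedule`.
#' @export
#' @examples
#' jobs <- reaction_jobs(job_id = 1:3, temperature = 70,
#'                       residence_time = c(300, 900, 600))
#' s <- schedule_jobs(jobs, hardware_config(n_reactors = 2))
#' schedule_metrics(s)$makespan
schedule_jobs <- function(jobs, cfg, ...) {
  resolve_schedule(initial_schedule(lpt_order(jobs), cfg), ...)
}

#' Flag jobs needing large reactor temperature swings
#'
#' The scheduler ignores heating/cooling; this post-hoc check lists
#' consecutive assignments on one reactor whose setpoint change exceeds a
#' threshold (the simulator's temperature pause will delay those preps).
#'
#' @param s A `droplet_schedule`.
#' @param threshold Temperature change, degrees C, above which to warn.
#' @return `data.frame` of (reactor, from_job, to_job, delta_temp) rows.
#' @export
temperature_change_warnings <- function(s, threshold = 20) {
  out <- list()
  ord <- order(s$prep_start)
  jid <- s$jobs$job_id[ord]
  for (r in unique(s$reactor_of)) {
    on_r <- jid[jid %in% names(s$reactor_of)[s$reactor_of == r]]
    if (length(on_r) < 2) next
    temps <- s$jobs$temperature[match(on_r, s$jobs$job_id)]
    d <- abs(diff(temps))
    big <- which(d > threshold)
    if (length(big))
      out[[length(out) + 1L]] <- data.frame(
        reactor = r, from_job = on_r[big], to_job = on_r[big + 1L],
        delta_temp = d[big], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(reactor = integer(), from_job = character(),
                      to_job = character(), delta_temp = numeric()))
  do.call(rbind, out)
}
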