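# Independent oracles used by the test suite. Everything here is written
# from first principles (hand-coded timelines, pairwise overlap scans, a
# fixed-step integrator, exhaustive search) so it shares no code path with
# the package internals it checks.

# hand-coded interval layout of one droplet's lifecycle (start, end,
# resource) given its prep start; mirrors the platform's operating rules,
# not the package's chain constructor
oracle_job_intervals <- function(prep_start, residence, reactor, cfg) {
  p <- cfg$t_prep; ti <- cfg$t_transit_in; ra <- cfg$t_rinse_a
  to <- cfg$t_transit_out; rb <- cfg$t_rinse_b; hp <- cfg$t_hplc
  t0 <- prep_start
  arrive <- t0 + p + ti
  depart <- arrive + residence
  data.frame(
    start = c(t0, t0 + p, t0 + p + ti, arrive, depart, depart + to, depart + to),
    end = c(t0 + p, t0 + p + ti, t0 + p + ti + ra,
            depart + to + rb,            # reactor blocked arrival -> rinse end
            depart + to, depart + to + rb, depart + to + hp),
    resource = c("liquid_handler", "main_flowpath", "main_flowpath",
                 paste0("reactor_", reactor), "main_flowpath",
                 "main_flowpath", "hplc"),
    stringsAsFactors = FALSE)
}

# pairwise positive-measure overlap scan between distinct jobs
oracle_any_collision <- function(iv) {
  n <- nrow(iv)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (iv$job[i] != iv$job[j] && iv$resource[i] == iv$resource[j] &&
        iv$start[i] < iv$end[j] && iv$start[j] < iv$end[i])
      return(TRUE)
  }
  FALSE
}

# exhaustive minimum-makespan search over per-job prep delays on the
# time_unit grid (LPT order, earliest-free reactor assignment and prep
# execution order fixed, as in the scheduler; delays bounded by the
# instance's total busy time). Depth-first over jobs in order; branches
# are cut once the partial span already reaches the best makespan found,
# which preserves the minimum.
oracle_min_makespan <- function(jobs, cfg) {
  jobs <- jobs[order(-jobs$residence_time), , drop = FALSE]
  n <- nrow(jobs)
  unit <- cfg$time_unit
  base_prep <- (seq_len(n) - 1) * cfg$t_prep
  reactor_free <- numeric(cfg$n_reactors)
  reactor <- integer(n)
  for (i in seq_len(n)) {
    r <- which.min(reactor_free)
    reactor[i] <- r
    reactor_free[r] <- base_prep[i] + cfg$t_prep + cfg$t_transit_in +
      jobs$residence_time[i] + cfg$t_transit_out + cfg$t_rinse_b
  }
  ivs <- lapply(seq_len(n), function(i)
    oracle_job_intervals(base_prep[i], jobs$residence_time[i], reactor[i], cfg))
  spans <- vapply(ivs, function(iv) max(iv$end) - min(iv$start), numeric(1))
  d_cap <- ceiling(sum(spans) / unit) * unit   # total busy time bound

  best <- Inf
  recurse <- function(i, pst, pen, pres, prev_prep) {
    if (i > n) {
      best <<- min(best, max(pen) - min(pst))
      return(invisible())
    }
    iv <- ivs[[i]]
    ## preps never reorder: start at the delay that keeps job i's prep at
    ## or after job i-1's
    d <- max(0, ceiling((prev_prep - base_prep[i]) / unit) * unit)
    repeat {
      ist <- iv$start + d; ien <- iv$end + d
      if (length(pst)) {
        spread <- max(c(pen, ien)) - min(c(pst, ist))
        if (spread >= best) break        # more delay only widens the span
      }
      clash <- FALSE
      if (length(pst)) {
        for (q in seq_along(ist)) {
          if (any(pres == iv$resource[q] & pst < ien[q] & ist[q] < pen)) {
            clash <- TRUE; break
          }
        }
      }
      if (!clash)
        recurse(i + 1, c(pst, ist), c(pen, ien), c(pres, iv$resource),
                base_prep[i] + d)
      d <- d + unit
      if (d > d_cap) break
    }
    invisible()
  }
  recurse(1, numeric(0), numeric(0), character(0), -Inf)
  best
}

# fixed-step RK4 integrator for the rate law (independent of deSolve);
# requested times must sit on the dt grid
oracle_rk4_arf <- function(k, arf0, amine0, times, stoich = 2, dt = 0.01) {
  stopifnot(all(abs(times / dt - round(times / dt)) < 1e-9))
  targets <- round(times / dt)
  y <- c(arf0, amine0)
  deriv <- function(y) {
    r <- k * y[1] * y[2]^2
    c(-r, -stoich * r)
  }
  out <- numeric(length(times))
  hit0 <- which(targets == 0)
  if (length(hit0)) out[hit0] <- arf0
  for (s in seq_len(max(targets))) {
    k1 <- deriv(y); k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2); k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- which(targets == s)
    if (length(hit)) out[hit] <- y[1]
  }
  out
}

# small hardware configs used across tests
tiny_cfg <- function(n_reactors = 2, ...) {
  hardware_config(n_reactors = n_reactors, t_prep = 20, t_transit_in = 10,
                  t_rinse_a = 10, t_transit_out = 10, t_rinse_b = 10,
                  t_hplc = 30, time_unit = 10, ...)
}

demo_cfg <- function(...) {
  hardware_config(n_reactors = 2, t_prep = 300, t_transit_in = 30,
                  t_rinse_a = 60, t_transit_out = 30, t_rinse_b = 60,
                  t_hplc = 240, ...)
}

random_cfg <- function(seed) {
  set.seed(seed)
  hardware_config(n_reactors = sample(1:10, 1),
                  t_prep = runif(1, 30, 300),
                  t_transit_in = runif(1, 10, 60),
                  t_rinse_a = runif(1, 10, 120),
                  t_transit_out = runif(1, 10, 60),
                  t_rinse_b = runif(1, 10, 120),
                  t_hplc = runif(1, 60, 600))
}
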