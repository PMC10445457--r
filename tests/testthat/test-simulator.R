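test_that("resolved schedules replay without conflicts", {
  for (seed in c(3, 17, 29)) {
    cfg <- random_cfg(seed)
    jobs <- generate_job_batch(sample(2:20, 1), cfg, seed = seed)
    s <- schedule_jobs(jobs, cfg)
    log <- simulate_schedule(s)
    expect_equal(nrow(log$conflicts), 0)
    expect_true(all(log$job_delays$delta == 0))
    expect_equal(log$makespan, schedule_metrics(s)$makespan)
  }
})

test_that("simulator and collision detection agree on feasibility", {
  ## mutual-oracle check on raw (unresolved) schedules, which may or may
  ## not be feasible
  agree <- 0L
  n_infeasible <- 0L
  for (seed in 1:60) {
    cfg <- random_cfg(seed + 200)
    jobs <- generate_job_batch(sample(1:15, 1), cfg, seed = seed + 200,
                               residence_range = c(30, 900))
    s <- initial_schedule(lpt_order(jobs), cfg)
    det <- nrow(detect_collisions(s)) > 0
    sim <- nrow(simulate_schedule(s)$conflicts) > 0
    if (det) n_infeasible <- n_infeasible + 1L
    if (det == sim) agree <- agree + 1L
  }
  expect_equal(agree, 60L)
  expect_gt(n_infeasible, 0)   # the sample exercised both outcomes
  expect_lt(n_infeasible, 60)
})

test_that("a hand-built double booking yields exactly one HPLC conflict", {
  cfg <- hardware_config(n_reactors = 2)
  jobs <- reaction_jobs(job_id = c("a", "b"), temperature = 70,
                        residence_time = c(900, 600))
  s <- initial_schedule(jobs, cfg)
  ## force b's chain onto a's HPLC window
  a_hplc <- s$allocations[s$allocations$job_id == "a" &
                            s$allocations$resource == "hplc", ]
  b_hplc <- s$allocations[s$allocations$job_id == "b" &
                            s$allocations$resource == "hplc", ]
  shift <- a_hplc$start + 60 - b_hplc$start    # overlap by t_hplc - 60
  s$prep_start["b"] <- s$prep_start["b"] + shift
  s$allocations <- dropletlab:::.build_allocations(
    s$chains, s$jobs, unname(s$prep_start), unname(s$reactor_of))
  log <- simulate_schedule(s)
  expect_equal(nrow(log$conflicts[log$conflicts$resource == "hplc", ]), 1)
})

test_that("temperature pause delays a cooling reactor by the ramp time", {
  cfg <- hardware_config(n_reactors = 1, cool_rate = 0.2, heat_rate = 1.0)
  jobs <- reaction_jobs(job_id = c("hot", "cool"), temperature = c(100, 50),
                        residence_time = c(600, 500))
  s <- schedule_jobs(jobs, cfg)
  log <- simulate_schedule(s, pause_for_temperature = TRUE,
                           initial_temps = 100)
  expect_equal(nrow(log$conflicts), 0)
  d <- log$job_delays
  expect_equal(d$delta[d$job_id == "hot"], 0)       # reactor already at 100
  ## 50 degC swing at 0.2 degC/s: at least 250 s beyond the scheduled start
  expect_gte(d$delta[d$job_id == "cool"], 250)
  ## exact ramp arithmetic: ready = reactor release + 50 / 0.2
  release <- max(s$allocations$end[s$allocations$job_id == "hot" &
                                     grepl("^reactor", s$allocations$resource)])
  expect_equal(d$actual_prep[d$job_id == "cool"], release + 250)

  cmp <- compare_schedule(s, log)
  expect_equal(cmp$makespan_inflation,
               log$makespan - schedule_metrics(s)$makespan)
  expect_gte(cmp$makespan_inflation, 0)
})

test_that("pause deltas are zero when reactors start at target", {
  cfg <- hardware_config(n_reactors = 2)
  jobs <- reaction_jobs(job_id = "a", temperature = 80, residence_time = 300)
  s <- schedule_jobs(jobs, cfg)
  log <- simulate_schedule(s, pause_for_temperature = TRUE,
                           initial_temps = c(80, 25))
  expect_equal(log$job_delays$delta, 0)
  expect_equal(compare_schedule(s, log)$makespan_inflation, 0)

  ## pause off: deltas identically zero regardless of temperatures
  log2 <- simulate_schedule(s, pause_for_temperature = FALSE)
  expect_true(all(log2$job_delays$delta == 0))
})

test_that("pauses keep execution conflict-free and traces slope-bounded", {
  for (seed in c(5, 11)) {
    cfg <- random_cfg(seed + 40)
    jobs <- generate_job_batch(sample(4:12, 1), cfg, seed = seed + 40,
                               temperature_range = c(30, 180))
    s <- schedule_jobs(jobs, cfg)
    log <- simulate_schedule(s, pause_for_temperature = TRUE)
    expect_equal(nrow(log$conflicts), 0)
    expect_true(all(log$job_delays$delta >= 0))
    expect_gte(log$makespan, schedule_metrics(s)$makespan)
    ## temperature traces: time-ordered, slopes within the ramp rates
    for (r in unique(log$temp_traces$reactor)) {
      tr <- log$temp_traces[log$temp_traces$reactor == r, ]
      expect_false(is.unsorted(tr$time))
      dt <- diff(tr$time); dT <- diff(tr$temp)
      ok <- dt > 1e-9
      rate <- abs(dT[ok]) / dt[ok]
      lim <- ifelse(dT[ok] > 0, cfg$heat_rate, cfg$cool_rate)
      expect_true(all(rate <= lim + 1e-8))
    }
  }
})

test_that("events pair acquires and releases per job stage", {
  cfg <- demo_cfg()
  jobs <- reaction_jobs(job_id = c("a", "b"), temperature = 70,
                        residence_time = c(1800, 1200))
  log <- simulate_schedule(schedule_jobs(jobs, cfg))
  ev <- log$events
  key <- paste(ev$job_id, ev$stage, ev$resource)
  acq <- table(key[ev$event == "acquire"])
  rel <- table(key[ev$event == "release"])
  expect_equal(acq, rel)
  expect_false(is.unsorted(ev$time))
})

test_that("malformed schedules and mismatched logs are rejected", {
  cfg <- demo_cfg()
  jobs <- reaction_jobs(job_id = "a", temperature = 70, residence_time = 600)
  s <- schedule_jobs(jobs, cfg)
  broken <- s
  broken$allocations <- broken$allocations[broken$allocations$stage != "analysis", ]
  expect_error(simulate_schedule(broken), "missing stages")

  log <- simulate_schedule(s)
  other <- schedule_jobs(reaction_jobs(job_id = "zz", temperature = 70,
                                       residence_time = 600), cfg)
  expect_error(compare_schedule(other, log), "different jobs")
})
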