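test_that("LPT ordering is descending in residence time and stable on ties", {
  j <- reaction_jobs(job_id = c("r5", "r40", "r15"), temperature = 70,
                     residence_time = c(5, 40, 15) * 60)
  expect_equal(lpt_order(j)$residence_time, c(40, 15, 5) * 60)

  eq <- reaction_jobs(job_id = c("a", "b", "c"), temperature = 70,
                      residence_time = 600)
  expect_equal(lpt_order(eq)$job_id, c("a", "b", "c"))

  tie <- reaction_jobs(job_id = c("a", "b", "c"), temperature = 70,
                       residence_time = c(10, 10, 20))
  expect_equal(lpt_order(tie)$job_id, c("c", "a", "b"))

  expect_error(lpt_order(reaction_jobs(job_id = 1, temperature = 70,
                                       residence_time = 60)[0, ]), "empty")
})

test_that("single-job schedule starts at zero with the hand-summed span", {
  cfg <- hardware_config(t_prep = 60, t_transit_in = 60, t_rinse_a = 60,
                         t_transit_out = 60, t_rinse_b = 60, t_hplc = 60)
  j <- reaction_jobs(job_id = "a", temperature = 70, residence_time = 300)
  s <- initial_schedule(j, cfg)
  expect_equal(unname(s$prep_start), 0)
  expect_equal(nrow(detect_collisions(s)), 0)
  ## 660 s of stage time minus the rinse-A/residence and analysis/rinse-B
  ## overlaps: 60+60+300+60+60
  expect_equal(schedule_metrics(s)$makespan, 540)
})

test_that("back-to-back prep works for long reactions, collides for short", {
  cfg <- demo_cfg()
  long <- reaction_jobs(job_id = c("a", "b"), temperature = 70,
                        residence_time = c(1800, 1200))
  expect_equal(nrow(detect_collisions(initial_schedule(long, cfg))), 0)

  short <- reaction_jobs(job_id = c("a", "b"), temperature = 70,
                         residence_time = c(600, 120))
  expect_gt(nrow(detect_collisions(initial_schedule(short, cfg))), 0)
})

test_that("collision detection matches a hand-enumerated intersection", {
  ## two transit-out intervals [100,160) and [130,190) on the main flowpath
  cfg <- hardware_config(n_reactors = 2, t_prep = 35, t_transit_in = 5,
                         t_rinse_a = 5, t_transit_out = 60, t_rinse_b = 5,
                         t_hplc = 5)
  ## job a: prep 0-35, arrive 40, depart 40+60=100 -> transit out [100,160)
  ## job b: prep 35-70, arrive 75, depart 130      -> transit out [130,190)
  jobs <- reaction_jobs(job_id = c("a", "b"), temperature = 70,
                        residence_time = c(60, 55))
  s <- initial_schedule(jobs, cfg)
  a <- s$allocations
  expect_equal(a$start[a$job_id == "a" & a$stage == "transit_out"], 100)
  expect_equal(a$start[a$job_id == "b" & a$stage == "transit_out"], 130)
  coll <- detect_collisions(s)
  out_coll <- coll[coll$resource == "main_flowpath" &
                     coll$overlap_start == 130, ]
  expect_equal(nrow(out_coll), 1)
  expect_equal(out_coll$overlap_end, 160)
  expect_equal(sort(c(out_coll$job_a, out_coll$job_b)), c("a", "b"))
})

test_that("resolve reaches feasibility, only delays, and is idempotent", {
  for (seed in 1:40) {
    cfg <- random_cfg(seed)
    jobs <- generate_job_batch(sample(2:25, 1), cfg, seed = seed,
                               residence_range = c(30, 1500))
    s0 <- initial_schedule(lpt_order(jobs), cfg)
    s1 <- resolve_schedule(s0)
    expect_equal(nrow(detect_collisions(s1)), 0)
    ## monotone: prep never advanced
    expect_true(all(s1$prep_start[names(s0$prep_start)] -
                      s0$prep_start >= -1e-9))
    ## shifts on the time-unit grid
    expect_true(all(abs((s1$prep_start - s0$prep_start) / cfg$time_unit -
                          round((s1$prep_start - s0$prep_start) /
                                  cfg$time_unit)) < 1e-6))
    ## execution order preserved
    expect_false(is.unsorted(s1$prep_start[lpt_order(jobs)$job_id]))
    ## fixed point
    s2 <- resolve_schedule(s1)
    expect_equal(s2$prep_start, s1$prep_start)
    expect_equal(s2$n_shifts, s1$n_shifts)
  }
})

test_that("already-feasible schedules are returned unchanged", {
  cfg <- demo_cfg()
  jobs <- reaction_jobs(job_id = c("a", "b"), temperature = 70,
                        residence_time = c(1800, 1200))
  s0 <- initial_schedule(jobs, cfg)
  s1 <- resolve_schedule(s0)
  expect_equal(s1$prep_start, s0$prep_start)
  expect_equal(s1$n_shifts, 0)
  expect_equal(schedule_metrics(s1)$total_shift_time, 0)
})

test_that("LPT ordering does not hurt mean makespan versus arbitrary order", {
  lpt_ms <- numeric(100)
  arb_ms <- numeric(100)
  for (seed in 1:100) {
    cfg <- random_cfg(seed + 500)
    jobs <- generate_job_batch(sample(3:15, 1), cfg, seed = seed + 500,
                               residence_range = c(30, 1200))
    lpt_ms[seed] <- schedule_metrics(resolve_schedule(
      initial_schedule(lpt_order(jobs), cfg)))$makespan
    set.seed(seed)
    shuffled <- jobs[sample(nrow(jobs)), , drop = FALSE]
    arb_ms[seed] <- schedule_metrics(resolve_schedule(
      initial_schedule(shuffled, cfg)))$makespan
  }
  expect_lte(mean(lpt_ms), mean(arb_ms))
})

test_that("metrics report makespan, utilization in [0,1], and error cases", {
  cfg <- hardware_config(n_reactors = 3, t_prep = 2, t_transit_in = 1,
                         t_rinse_a = 1, t_transit_out = 1, t_rinse_b = 1,
                         t_hplc = 1)
  jobs <- reaction_jobs(job_id = 1:3, temperature = 70, residence_time = 3600)
  s <- schedule_jobs(jobs, cfg)
  m <- schedule_metrics(s)
  expect_true(all(m$utilization >= 0 & m$utilization <= 1))
  ## negligible bottlenecks: each reactor is busy ~ residence / makespan
  ru <- m$utilization[grepl("^reactor", names(m$utilization))]
  expect_true(all(abs(ru - 3600 / m$makespan) < 0.01))
  ## makespan at least a single-job span
  expect_gte(m$makespan, 3600 + 5)

  infeasible <- initial_schedule(
    reaction_jobs(job_id = 1:2, temperature = 70,
                  residence_time = c(600, 120)), demo_cfg())
  expect_error(schedule_metrics(infeasible), "infeasible")
})

test_that("scheduling 500 random jobs completes within the shift budget", {
  jobs <- generate_job_batch(500, hardware_config(), seed = 99)
  s <- schedule_jobs(jobs, hardware_config())
  expect_equal(nrow(detect_collisions(s)), 0)
  expect_equal(nrow(s$jobs), 500)
})

test_that("temperature-change warnings list consecutive reactor swings", {
  cfg <- hardware_config(n_reactors = 1)
  jobs <- reaction_jobs(job_id = c("hot", "cold"), temperature = c(150, 30),
                        residence_time = c(600, 500))
  s <- schedule_jobs(jobs, cfg)
  w <- temperature_change_warnings(s, threshold = 50)
  expect_equal(nrow(w), 1)
  expect_equal(w$delta_temp, 120)
})
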