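## Seeded synthetic benches standing in for the physical platform:
## SNAr concentration decays with HPLC-like multiplicative noise, a
## qualitative Buchwald-Hartwig amination response surface, and random job
## batches for scheduler stress tests. Every generator is reproducible from
## an explicit seed; the bench optimum is a property of the surface and
## never depends on the seed.

#' Ground-truth SNAr rate constants
#'
#' Reference rate constants for the model nucleophilic aromatic
#' substitution (4-fluoronitrobenzene + 1-methylpiperazine, acetonitrile)
#' used to seed the kinetic bench: 3.32e-4, 5.00e-4, 7.90e-4 and 10.6e-4
#' M^-2 s^-1 at 60, 70, 80 and 90 degC.
#'
#' @param k_by_temp Named numeric map degC -> k (M^-2 s^-1), strictly
#'   increasing in temperature.
#' @param order_arf,order_amine,amine_stoich Rate-law settings (see
#'   [integrate_rate_law()]).
#' @return List of class `snar_truth`.
#' @export
snar_ground_truth <- function(k_by_temp = c(`60` = 3.32e-4, `70` = 5.00e-4,
                                            `80` = 7.90e-4, `90` = 10.6e-4),
                              order_arf = 1, order_amine = 2,
                              amine_stoich = 2) {
  tt <- as.numeric(names(k_by_temp))
  if (any(is.na(tt)) || is.unsorted(tt, strictly = TRUE))
    stop("k_by_temp must be named by increasing temperature (degC)",
         call. = FALSE)
  if (is.unsorted(k_by_temp, strictly = TRUE))
    stop("rate constants must increase strictly with temperature",
         call. = FALSE)
  out <- list(k_by_temp = k_by_temp, order_arf = order_arf,
              order_amine = order_amine, amine_stoich = amine_stoich)
  class(out) <- "snar_truth"
  out
}

#' Kinetic experiment design
#'
#' The default mirrors the platform's demonstration design: two initial
#' aryl-halide concentrations (0.8 and 1.04 M) at 70 degC plus a single
#' concentration (1.04 M) at 60, 80 and 90 degC, each sampled at residence
#' times of 5, 10, 15, 25 and 40 minutes, with 2 equivalents of amine.
#'
#' @param times_s Residence times, s.
#' @param amine_equiv Amine equivalents relative to ArF.
#' @return `data.frame` with columns `temperature_C`, `arf0_M`, `amine0_M`,
#'   `time_s` (one row per planned measurement).
#' @export
snar_design <- function(times_s = c(5, 10, 15, 25, 40) * 60,
                        amine_equiv = 2) {
  cond <- data.frame(temperature_C = c(70, 70, 60, 80, 90),
                     arf0_M = c(0.8, 1.04, 1.04, 1.04, 1.04))
  cond$amine0_M <- amine_equiv * cond$arf0_M
  out <- merge(cond, data.frame(time_s = times_s))
  out <- out[order(out$temperature_C, out$arf0_M, out$time_s), ]
  rownames(out) <- NULL
  out[, c("temperature_C", "arf0_M", "amine0_M", "time_s")]
}

#' Generate a synthetic SNAr kinetic dataset
#'
#' Integrates the rate law for every design condition and applies
#' multiplicative Gaussian measurement noise (clipped at zero), emulating
#' HPLC quantification scatter.
#'
#' @param truth A [snar_ground_truth()].
#' @param design A [snar_design()]-style `data.frame`; all its temperatures
#'   must appear in `truth$k_by_temp`.
#' @param noise_sd Relative noise standard deviation (default 0.01).
#' @param seed Integer seed.
#' @return The design with a measured `arf_M` column appended.
#' @export
#' @examples
#' d <- generate_snar_dataset(seed = 7)
#' nrow(d)  # 25: (2 + 3) conditions x 5 residence times
generate_snar_dataset <- function(truth = snar_ground_truth(),
                                  design = snar_design(),
                                  noise_sd = 0.01, seed = 1) {
  tt <- as.character(design$temperature_C)
  missing_t <- setdiff(unique(tt), names(truth$k_by_temp))
  if (length(missing_t))
    stop("no ground-truth rate constant for temperature(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  withr::with_seed(.derive_seed(seed, 11L), {
    out <- design
    out$arf_M <- NA_real_
    key <- interaction(design$temperature_C, design$arf0_M, design$amine0_M,
                       drop = TRUE)
    for (g in levels(key)) {
      idx <- which(key == g)
      idx <- idx[order(design$time_s[idx])]
      k <- truth$k_by_temp[[tt[idx[1]]]]
      sim <- integrate_rate_law(
        k, c(arf = design$arf0_M[idx[1]], amine = design$amine0_M[idx[1]]),
        times = design$time_s[idx], order_arf = truth$order_arf,
        order_amine = truth$order_amine, amine_stoich = truth$amine_stoich)
      out$arf_M[idx] <- sim$arf
    }
    if (noise_sd > 0)
      out$arf_M <- pmax(out$arf_M * (1 + rnorm(nrow(out), 0, noise_sd)), 0)
    out
  })
}

#' Buchwald-Hartwig amination response surface
#'
#' A qualitative-faithful virtual response surface for the C-N coupling
#' campaigns: multiplicative catalyst and base effects, a monotone
#' temperature response that is maximal at the top of the range, and a
#' near-flat residence-time effect. The noiseless surface lies in [0, 1];
#' its optimum is the best catalyst-base cell at maximum temperature and
#' residence time. A XantPhos-like "dead" catalyst level is available for
#' domains that include it.
#'
#' @param catalyst_effects,base_effects Named multipliers in (0, 1].
#' @param temp_range Temperature bounds, degC.
#' @param temp_curvature Depth of the quadratic temperature penalty at the
#'   low end of the range (0.6: the surface falls to 40% of its plateau at
#'   `temp_range[1]`).
#' @param time_range Residence-time bounds, min.
#' @param time_span Total relative effect of residence time (0.02 = 2%,
#'   i.e. nearly flat).
#' @return List of class `bha_surface`.
#' @export
bha_surface <- function(catalyst_effects = c("tBuBrettPhos Pd G3" = 1.0,
                                             "tBuXPhos Pd G3" = 0.7,
                                             "XantPhos Pd G3" = 0.02),
                        base_effects = c(DBU = 1.0, BTMG = 0.8),
                        temp_range = c(50, 100), temp_curvature = 0.6,
                        time_range = c(5, 60), time_span = 0.02) {
  stopifnot(all(catalyst_effects > 0), all(catalyst_effects <= 1),
            all(base_effects > 0), all(base_effects <= 1),
            temp_range[1] < temp_range[2], time_range[1] < time_range[2],
            temp_curvature >= 0, temp_curvature < 1,
            time_span >= 0, time_span < 1)
  out <- list(catalyst_effects = catalyst_effects,
              base_effects = base_effects,
              temp_range = temp_range, temp_curvature = temp_curvature,
              time_range = time_range, time_span = time_span)
  class(out) <- "bha_surface"
  out
}

#' Noiseless surface response at a condition
#'
#' @param x Condition record (named list / one-row `data.frame`) with
#'   `catalyst`, `base`, `temperature_C`, `residence_time_min`.
#' @param surface A [bha_surface()].
#' @return Deterministic response in [0, 1].
#' @export
bha_surface_value <- function(x, surface = bha_surface()) {
  x <- as.list(x)
  cat_eff <- surface$catalyst_effects[[as.character(x$catalyst)]]
  base_eff <- surface$base_effects[[as.character(x$base)]]
  if (is.null(cat_eff)) stop("unknown catalyst: ", x$catalyst, call. = FALSE)
  if (is.null(base_eff)) stop("unknown base: ", x$base, call. = FALSE)
  tr <- surface$temp_range
  u <- (tr[2] - x$temperature_C) / (tr[2] - tr[1])   # 0 at Tmax
  te <- 1 - surface$temp_curvature * u^2
  rr <- surface$time_range
  v <- (x$residence_time_min - rr[1]) / (rr[2] - rr[1])
  tm <- (1 - surface$time_span) + surface$time_span * v
  unname(cat_eff * base_eff * te * tm)
}

#' Known optimum of a BHA surface over a domain
#'
#' The surface is separable and monotone in both continuous variables, so
#' the optimum is the best catalyst-base cell at maximum temperature and
#' residence time; this is verified by exhaustive grid search over the
#' categorical cells.
#'
#' @param surface A [bha_surface()].
#' @param domain Optional [domain_spec()] restricting catalysts/bases and
#'   the continuous ranges.
#' @return List with `x` (the optimal condition record) and `value`.
#' @export
bha_optimum <- function(surface = bha_surface(), domain = bha_domain(surface)) {
  cats <- domain$categorical$catalyst
  bases <- domain$categorical$base
  tmax <- domain$continuous$temperature_C[2]
  rmax <- domain$continuous$residence_time_min[2]
  best <- NULL
  for (ca in cats) for (ba in bases) {
    x <- list(temperature_C = tmax, residence_time_min = rmax,
              catalyst = ca, base = ba)
    v <- bha_surface_value(x, surface)
    if (is.null(best) || v > best$value) best <- list(x = x, value = v)
  }
  best
}

#' Optimization domain for the BHA campaigns
#'
#' Catalyst and base as two-level categoricals, temperature 50-100 degC and
#' residence time 5-60 min as continuous variables.
#'
#' @param surface A [bha_surface()] (supplies the continuous ranges).
#' @param catalysts,bases Level sets (default: the first two catalyst
#'   effects and both bases of the surface).
#' @return A [domain_spec()].
#' @export
bha_domain <- function(surface = bha_surface(),
                       catalysts = head(names(surface$catalyst_effects), 2),
                       bases = names(surface$base_effects)) {
  domain_spec(
    continuous = list(temperature_C = surface$temp_range,
                      residence_time_min = surface$time_range),
    categorical = list(catalyst = catalysts, base = bases))
}

#' HPLC-like measurement model
#'
#' The objective reported by the platform is product peak area divided by
#' the internal-standard peak area; the normalized value is invariant to
#' the internal-standard scale. The default 3% relative noise reflects the
#' platform's replicate reproducibility (its design target is < 5%).
#'
#' @param internal_standard_area Internal-standard peak area, arbitrary
#'   units.
#' @param relative_noise_sd Relative standard deviation of the measurement
#'   (must stay below 0.05).
#' @return List of class `measurement_model`.
#' @export
measurement_model <- function(internal_standard_area = 1000,
                              relative_noise_sd = 0.03) {
  stopifnot(internal_standard_area > 0,
            relative_noise_sd >= 0, relative_noise_sd < 0.05)
  out <- list(internal_standard_area = internal_standard_area,
              relative_noise_sd = relative_noise_sd)
  class(out) <- "measurement_model"
  out
}

#' Evaluate the virtual BHA bench at a condition
#'
#' Deterministic surface value times multiplicative measurement noise,
#' reported as normalized peak area. Uses the current RNG stream: seed the
#' caller (or use [make_bha_objective()] inside [run_campaign()]) for
#' reproducibility.
#'
#' @param x Condition record.
#' @param surface A [bha_surface()].
#' @param mm A [measurement_model()].
#' @return Observed objective (product area / internal-standard area).
#' @export
bha_objective <- function(x, surface = bha_surface(),
                          mm = measurement_model()) {
  value <- bha_surface_value(x, surface)
  product_area <- value * mm$internal_standard_area *
    (1 + rnorm(1, 0, mm$relative_noise_sd))
  max(product_area, 0) / mm$internal_standard_area
}

#' Seeded bench objective for closed-loop campaigns
#'
#' Wraps [bha_objective()] as a `function(x, iteration)` whose measurement
#' noise is reproducibly derived from `seed` and the iteration index, the
#' form [run_campaign()] expects.
#'
#' @param surface A [bha_surface()].
#' @param mm A [measurement_model()].
#' @param seed Integer seed.
#' @return Function `(x, iteration) -> y`.
#' @export
make_bha_objective <- function(surface = bha_surface(),
                               mm = measurement_model(), seed = 1) {
  function(x, iteration) {
    withr::with_seed(.derive_seed(seed, 23L, iteration),
                     bha_objective(x, surface, mm))
  }
}

#' Generate a random batch of reaction jobs
#'
#' Seeded random instances for scheduler property tests and demos.
#'
#' @param n Number of jobs (>= 1).
#' @param cfg A [hardware_config()] (bounds temperatures).
#' @param seed Integer seed.
#' @param residence_range Residence-time range, s (a zero-width range gives
#'   the all-equal LPT tie fixture).
#' @param temperature_range Temperature range, degC (clipped to config
#'   bounds).
#' @param photo_fraction Probability a job is photochemical.
#' @return A validated job table.
#' @export
generate_job_batch <- function(n, cfg = hardware_config(), seed = 1,
                               residence_range = c(60, 2400),
                               temperature_range = c(25, 150),
                               photo_fraction = 0.2) {
  stopifnot(n >= 1, diff(residence_range) >= 0)
  lo <- max(temperature_range[1], cfg$temp_min)
  hi <- min(temperature_range[2], cfg$temp_max)
  withr::with_seed(.derive_seed(seed, 31L), {
    mode <- ifelse(runif(n) < photo_fraction, "photochemical", "thermal")
    reaction_jobs(
      job_id = sprintf("job%03d", seq_len(n)),
      temperature = runif(n, lo, hi),
      residence_time = if (diff(residence_range) == 0)
        rep(residence_range[1], n) else
          runif(n, residence_range[1], residence_range[2]),
      mode = mode,
      led_power = ifelse(mode == "photochemical", runif(n), NA_real_),
      cfg = cfg)
  })
}
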