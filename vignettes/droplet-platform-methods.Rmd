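---
title: "Methods: scheduling, simulation, kinetics and optimization for parallel droplet reactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scheduling, simulation, kinetics and optimization for parallel droplet reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletlab)
```

`dropletlab` models an automated screening platform in which reaction
droplets run in parallel, independently temperature-controlled
microreactors, while three pieces of hardware are shared by every droplet:
a liquid handler that prepares droplets, a main flowpath that carries every
transit and rinse, and an HPLC that analyses every product. This vignette
records the models, the parameter choices, and the reasoning behind the
design decisions that were genuinely open.

## The resource model

Every droplet passes through the same rigid seven-stage lifecycle:

1. **prep** on the liquid handler (`t_prep`);
2. **transit in** along the main flowpath (`t_transit_in`) — starts the
   instant prep ends, because a prepared droplet must move to its heated
   reactor immediately to suppress room-temperature reactivity;
3. **rinse A** of the flowpath only (`t_rinse_a`), immediately after the
   inbound transit, running concurrently with the reaction;
4. **residence** in the assigned reactor (the job's residence time) — the
   reaction clock starts on arrival;
5. **transit out** to the HPLC sampling valve (`t_transit_out`) — starts
   the instant the residence ends, again for immediacy;
6. **rinse B** (`t_rinse_b`), which cleans the flowpath *and* the droplet's
   reactor; the reactor only accepts a new droplet after rinse B ends;
7. **analysis** on the HPLC (`t_hplc`), starting when transit out ends and
   overlapping rinse B, which uses disjoint hardware.

Intervals are half-open `[start, end)`, so back-to-back stages on one
resource are legal and a "collision" is an overlap of positive measure
between intervals of *distinct* droplets on one resource. Two choices here
deserve a note:

* The platform's multiple rinse droplets per transit are folded into one
  aggregate rinse duration per rinse type; no per-droplet rinse timing is
  modelled.
* The reactor-side rinse B interval is started at transit-out start rather
  than transit-out end. The stage chain as literally stated would leave the
  reactor unclaimed for the duration of transit out, and a sufficiently
  short droplet could in principle be slotted into that gap of an
  un-rinsed reactor. Starting the reactor-side block at transit-out start
  makes reactor occupancy contiguous from droplet arrival to rinse
  completion.

Stage durations are deployment properties, not universal constants; the
`hardware_config()` defaults (300/30/60/30/60/240 s, ten reactors) are
representative bench-top values, and `load_hardware_config()` *requires*
the six durations in any config file.

A consequence worth knowing: a single droplet with stages
(60, 60, 60, 300, 60, 60, 60) s spans 540 s, i.e. the 660 s of stage time
minus the two permitted overlaps (rinse A under the residence, analysis
under rinse B).

## The scheduler

Scheduling *m* droplets on *n* identical reactors to minimize makespan is
the classic parallel-machine problem; the package uses the Longest
Processing Time rule — jobs sorted from longest residence time to shortest,
stable under ties — followed by repair:

1. `initial_schedule()` lays preps back-to-back on the liquid handler and
   assigns each job the reactor that frees earliest (ties to the lowest
   index). This layout may contain collisions.
2. `resolve_schedule()` repeatedly finds the earliest collision and delays
   the *later-prepared* droplet of the pair (delaying the earlier one can
   never clear the overlap), in multiples of the config's `time_unit`
   (default 1 s, small relative to every stage), until no collision
   remains. A shifted droplet's whole chain moves rigidly, and preps never
   reorder: a shift cascades so that each later prep stays at or after its
   predecessor's.

Two implementation decisions on points the design left open:

* **Aggregated shifting.** Rather than literally moving one unit per scan,
  each iteration applies the smallest multiple of `time_unit` that clears
  the current earliest collision. On a persistent colliding pair this is
  exactly what unit-stepping converges to, and it cuts the number of scans
  by orders of magnitude (500 random jobs schedule in about a second).
  `n_shifts` still counts unit shifts, so it is comparable across the two
  formulations.
* **Order preservation.** Whether a shifted droplet may leapfrog a later
  droplet's prep was open; the package says no. This keeps the
  liquid-handler sequence physically meaningful and the algorithm's
  behavior predictable, at a known cost: on some instances (typically short
  reactions with inverted bottleneck pressure) a reordered schedule is
  strictly shorter. The test suite's exhaustive-search oracle therefore
  minimizes over the order-preserving delay space the algorithm is defined
  on; within that space `resolve_schedule()` matches the exhaustive
  minimum to within one time unit on every small instance tried.

Reactor assignment is fixed before shifting and not revisited — a known
limitation; revisiting assignment during repair could shorten some
schedules. The scheduler deliberately ignores heating and cooling
(`temperature_change_warnings()` flags large swings post hoc); the
simulator owns that behavior.

## The discrete-event simulator

`simulate_schedule()` replays a schedule as acquire/release events on
exclusive resources. It is implemented as occupancy counting per resource
— mechanically different from the scheduler's pairwise interval
intersection — so the two serve as mutual feasibility oracles: every
resolved schedule must replay with zero conflicts, and both detectors must
agree on raw, possibly-infeasible schedules.

With `pause_for_temperature = TRUE` the simulator reproduces the control
software's behavior that the scheduler ignores: a droplet's prep is delayed
until its reactor, ramping linearly from its previous setpoint, reaches the
droplet's target. Heating (cartridge heaters) is fast and cooling (through
the heat sink) slow; the defaults are 1.0 °C/s heating and 0.1 °C/s
cooling, config-overridable, as the hardware guidance is qualitative only.
Pauses move the paused droplet's chain rigidly and any contention this
creates is resolved first-come-first-served per resource, so pauses only
ever delay acquisition and the executed timeline stays conflict-free. The
simulated makespan is measured from the schedule's time origin (ramps run
from t = 0), so pauses can only inflate it. Whether the real control
software also delays inter-stage transfers during equilibration is not
documented; the package delays prep only.

## The kinetics engine

The model chemistry is the nucleophilic aromatic substitution of
4-fluoronitrobenzene (ArF, limiting) by 1-methylpiperazine with rate law

$$r = k\,[\mathrm{ArF}]\,[\mathrm{R_2NH}]^2,$$

integrated as d[ArF]/dt = −r, d[amine]/dt = −2r. The amine stoichiometry
(2 mol consumed per mol ArF: one equivalent as nucleophile, one consuming
the HF by-product) is a documented default, configurable to 1; recovery
tests use the generator's own setting so correctness is self-consistent.
Integration uses `deSolve`'s lsoda with rtol 1e-8 / atol 1e-10, tight
enough that solver bias is negligible against 1% measurement noise (the
suite checks agreement with a fixed-step RK4 oracle to 1e-6 M).

`fit_rate_constant()` estimates k at one temperature by bounded
Levenberg–Marquardt least squares of measured [ArF] against the integrated
model, jointly across all initial-concentration groups at that temperature;
flat series pin k at 0. `eyring_regression()` then fits the linearized
transition-state form

$$\ln(k/T) = -\frac{\Delta H^\ddagger}{R}\cdot\frac{1}{T}
  + \ln\frac{k_B}{h} + \frac{\Delta S^\ddagger}{R}$$

by *unweighted* ordinary least squares (a weighted variant sits behind the
`weights` argument), with CODATA constants at full precision and standard
errors propagated linearly from the slope and intercept. Rate constants are
SI (M⁻² s⁻¹) internally; printing scales by 10⁴ to match the conventional
reporting scale. On the bundled reference rate constants (3.32, 5.00, 7.90,
10.6 ×10⁻⁴ M⁻² s⁻¹ at 60–90 °C) the four-point fit gives
ΔH‡ ≈ 36.8 kJ/mol and ΔS‡ ≈ −202 J/(mol K), and the three-point fit
(90 °C excluded) 39.5 and −194 — the values the acceptance script
recomputes.

```{r}
fit <- eyring_regression(c(60, 70, 80, 90) + 273.15,
                         c(3.32, 5.00, 7.90, 10.6) * 1e-4)
fit
```

## The ask-tell optimizer

`new_optimizer()` / `ask()` / `tell()` implement closed-loop Bayesian
optimization over mixed domains: continuous variables min-max scaled to
[0, 1], categorical variables one-hot encoded, the encoding round-tripping
losslessly. The first `n_init = 5` proposals are a seeded Latin hypercube
(uniform categorical levels); afterwards a Gaussian-process surrogate is
fit to the encoded history and each proposal maximizes one acquisition
function — UCB (mean + 2·sd), EI (ξ = 0.01) or a Thompson draw — sampled
according to adaptive weights. An acquisition whose proposal improves the
incumbent has its weight multiplied by 1.5; weights are renormalized onto a
uniform floor (total mass 0.1) so no acquisition ever starves.

Deliberately simple, documented choices where a library would offer many:

* **Surrogate.** Matérn-5/2 kernel with one shared lengthscale (ARD off),
  signal and noise variances fitted by L-BFGS-B maximization of the log
  marginal likelihood from two starts, on standardized responses. With a
  few dozen observations the dense Cholesky algebra is exact and cheap,
  and the fitted noise floor is low enough that the posterior mean
  interpolates noiseless data to 1e-3.
* **Acquisition maximization** is candidate-pool search: 2000 seeded
  uniform points plus 10% local perturbations of the incumbent, the
  Thompson draw taken jointly over a 500-point subsample. Pool search is
  deterministic given the seed and adequate at the ≤ 10 encoded dimensions
  these campaigns use; branch-and-bound or evolutionary acquisition
  optimizers are out of scope.
* **Batches** of `n > 1` rely on the diversity of sampled acquisitions
  rather than fantasized updates — a known limitation for strongly
  parallel campaigns.
* Single-objective only.

All randomness derives from the state's seed and the current history
length, so identical seeds give identical trajectories and `ask()` is a
pure function of the state.

## The virtual bench

The bench exists so that every module is exercisable with no hardware and
no downloads; it emulates the *statistical shape* of platform data, not
any particular laboratory's numbers.

* **SNAr profiles** (`generate_snar_dataset()`): the default design is two
  initial ArF concentrations (0.8, 1.04 M) at 70 °C plus 1.04 M at 60, 80
  and 90 °C, five residence times (5–40 min) each — 25 measurements.
  Initial amine is 2 equivalents of ArF (the nucleophile-plus-scavenger
  convention; the demonstration campaigns' exact charge is not published).
  Noise is multiplicative Gaussian, 1% by default, clipped at zero —
  matching how platform reproducibility is quoted as a relative SD.
* **The Buchwald–Hartwig surface** (`bha_surface()`): multiplicative
  catalyst effects (tBuBrettPhos Pd G3 1.0, tBuXPhos Pd G3 0.7, and a
  XantPhos-like dead option at 0.02), base effects (DBU 1.0, BTMG 0.8), a
  quadratic temperature response rising monotonically to its maximum at
  100 °C (falling to 40% of plateau at 50 °C), and a near-flat
  residence-time effect spanning 2% — so the optimum is the
  (tBuBrettPhos, DBU) cell at maximum temperature, reachable only by
  getting both categoricals and the temperature right. The surface is
  qualitative-faithful, not data-fitted: no per-experiment campaign data
  exist to fit, so every quantitative optimizer test is stated against
  the bench's own known optimum, never against a published campaign value.
* **Measurement model**: the objective is product peak area normalized by
  an internal-standard peak area, invariant to the standard's scale, with
  3% relative noise by default (the replicate-level scatter of the
  platform's detector boards; the construction refuses anything at or
  above the 5% reproducibility envelope).

What passing tests on this bench do *not* show: robustness to the failure
modes of real campaigns — evaporation and charge errors, HPLC peak
overlap, catalyst decomposition, non-Gaussian outliers, or solvent effects
(the bench has no solvent axis). The DMF-versus-DMSO performance gap seen
on hardware depends on real chemistry and is intentionally out of the
bench's scope.

## Problem sizes and tolerances in the test suite

The suite's study conditions were fixed before measurement and are sized
for a single CPU: 200 random job batches (1–50 jobs, 1–10 reactors,
randomized stage durations) for the scheduler/simulator mutual-oracle
check; 20 coarse-grid instances (≤ 4 jobs, ≤ 2 reactors, 10 s unit) for
the exhaustive-search comparison; 100 seeds for the 1%-noise rate-constant
recovery (median |bias| < 2%) and 50 seeds for end-to-end ΔH‡ recovery
(median within 5%); 20 seeded 30-experiment campaigns for the optimizer
(≥ 80% must bring the incumbent within 10% of the bench optimum — echoing
"an optimum within a few dozen experiments", since real campaign yields
are not reproducible from a desk). The whole suite runs in about two
minutes.

## Known limitations

* Reactor assignment is never revisited during collision repair.
* Order-preserving shifting is provably suboptimal on some instances (see
  above); the gap is the price of a predictable liquid-handler sequence.
* The temperature model is a linear ramp with two rates; no thermal mass,
  PID behavior or photochemical heat load.
* The GP surrogate uses a single lengthscale; strongly anisotropic
  response surfaces would benefit from ARD, which is off by default.
* Valve-level hardware states, droplet volumes and pressures are not
  modelled.
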