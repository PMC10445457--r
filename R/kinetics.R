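## Reaction-kinetics engine for the SNAr model system:
## rate law r = k [ArF] [R2NH]^2, per-temperature rate-constant fitting by
## nonlinear least squares against the integrated rate law, and Eyring
## analysis ln(k/T) vs 1/T for activation enthalpy and entropy.

#' Integrate the third-order SNAr rate law
#'
#' Solves d[ArF]/dt = -k [ArF]^a [amine]^b with the amine consumed at
#' `amine_stoich` mol per mol of ArF (default 2: one equivalent acts as the
#' nucleophile and a second scavenges the HF by-product). Default orders are
#' a = 1, b = 2. Uses an adaptive solver (lsoda) with tight tolerances so
#' integration error is negligible next to measurement noise.
#'
#' @param k Rate constant, M^-2 s^-1 (>= 0).
#' @param c0 Named list or vector with initial concentrations `arf` and
#'   `amine`, M.
#' @param times Increasing observation times, s.
#' @param order_arf,order_amine Reaction orders (fixed 1 and 2 for the
#'   SNAr rate law; other values enable a generic power-law mode).
#' @param amine_stoich Mol amine consumed per mol ArF (default 2).
#' @param rtol,atol Solver tolerances.
#' @return `data.frame` with columns `time`, `arf`, `amine`, `product`
#'   (`product = arf0 - arf`), one row per requested time.
#' @export
#' @examples
#' integrate_rate_law(5e-4, c(arf = 1.04, amine = 2.08),
#'                    times = c(5, 10, 15, 25, 40) * 60)
integrate_rate_law <- function(k, c0, times, order_arf = 1, order_amine = 2,
                               amine_stoich = 2, rtol = 1e-8, atol = 1e-10) {
  c0 <- as.list(c0)
  if (is.null(c0$arf) || is.null(c0$amine))
    stop("c0 must provide 'arf' and 'amine'", call. = FALSE)
  if (!is.finite(k) || k < 0) stop("k must be >= 0", call. = FALSE)
  if (c0$arf < 0 || c0$amine < 0)
    stop("initial concentrations must be >= 0", call. = FALSE)
  if (length(times) == 0 || any(diff(times) <= 0) || any(times < 0))
    stop("times must be nonnegative and strictly increasing", call. = FALSE)

  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  if (k == 0 || c0$arf == 0) {
    out <- data.frame(time = tt, arf = c0$arf, amine = c0$amine)
  } else {
    deriv <- function(t, y, parms) {
      r <- k * max(y[1], 0)^order_arf * max(y[2], 0)^order_amine
      list(c(-r, -amine_stoich * r))
    }
    sol <- deSolve::ode(y = c(arf = c0$arf, amine = c0$amine), times = tt,
                        func = deriv, parms = NULL, rtol = rtol, atol = atol,
                        method = "lsoda")
    out <- as.data.frame(sol)
    names(out)[1] <- "time"
  }
  out$arf <- pmax(out$arf, 0)
  out$amine <- pmax(out$amine, 0)
  out$product <- c0$arf - out$arf
  if (prepend) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the rate constant at one temperature
#'
#' Nonlinear least squares of measured ArF concentrations against the
#' integrated rate law, jointly across all initial-concentration groups at
#' that temperature (bounded Levenberg-Marquardt, k >= 0).
#'
#' @param data `data.frame` with columns `time_s`, `arf_M`, `arf0_M`,
#'   `amine0_M` for a single temperature; rows from different initial
#'   concentrations are grouped by their (`arf0_M`, `amine0_M`) pair.
#' @param k0 Positive initial guess for k, M^-2 s^-1.
#' @param order_arf,order_amine,amine_stoich Passed to
#'   [integrate_rate_law()].
#' @return List of class `rate_fit`: `k`, `se` (asymptotic standard error;
#'   `NA` when k is pinned at the 0 boundary), `n_obs`, `converged`.
#' @export
fit_rate_constant <- function(data, k0 = 1e-4, order_arf = 1,
                              order_amine = 2, amine_stoich = 2) {
  need <- c("time_s", "arf_M", "arf0_M", "amine0_M")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("kinetic data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (!is.finite(k0) || k0 <= 0) stop("k0 must be > 0", call. = FALSE)

  grp <- interaction(data$arf0_M, data$amine0_M, drop = TRUE)
  pred_all <- function(k) {
    out <- numeric(nrow(data))
    for (g in levels(grp)) {
      idx <- which(grp == g)
      o <- order(data$time_s[idx]); idx <- idx[o]
      sim <- integrate_rate_law(
        k, c(arf = data$arf0_M[idx[1]], amine = data$amine0_M[idx[1]]),
        times = data$time_s[idx], order_arf = order_arf,
        order_amine = order_amine, amine_stoich = amine_stoich)
      out[idx] <- sim$arf
    }
    out
  }

  y <- data$arf_M
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ pred_all(k), start = list(k = k0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## degenerate data (e.g. flat series): fall back to 1-D profile search
    sse <- function(lk) sum((y - pred_all(exp(lk)))^2)
    opt <- stats::optimize(sse, interval = log(c(k0 * 1e-6, k0 * 1e6)))
    k_hat <- exp(opt$minimum)
    if (sse(log(k0 * 1e-6)) <= opt$objective + 1e-30) k_hat <- 0
    out <- list(k = k_hat, se = NA_real_, n_obs = nrow(data),
                converged = FALSE)
  } else {
    k_hat <- unname(coef(fit)["k"])
    se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
    if (k_hat < .Machine$double.eps) { k_hat <- 0; se <- NA_real_ }
    out <- list(k = k_hat, se = unname(se), n_obs = nrow(data),
                converged = TRUE)
  }
  class(out) <- "rate_fit"
  out
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.4g M^-2 s^-1 (se %.2g), n = %d\n",
              x$k, x$se, x$n_obs))
  invisible(x)
}

#' Eyring regression of rate constants against temperature
#'
#' Ordinary least squares of ln(k/T) on 1/T. Transition-state theory gives
#' the linearized Eyring form
#' ln(k/T) = -dH/R * (1/T) + ln(kB/h) + dS/R,
#' so the activation enthalpy is `dH = -slope * R` and the activation
#' entropy is `dS = (intercept - ln(kB/h)) * R`. Standard errors are
#' propagated linearly from the slope/intercept standard errors.
#'
#' @param temperature_K Absolute temperatures, K (>= 2 distinct values).
#' @param k Rate constants at those temperatures (> 0).
#' @param weights Optional OLS weights (the default, `NULL`, is the plain
#'   unweighted regression).
#' @return List of class `eyring_fit`: `slope` (K), `intercept`, `se_slope`,
#'   `se_intercept`, `dH` (kJ/mol), `dS` (J/mol/K), `se_dH`, `se_dS`,
#'   `n`, `constants`, `data`.
#' @export
#' @examples
#' fit <- eyring_regression(c(60, 70, 80, 90) + 273.15,
#'                          c(3.32, 5.00, 7.90, 10.6) * 1e-4)
#' c(fit$dH, fit$dS)
eyring_regression <- function(temperature_K, k, weights = NULL) {
  if (length(temperature_K) != length(k))
    stop("temperature_K and k must have equal length", call. = FALSE)
  if (length(unique(temperature_K)) < 2)
    stop("need at least 2 distinct temperatures", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all rate constants must be positive", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperatures must be in kelvin (> 0)",
                                    call. = FALSE)
  y <- log(k / temperature_K)
  x <- 1 / temperature_K
  fit <- if (is.null(weights)) lm(y ~ x) else lm(y ~ x, weights = weights)
  cf <- summary(fit)$coefficients
  slope <- cf["x", "Estimate"]; intercept <- cf["(Intercept)", "Estimate"]
  se_slope <- cf["x", "Std. Error"]; se_int <- cf["(Intercept)", "Std. Error"]
  out <- list(slope = slope, intercept = intercept,
              se_slope = se_slope, se_intercept = se_int,
              dH = -slope * .const$R / 1000,
              dS = (intercept - log(.const$kB / .const$h)) * .const$R,
              se_dH = se_slope * .const$R / 1000,
              se_dS = se_int * .const$R,
              n = length(k), constants = .const,
              data = data.frame(temperature_K = temperature_K, k = k))
  class(out) <- "eyring_fit"
  out
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("<eyring_fit> %d temperatures\n", x$n))
  cat(sprintf("  dH = %.1f +/- %.1f kJ/mol, dS = %.0f +/- %.0f J/mol/K\n",
              x$dH, x$se_dH, x$dS, x$se_dS))
  invisible(x)
}

#' Predict a rate constant from a fitted Eyring line
#'
#' Evaluates k = T * exp(intercept + slope / T) on the fitted scale.
#'
#' @param fit An [eyring_regression()] result.
#' @param temperature_K Absolute temperature(s), K (> 0).
#' @return Predicted rate constant(s), M^-2 s^-1.
#' @export
predict_k <- function(fit, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  temperature_K * exp(fit$intercept + fit$slope / temperature_K)
}

#' Full kinetics workflow: per-temperature fits plus Eyring analysis
#'
#' @param data Kinetic dataset: `data.frame` with columns `temperature_C`,
#'   `arf0_M`, `amine0_M`, `time_s`, `arf_M`.
#' @param k0 Initial guess for each per-temperature fit.
#' @param exclude_temps Optional temperatures (degrees C) left out of the
#'   Eyring regression (their rate constants are still fitted and reported).
#' @param ... Passed to [fit_rate_constant()].
#' @return List of class `kinetics_fit`: `rate_constants` (data.frame with
#'   `temperature_C`, `k`, `se`, `in_eyring`) and `eyring`
#'   (an `eyring_fit`).
#' @export
fit_kinetics <- function(data, k0 = 1e-4, exclude_temps = NULL, ...) {
  temps <- sort(unique(data$temperature_C))
  fits <- lapply(temps, function(tc)
    fit_rate_constant(data[data$temperature_C == tc, , drop = FALSE],
                      k0 = k0, ...))
  ks <- vapply(fits, `[[`, numeric(1), "k")
  ses <- vapply(fits, `[[`, numeric(1), "se")
  keep <- !(temps %in% exclude_temps)
  if (sum(keep) < 2)
    stop("need at least 2 temperatures in the Eyring regression", call. = FALSE)
  ey <- eyring_regression(temps[keep] + 273.15, ks[keep])
  out <- list(rate_constants = data.frame(temperature_C = temps, k = ks,
                                          se = ses, in_eyring = keep),
              eyring = ey)
  class(out) <- "kinetics_fit"
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>\n")
  rc <- x$rate_constants
  for (i in seq_len(nrow(rc)))
    cat(sprintf("  %3g degC  k = %.3f x 10^-4 M^-2 s^-1%s\n",
                rc$temperature_C[i], rc$k[i] * 1e4,
                if (rc$in_eyring[i]) "" else "  (excluded from Eyring)"))
  print(x$eyring)
  invisible(x)
}
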