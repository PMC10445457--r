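## Ask-tell Bayesian optimization over mixed categorical/continuous
## reaction variables. The first few proposals are space-filling; after
## that a GP surrogate is fit to the (encoded) history and each proposal
## maximizes one of a set of acquisition functions -- upper confidence
## bound, expected improvement, or a Thompson sample -- chosen at random
## with weights that adapt to favor acquisitions whose proposals have been
## improving the incumbent. Acquisitions are maximized over a seeded
## candidate pool, so whole trajectories are reproducible from one seed.

#' Create an ask-tell optimizer
#'
#' @param domain A [domain_spec()].
#' @param seed Integer seed; all randomness in [ask()] derives from it and
#'   the current history length, so identical seeds give identical
#'   trajectories.
#' @param n_init Number of space-filling (Latin hypercube) observations
#'   before the surrogate is used (default 5).
#' @param acquisitions Acquisition functions to sample from.
#' @param weight_floor Total probability mass guaranteed to the acquisition
#'   weights' uniform floor (default 0.1): every weight stays at or above
#'   `weight_floor / length(acquisitions)` so no acquisition starves.
#' @param weight_gain Multiplicative reward applied to an acquisition's
#'   weight when its proposal improves the incumbent.
#' @param ucb_beta UCB exploration coefficient (score = mean + beta * sd).
#' @param ei_xi EI improvement margin.
#' @param pool_size Candidate-pool size for acquisition maximization
#'   (>= 2000 by default; 10% of it is local perturbations of the
#'   incumbent).
#' @param thompson_pool Pool subset size for the joint Thompson draw.
#' @return Object of class `optimizer_state`.
#' @seealso [ask()], [tell()], [incumbent()], [run_campaign()]
#' @export
new_optimizer <- function(domain, seed = 1, n_init = 5,
                          acquisitions = c("ucb", "ei", "thompson"),
                          weight_floor = 0.1, weight_gain = 1.5,
                          ucb_beta = 2, ei_xi = 0.01,
                          pool_size = 2000, thompson_pool = 500) {
  stopifnot(inherits(domain, "domain_spec"), n_init >= 1,
            weight_floor >= 0, weight_floor < 1, pool_size >= 10)
  state <- list(domain = domain, seed = as.integer(seed), n_init = n_init,
                acquisitions = acquisitions,
                acquisition_weights = setNames(rep(1 / length(acquisitions),
                                                   length(acquisitions)),
                                               acquisitions),
                weight_floor = weight_floor, weight_gain = weight_gain,
                ucb_beta = ucb_beta, ei_xi = ei_xi,
                pool_size = pool_size, thompson_pool = thompson_pool,
                history = NULL)
  class(state) <- "optimizer_state"
  state
}

#' @export
print.optimizer_state <- function(x, ...) {
  n <- if (is.null(x$history)) 0L else nrow(x$history)
  cat(sprintf("<optimizer_state> %d observation(s), seed %d\n", n, x$seed))
  w <- x$acquisition_weights
  cat("  weights:", paste(sprintf("%s %.2f", names(w), w), collapse = ", "), "\n")
  if (n > 0) {
    inc <- incumbent(x)
    cat(sprintf("  incumbent y = %.4g\n", inc$.y))
  }
  invisible(x)
}

## internal: candidate pool (encoded); 10% local perturbations of the best x
.candidate_pool <- function(state, d, best_enc) {
  m <- state$pool_size
  m_local <- floor(m / 10)
  M <- .random_encoded(d, m)
  if (m_local > 0 && !is.null(best_enc)) {
    p_cont <- length(d$continuous)
    loc <- matrix(rep(best_enc, m_local), m_local, byrow = TRUE)
    if (p_cont > 0) {
      jit <- matrix(rnorm(m_local * p_cont, 0, 0.05), m_local, p_cont)
      loc[, seq_len(p_cont)] <- pmin(pmax(loc[, seq_len(p_cont)] + jit, 0), 1)
    }
    j <- p_cont
    for (nm in names(d$categorical)) {
      lv <- d$categorical[[nm]]
      flip <- runif(m_local) < 0.2
      if (any(flip)) {
        loc[flip, j + seq_along(lv)] <- 0
        pick <- sample.int(length(lv), sum(flip), replace = TRUE)
        loc[cbind(which(flip), j + pick)] <- 1
      }
      j <- j + length(lv)
    }
    M[(m - m_local + 1):m, ] <- loc
  }
  M
}

#' Request the next condition(s) to evaluate
#'
#' Before `n_init` observations have been told, proposals are seeded
#' space-filling draws (Latin hypercube over the continuous block, uniform
#' categorical levels). Afterwards a GP surrogate is fit to the encoded
#' history and, for each requested point, one acquisition function is
#' sampled according to the current acquisition weights and maximized over
#' a seeded candidate pool.
#'
#' `ask()` is deterministic given the state: calling it twice on the same
#' state returns the same proposals.
#'
#' @param state An `optimizer_state`.
#' @param n Number of proposals (>= 1).
#' @return `data.frame` of condition records with a `.acquisition` column
#'   recording which acquisition proposed each point (`"init"` during the
#'   space-filling phase).
#' @export
ask <- function(state, n = 1) {
  stopifnot(inherits(state, "optimizer_state"), n >= 1)
  d <- state$domain
  h <- state$history
  n_obs <- if (is.null(h)) 0L else nrow(h)

  if (n_obs < state$n_init) {
    props <- withr::with_seed(.derive_seed(state$seed, n_obs, 1L), {
      .decode_rows(.lhs_encoded(d, n), d)
    })
    props$.acquisition <- "init"
    return(props)
  }

  withr::with_seed(.derive_seed(state$seed, n_obs, 2L), {
    var_names <- c(names(d$continuous), names(d$categorical))
    X <- encode_design(h[, var_names, drop = FALSE], d)
    y <- h$.y
    gp <- gp_fit(X, y)
    best_enc <- X[which.max(y), ]
    pool <- .candidate_pool(state, d, best_enc)
    w <- state$acquisition_weights
    picks <- matrix(0, n, n_encoded(d))
    used <- character(n)
    pred <- gp_predict(gp, pool)
    for (i in seq_len(n)) {
      acq <- sample(names(w), 1, prob = w)
      used[i] <- acq
      score <- switch(acq,
        ucb = pred$mean + state$ucb_beta * pred$sd,
        ei = {
          imp <- pred$mean - max(y) - state$ei_xi
          z <- ifelse(pred$sd > 0, imp / pred$sd, 0)
          ifelse(pred$sd > 0, imp * pnorm(z) + pred$sd * dnorm(z),
                 pmax(imp, 0))
        },
        thompson = {
          idx <- sample.int(nrow(pool), min(state$thompson_pool, nrow(pool)))
          draw <- rep(-Inf, nrow(pool))
          draw[idx] <- gp_sample(gp, pool[idx, , drop = FALSE], 1)[, 1]
          draw
        })
      picks[i, ] <- pool[which.max(score), ]
    }
    props <- .decode_rows(picks, d)
    props$.acquisition <- used
    props
  })
}

#' Report measured outcomes back to the optimizer
#'
#' Extends the history and updates the acquisition weights: each
#' observation that improves the incumbent multiplies its proposing
#' acquisition's weight by `weight_gain`; weights are then renormalized
#' onto a uniform floor so every acquisition keeps at least
#' `weight_floor / n_acquisitions` probability.
#'
#' @param state An `optimizer_state`.
#' @param x `data.frame` of evaluated condition records (may carry a
#'   `.acquisition` column, as returned by [ask()]).
#' @param y Numeric objective values (finite), one per row of `x`.
#' @return The updated `optimizer_state`.
#' @export
tell <- function(state, x, y) {
  stopifnot(inherits(state, "optimizer_state"))
  if (is.null(x) || nrow(x) == 0) return(state)
  if (length(y) != nrow(x)) stop("one y per condition row", call. = FALSE)
  if (any(!is.finite(y))) stop("objective values must be finite", call. = FALSE)
  acq <- if (".acquisition" %in% names(x)) x$.acquisition else
    rep("manual", nrow(x))
  x <- x[, setdiff(names(x), ".acquisition"), drop = FALSE]
  ## domain check
  for (i in seq_len(nrow(x))) encode_condition(x[i, , drop = FALSE],
                                               state$domain)
  n0 <- if (is.null(state$history)) 0L else nrow(state$history)
  new <- x
  new$.y <- y
  new$.acquisition <- acq
  new$.iteration <- n0 + seq_len(nrow(x))

  w <- state$acquisition_weights
  best <- if (n0 > 0) max(state$history$.y) else -Inf
  for (i in seq_len(nrow(new))) {
    if (new$.y[i] > best && acq[i] %in% names(w))
      w[acq[i]] <- w[acq[i]] * state$weight_gain
    best <- max(best, new$.y[i])
  }
  w <- w / sum(w)
  w <- (1 - state$weight_floor) * w + state$weight_floor / length(w)
  state$acquisition_weights <- w
  state$history <- if (is.null(state$history)) new else
    rbind(state$history, new)
  state
}

#' Best observation so far
#'
#' @param state An `optimizer_state` with nonempty history.
#' @return One-row `data.frame`: the maximum-objective observation
#'   (earliest one on ties).
#' @export
incumbent <- function(state) {
  h <- state$history
  if (is.null(h) || nrow(h) == 0) stop("history is empty", call. = FALSE)
  h[which.max(h$.y), , drop = FALSE]
}

#' Run a closed-loop campaign against an objective function
#'
#' Repeats ask / evaluate / tell for `budget` experiments.
#'
#' @param state A fresh or resumed `optimizer_state`.
#' @param objective `function(x, iteration)` returning one finite objective
#'   value for a one-row condition `data.frame` (the iteration index lets
#'   benches seed their measurement noise).
#' @param budget Total number of experiments to run.
#' @return List with `state` (final optimizer state) and `log`
#'   (`data.frame`: one row per experiment with the condition, `.y`,
#'   `.acquisition`, `.iteration` and running `.incumbent_y`).
#' @export
run_campaign <- function(state, objective, budget) {
  stopifnot(budget >= 1)
  for (i in seq_len(budget)) {
    props <- ask(state, 1)
    y <- objective(props[, setdiff(names(props), ".acquisition"),
                         drop = FALSE], i)
    state <- tell(state, props, y)
  }
  log <- state$history
  log$.incumbent_y <- cummax(log$.y)
  list(state = state, log = log)
}
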