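## Gaussian-process surrogate on the encoded domain: Matern-5/2 kernel with
## a single shared lengthscale (ARD off), signal and observation-noise
## variances fitted by maximizing the log marginal likelihood. Small-n
## (dozens of points) dense-Cholesky implementation; exposes the posterior
## covariance needed for Thompson sampling over a candidate pool.

.gp_dist <- function(X1, X2) {
  ## Euclidean cross-distance matrix
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  sqrt(pmax(d2, 0))
}

.matern52 <- function(r) {
  s <- sqrt(5) * r
  (1 + s + s^2 / 3) * exp(-s)
}

.gp_kernel <- function(X1, X2, lengthscale, sf2) {
  sf2 * .matern52(.gp_dist(X1, X2) / lengthscale)
}

#' Fit a Gaussian-process surrogate
#'
#' @param X Numeric design matrix (encoded conditions, rows = observations).
#' @param y Numeric responses.
#' @param jitter Diagonal jitter added for numerical stability.
#' @return Object of class `gp_model` holding the Cholesky factor, the
#'   fitted hyperparameters (`lengthscale`, `sf2`, `sn2` on the
#'   standardized-response scale) and the training data.
#' @export
gp_fit <- function(X, y, jitter = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- mean(y)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  ys <- (y - mu) / sdy

  nll <- function(par) {
    l <- exp(par[1]); sf2 <- exp(par[2]); sn2 <- exp(par[3])
    K <- .gp_kernel(X, X, l, sf2)
    diag(K) <- diag(K) + sn2 + jitter
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }

  med_d <- {
    D <- .gp_dist(X, X)
    m <- median(D[upper.tri(D)][D[upper.tri(D)] > 0])
    if (!is.finite(m) || m <= 0) 0.5 else m
  }
  lower <- log(c(0.05, 1e-3, 1e-8))
  upper <- log(c(20, 50, 1))
  starts <- list(c(log(med_d), log(1), log(1e-2)),
                 c(log(max(0.2, med_d / 3)), log(1), log(1e-4)))
  best <- NULL
  for (p0 in starts) {
    op <- tryCatch(
      optim(pmin(pmax(p0, lower), upper), nll, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) best <- list(par = starts[[1]])
  l <- exp(best$par[1]); sf2 <- exp(best$par[2]); sn2 <- exp(best$par[3])
  K <- .gp_kernel(X, X, l, sf2)
  diag(K) <- diag(K) + sn2 + jitter
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  gp <- list(X = X, y_mu = mu, y_sd = sdy, ys = ys,
             lengthscale = l, sf2 = sf2, sn2 = sn2,
             L = L, alpha = alpha, jitter = jitter)
  class(gp) <- "gp_model"
  gp
}

#' Posterior mean and standard deviation at new points
#'
#' @param gp A [gp_fit()] model.
#' @param Xnew Matrix of encoded points.
#' @return List with `mean` and `sd` (response scale; `sd` is the latent
#'   function's marginal posterior standard deviation).
#' @export
gp_predict <- function(gp, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- .gp_kernel(Xnew, gp$X, gp$lengthscale, gp$sf2)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(gp$sf2 - colSums(V^2), 0)
  list(mean = gp$y_mu + gp$y_sd * mean_s,
       sd = gp$y_sd * sqrt(var_s))
}

#' Draw joint samples from the GP posterior at new points
#'
#' @param gp A [gp_fit()] model.
#' @param Xnew Matrix of encoded points.
#' @param n Number of joint draws.
#' @return Matrix (`nrow(Xnew)` x `n`) of posterior function draws on the
#'   response scale.
#' @export
gp_sample <- function(gp, Xnew, n = 1) {
  Xnew <- as.matrix(Xnew)
  m <- nrow(Xnew)
  Ks <- .gp_kernel(Xnew, gp$X, gp$lengthscale, gp$sf2)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$L), t(Ks))
  Kss <- .gp_kernel(Xnew, Xnew, gp$lengthscale, gp$sf2)
  S <- Kss - crossprod(V)
  diag(S) <- diag(S) + 1e-8
  Ls <- tryCatch(chol(S), error = function(e) {
    diag(S) <- diag(S) + 1e-5
    chol(S)
  })
  Z <- matrix(rnorm(m * n), m, n)
  draws <- mean_s + t(Ls) %*% Z
  gp$y_mu + gp$y_sd * draws
}
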