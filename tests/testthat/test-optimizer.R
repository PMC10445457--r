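bha_like_domain <- function() {
  domain_spec(
    continuous = list(temperature_C = c(50, 100),
                      residence_time_min = c(5, 60)),
    categorical = list(catalyst = c("tBuBrettPhos Pd G3", "tBuXPhos Pd G3"),
                       base = c("DBU", "BTMG")))
}

test_that("encoding scales, one-hots, and round-trips", {
  d <- bha_like_domain()
  ## 2 continuous + 2 + 2 one-hot = 6 dimensions
  expect_equal(n_encoded(d), 6)
  x <- list(temperature_C = 50, residence_time_min = 60,
            catalyst = "tBuBrettPhos Pd G3", base = "BTMG")
  v <- encode_condition(x, d)
  expect_equal(unname(v[1]), 0)      # low bound -> 0
  expect_equal(unname(v[2]), 1)      # high bound -> 1
  expect_equal(unname(v[3:4]), c(1, 0))
  expect_equal(unname(v[5:6]), c(0, 1))
  back <- decode_condition(v, d)
  expect_equal(back$catalyst, x$catalyst)
  expect_equal(back$base, x$base)
  expect_equal(back$temperature_C, 50)
  expect_equal(back$residence_time_min, 60)

  ## random round-trips
  set.seed(1)
  for (i in 1:25) {
    x <- list(temperature_C = runif(1, 50, 100),
              residence_time_min = runif(1, 5, 60),
              catalyst = sample(d$categorical$catalyst, 1),
              base = sample(d$categorical$base, 1))
    back <- decode_condition(encode_condition(x, d), d)
    expect_equal(back$temperature_C, x$temperature_C, tolerance = 1e-12)
    expect_equal(back$catalyst, x$catalyst)
    expect_equal(back$base, x$base)
  }

  expect_error(encode_condition(list(temperature_C = 120,
                                     residence_time_min = 10,
                                     catalyst = "tBuBrettPhos Pd G3",
                                     base = "DBU"), d), "outside")
  expect_error(encode_condition(list(temperature_C = 80,
                                     residence_time_min = 10,
                                     catalyst = "nope", base = "DBU"), d),
               "unknown level")
})

test_that("GP surrogate interpolates noiseless training data", {
  set.seed(7)
  X <- matrix(runif(30), 15, 2)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  gp <- gp_fit(X, y)
  pred <- gp_predict(gp, X)
  expect_lt(max(abs(pred$mean - y)), 1e-3)
  ## posterior draws concentrate at training points
  s <- gp_sample(gp, X[1:5, , drop = FALSE], 30)
  expect_lt(max(abs(rowMeans(s) - y[1:5])), 0.05)
})

test_that("fresh optimizer proposes distinct in-domain points", {
  d <- bha_like_domain()
  st <- new_optimizer(d, seed = 5)
  props <- ask(st, 3)
  expect_equal(nrow(props), 3)
  expect_equal(props$.acquisition, rep("init", 3))
  for (i in 1:3) expect_silent(encode_condition(props[i, ], d))
  expect_equal(nrow(unique(props)), 3)
  ## ask is deterministic given state
  expect_equal(ask(st, 3), props)
})

test_that("identical seeds give identical trajectories", {
  d <- bha_like_domain()
  obj <- function(x, i) {
    -abs(x$temperature_C - 90) / 50 + (x$catalyst == "tBuBrettPhos Pd G3")
  }
  r1 <- run_campaign(new_optimizer(d, seed = 11), obj, 10)
  r2 <- run_campaign(new_optimizer(d, seed = 11), obj, 10)
  expect_equal(r1$log, r2$log)
  r3 <- run_campaign(new_optimizer(d, seed = 12), obj, 10)
  expect_false(isTRUE(all.equal(r1$log$.y, r3$log$.y)))
})

test_that("optimizer converges on a 1-D quadratic", {
  d <- domain_spec(continuous = list(x = c(0, 1)))
  obj <- function(x, i) -(x$x - 0.3)^2
  res <- run_campaign(new_optimizer(d, seed = 42), obj, 25)
  expect_lt(abs(incumbent(res$state)$x - 0.3), 0.05)
})

test_that("categorical-only optimization prefers the best cell", {
  d <- domain_spec(categorical = list(cat = c("A", "B"), base = c("X", "Y")))
  cell_value <- c("A.X" = 0.2, "A.Y" = 0.5, "B.X" = 0.35, "B.Y" = 0.9)
  grid <- expand.grid(cat = c("A", "B"), base = c("X", "Y"),
                      stringsAsFactors = FALSE)
  grid <- rbind(grid, grid)   # 8 observations covering all cells twice
  best_cell_picked <- 0L
  for (seed in 1:50) {
    st <- new_optimizer(d, seed = seed, n_init = 5)
    set.seed(seed)
    y <- cell_value[paste(grid$cat, grid$base, sep = ".")] *
      (1 + rnorm(8, 0, 0.01))
    st <- tell(st, grid, unname(y))
    prop <- ask(st, 1)
    if (prop$cat == "B" && prop$base == "Y")
      best_cell_picked <- best_cell_picked + 1L
  }
  ## better than uniform-over-cells proposal frequency
  expect_gt(best_cell_picked / 50, 0.25)
})

test_that("tell validates inputs and leaves state unchanged on empty", {
  d <- bha_like_domain()
  st <- new_optimizer(d, seed = 3)
  expect_identical(tell(st, data.frame(), numeric(0)), st)
  x <- data.frame(temperature_C = 80, residence_time_min = 10,
                  catalyst = "tBuBrettPhos Pd G3", base = "DBU",
                  stringsAsFactors = FALSE)
  expect_error(tell(st, x, NaN), "finite")
  expect_error(tell(st, x, c(1, 2)), "one y per")
  bad <- x; bad$temperature_C <- 200
  expect_error(tell(st, bad, 0.5), "outside")
})

test_that("acquisition weights reward improving acquisitions with a floor", {
  d <- domain_spec(continuous = list(x = c(0, 1)))
  st <- new_optimizer(d, seed = 1)
  mk <- function(xv, acq) {
    out <- data.frame(x = xv)
    out$.acquisition <- acq
    out
  }
  ## three consecutive incumbent improvements from "ucb", none from "ei"
  st <- tell(st, mk(0.1, "ei"), 0.1)
  st <- tell(st, mk(0.2, "ucb"), 0.3)
  st <- tell(st, mk(0.3, "ucb"), 0.5)
  st <- tell(st, mk(0.4, "ucb"), 0.8)
  st <- tell(st, mk(0.5, "ei"), 0.2)   # no improvement
  w <- st$acquisition_weights
  expect_gt(w[["ucb"]], w[["ei"]])
  expect_equal(sum(w), 1)
  expect_true(all(w >= st$weight_floor / length(w) - 1e-12))
})

test_that("incumbent matches a brute-force scan and breaks ties early", {
  d <- domain_spec(continuous = list(x = c(0, 1)))
  st <- new_optimizer(d, seed = 2)
  expect_error(incumbent(st), "empty")
  set.seed(9)
  xs <- data.frame(x = runif(20))
  ys <- round(runif(20), 1)   # ties likely
  st <- tell(st, xs, ys)
  inc <- incumbent(st)
  expect_equal(inc$.y, max(ys))
  expect_equal(inc$.iteration, which(ys == max(ys))[1])
})
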