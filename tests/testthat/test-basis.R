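test_that("quantile knots match order-statistic interpolation", {
  expect_equal(quantile_knots(0:100, c(27.5, 72.5)), c(27.5, 72.5))
  expect_equal(formals(quantile_knots)$percentiles, quote(c(27.5, 72.5)))
  set.seed(21)
  for (rep in 1:200) {
    x <- rnorm(sample(10:200, 1))
    p <- sort(runif(2, 1, 99))
    expect_equal(quantile_knots(x, p),
                 c(oracle_quantile7(x, p[1] / 100),
                   oracle_quantile7(x, p[2] / 100)),
                 tolerance = 1e-12)
  }
  expect_error(quantile_knots(rep(1, 50), c(25, 75)), "strictly increasing")
  expect_error(quantile_knots(rnorm(10), c(75, 25)), "strictly increasing")
  expect_error(quantile_knots(rnorm(10), c(0, 50)), "inside")
})

test_that("spline specifications validate and count columns correctly", {
  expect_error(spline_spec("bspline", degree = 0, boundary_knots = c(0, 1)),
               "degree")
  expect_error(spline_spec(boundary_knots = c(1, 0)), "increasing")
  expect_error(spline_spec(internal_knots = c(5, 2), boundary_knots = c(0, 10)),
               "increasing")
  expect_error(spline_spec(internal_knots = 11, boundary_knots = c(0, 10)),
               "inside")
  expect_identical(
    spline_ncol(spline_spec("bspline", 2, c(3, 6), c(0, 10), intercept = FALSE)),
    4L)
  expect_identical(
    spline_ncol(spline_spec("natural_cubic", internal_knots = c(3, 6),
                            boundary_knots = c(0, 10), intercept = TRUE)),
    4L)
  x <- rnorm(50)
  for (spec in list(
    spline_spec("bspline", 3, c(-0.5, 0.5), c(-3, 3), intercept = TRUE),
    spline_spec("natural_cubic", internal_knots = 0, boundary_knots = c(-3, 3)))) {
    expect_identical(ncol(spline_basis(pmax(pmin(x, 3), -3), spec)),
                     spline_ncol(spec))
  }
})

test_that("natural cubic splines are linear beyond the boundary knots", {
  spec <- spline_spec("natural_cubic", internal_knots = c(4, 6),
                      boundary_knots = c(2, 8), intercept = TRUE)
  x_out <- c(seq(-5, 1.5, by = 0.25), seq(8.5, 15, by = 0.25))
  B <- spline_basis(x_out, spec)
  left <- B[x_out < 2, , drop = FALSE]
  right <- B[x_out > 8, , drop = FALSE]
  for (side in list(left, right)) {
    d2 <- diff(diff(side))  # equally spaced => second differences
    expect_lt(max(abs(d2)), 1e-8)
  }
})

test_that("quadratic B-spline bases match the Cox-de Boor recursion", {
  set.seed(5)
  for (rep in 1:20) {
    bk <- sort(runif(2, -10, 10))
    while (diff(bk) < 1) bk <- sort(runif(2, -10, 10))
    ik <- sort(runif(2, bk[1] + 0.1 * diff(bk), bk[2] - 0.1 * diff(bk)))
    deg <- sample(1:3, 1)
    spec <- spline_spec("bspline", deg, ik, bk, intercept = TRUE)
    x <- runif(40, bk[1] + 1e-6, bk[2] - 1e-6)
    ours <- spline_basis(x, spec)
    knots <- c(rep(bk[1], deg + 1), ik, rep(bk[2], deg + 1))
    expect_equal(ours, oracle_bspline(x, knots, deg), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # partition of unity and non-negativity with the intercept retained
    expect_equal(rowSums(ours), rep(1, 40), tolerance = 1e-10)
    expect_true(all(ours >= -1e-12))
  }
})

test_that("natural cubic bases span the truncated-power natural spline space", {
  set.seed(6)
  for (rep in 1:10) {
    ik <- sort(runif(3, 2, 8))
    spec <- spline_spec("natural_cubic", internal_knots = ik,
                        boundary_knots = c(0, 10))
    x <- runif(120, 0, 10)
    y <- rnorm(120)
    ours <- cbind(1, spline_basis(x, spec))
    oracle <- oracle_natural_basis(x, c(0, ik, 10))
    fit_ours <- drop(ours %*% qr.coef(qr(ours), y))
    fit_oracle <- drop(oracle %*% qr.coef(qr(oracle), y))
    expect_equal(fit_ours, fit_oracle, tolerance = 1e-8)
  }
})

test_that("cross-basis entries equal the direct double-loop summation", {
  set.seed(7)
  temp <- rnorm(30, 15, 5)
  var_spec <- default_var_spec(temp)
  lag_spec <- default_lag_spec(5L)
  cb <- cross_basis(temp, var_spec, lag_spec, 5L)
  bvar <- spline_basis(temp, var_spec)
  blag <- spline_basis(0:5, lag_spec)
  expect_equal(unname(cb$values), oracle_cross_basis(bvar, blag, 5L),
               tolerance = 1e-12)
  expect_identical(cb$valid_from, 6L)
  expect_true(all(is.na(cb$values[1:5, ])))
})

test_that("the default cross-basis is 4 x 4 over 21 lags", {
  sim <- simulate_city_series(tiny_cfg(500), seed = 2)
  cb <- cross_basis(sim$series$temp)
  expect_identical(cb$max_lag, 21L)
  expect_identical(ncol(cb$values), 16L)
  expect_identical(spline_ncol(cb$var_spec), 4L)
  expect_identical(spline_ncol(cb$lag_spec), 4L)
})

test_that("constant exposure gives identical complete cross-basis rows", {
  cb <- cross_basis(rep(12, 40), spline_spec("bspline", 2, c(10, 20), c(0, 30)),
                    default_lag_spec(4L), 4L)
  rows <- cb$values[cb$valid_from:40, ]
  expect_lt(max(abs(sweep(rows, 2L, rows[1, ]))), 1e-12)
})

test_that("the cross-basis is linear in the temperature basis", {
  # scaling every var-basis column by c scales the cross-basis by c; check
  # via the bilinear form: entries are linear in each Bvar evaluation
  set.seed(8)
  temp <- rnorm(25, 15, 4)
  var_spec <- default_var_spec(temp)
  lag_spec <- default_lag_spec(3L)
  cb <- cross_basis(temp, var_spec, lag_spec, 3L)
  bvar <- spline_basis(temp, var_spec)
  blag <- spline_basis(0:3, lag_spec)
  expect_equal(unname(cb$values[4:25, ]),
               3 * oracle_cross_basis(bvar / 3, blag, 3L)[4:25, ],
               tolerance = 1e-12)
  expect_error(cross_basis(rnorm(3), max_lag = 21L), "exceed")
})
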