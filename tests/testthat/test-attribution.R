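test_that("the MMT search finds an interior vertex and boundary minima", {
  # a curve that is exactly quadratic with vertex at 20: fit the basis to it
  spec_grid <- seq(0, 30, by = 0.01)
  spec <- spline_spec("bspline", 2, c(10, 20), c(0, 30), intercept = TRUE)
  B <- spline_basis(spec_grid, spec)
  eta_quad <- qr.coef(qr(B), (spec_grid - 20)^2)
  a_quad <- toy_assoc(eta_quad, intercept = TRUE)
  expect_equal(find_mmt(a_quad, c(1, 99)), 20, tolerance = 0.051)

  # monotone increasing curve: minimum at the lower end of the search range
  eta_mono <- qr.coef(qr(B), spec_grid * 2)
  a_mono <- toy_assoc(eta_mono, intercept = TRUE)
  q1 <- a_mono$temp_quantiles[2]
  expect_equal(find_mmt(a_mono, c(1, 99)), seq(q1, 30, by = 0.1)[1],
               tolerance = 1e-8)
})

test_that("the 0.1-degree grid MMT agrees with a fine-grid oracle", {
  set.seed(50)
  for (rep in 1:40) {
    a <- toy_assoc(rnorm(4))
    got <- find_mmt(a, c(1, 99))
    want <- oracle_fine_mmt(a, a$temp_quantiles[2], a$temp_quantiles[100])
    expect_lt(abs(got - want), 0.1 + 1e-9)
  }
})

test_that("attributable series vanish at the reference and under a null curve", {
  sim <- simulate_city_series(tiny_cfg(450), seed = 51)
  s <- sim$series
  a0 <- toy_assoc(rep(0, 4), temps = s$temp)
  r0 <- attributable_series(s, a0, 19)
  expect_identical(r0$attributable, rep(0, nrow(s)))

  flat <- s
  flat$temp <- rep(19, nrow(s))
  a1 <- toy_assoc(rnorm(4), temps = flat$temp)
  r1 <- attributable_series(flat, a1, 19)
  expect_lt(max(abs(r1$attributable)), 1e-12)
  expect_true(all(r1$label == "reference"))
})

test_that("per-day attribution equals a hand computation on a toy series", {
  set.seed(52)
  eta <- rnorm(4)
  days <- data.frame(
    date = seq(as.Date("2014-01-01"), by = "day", length.out = 10),
    yll = rep(100, 10), temp = c(2, 5, 12, 19, 22, 25, 28, 16, 9, 19),
    rh = 70, ws = 2, sunshine = 5, ap = 840, holiday = FALSE)
  s <- city_series(days)
  a <- toy_assoc(eta, temps = seq(0, 30, length.out = 50))
  mmt <- 19
  r <- attributable_series(s, a, mmt)
  B <- spline_basis(s$temp, a$var_spec)
  Bm <- spline_basis(mmt, a$var_spec)
  for (t in 1:10) {
    expect_equal(r$attributable[t],
                 sum((B[t, ] - Bm[1, ]) * eta), tolerance = 1e-12)
    expect_identical(r$label[t],
                     if (s$temp[t] < mmt) "cold"
                     else if (s$temp[t] > mmt) "heat" else "reference")
  }
})

test_that("attribution is centering-invariant and scales linearly with eta", {
  sim <- simulate_city_series(tiny_cfg(450), seed = 53)
  s <- sim$series
  eta <- rnorm(4)
  a1 <- toy_assoc(eta, temps = s$temp)
  a2 <- a1
  a2$reference <- a1$temp_quantiles[26]
  r1 <- attributable_series(s, a1, 18)
  r2 <- attributable_series(s, a2, 18)
  expect_identical(r1$attributable, r2$attributable)

  a3 <- a1
  a3$eta <- 3 * eta
  r3 <- attributable_series(s, a3, 18)
  expect_equal(r3$attributable, 3 * r1$attributable, tolerance = 1e-12)
})

test_that("attributable fractions partition exactly and pool by summation", {
  set.seed(54)
  series <- lapply(1:3, function(i)
    simulate_city_series(tiny_cfg(450), seed = 60 + i)$series)
  assocs <- lapply(1:3, function(i)
    toy_assoc(rnorm(4), temps = series[[i]]$temp))
  mmts <- c(17, 18.5, 20)
  pooled <- attributable_fraction(series, assocs, mmts)
  expect_equal(pooled[["af_total"]],
               pooled[["af_cold"]] + pooled[["af_heat"]], tolerance = 1e-12)
  # province pooling = sum of city attributable YLL over sum of city YLL
  num <- 0; den <- 0
  for (i in 1:3) {
    ci <- attributable_fraction(series[[i]], assocs[[i]], mmts[i])
    num <- num + ci[["attr_total"]]
    den <- den + ci[["yll_total"]]
  }
  expect_equal(pooled[["af_total"]], num / den, tolerance = 1e-12)
  expect_error(attributable_fraction(
    local({x <- series[[1]]; x$yll <- -x$yll; x}), assocs[[1]], 18),
    "positive")
})

test_that("a null association yields a zero attributable fraction", {
  sim <- simulate_city_series(tiny_cfg(450), seed = 55)
  a <- toy_assoc(rep(0, 4), temps = sim$series$temp)
  af <- attributable_fraction(sim$series, a, 19)
  expect_identical(unname(af[c("af_total", "af_cold", "af_heat")]), c(0, 0, 0))
})

test_that("Monte Carlo intervals collapse under zero covariance and are seeded", {
  sim <- simulate_city_series(tiny_cfg(450), seed = 56)
  s <- sim$series
  eta <- c(2, -1, 0.5, 3)
  a0 <- toy_assoc(eta, vcov = matrix(0, 4, 4), temps = s$temp)
  mmt <- find_mmt(a0)
  point <- attributable_fraction(s, a0, mmt)
  mc <- mc_eci(s, a0, mmt, n_iter = 50, seed = 1)
  expect_equal(unname(mc$eci["total", ]),
               rep(point[["af_total"]], 2), tolerance = 1e-12)

  a1 <- toy_assoc(eta, vcov = rand_psd(4, 0.1), temps = s$temp)
  m1 <- mc_eci(s, a1, mmt, n_iter = 100, seed = 7)
  m2 <- mc_eci(s, a1, mmt, n_iter = 100, seed = 7)
  expect_identical(m1$eci, m2$eci)
  m3 <- mc_eci(s, a1, mmt, n_iter = 100, seed = 8)
  expect_false(identical(m1$eci, m3$eci))
  # partition identity holds draw by draw
  expect_equal(m1$draws[, "total"], m1$draws[, "cold"] + m1$draws[, "heat"],
               tolerance = 1e-12)
  expect_error(mc_eci(s, a1, mmt, n_iter = 1), "n_iter")
})

test_that("refinding the MMT per draw widens or shifts but keeps additivity", {
  sim <- simulate_city_series(tiny_cfg(450), seed = 57)
  s <- sim$series
  a <- toy_assoc(c(2, -1, 0.5, 3), vcov = rand_psd(4, 0.05), temps = s$temp)
  mmt <- find_mmt(a)
  mr <- mc_eci(s, a, mmt, n_iter = 80, seed = 3, mmt_policy = "refind")
  expect_equal(mr$draws[, "total"], mr$draws[, "cold"] + mr$draws[, "heat"],
               tolerance = 1e-12)
})

test_that("attribute_burden returns a coherent pooled result", {
  sim <- simulate_city_series(tiny_cfg(600), seed = 58)
  ct <- fit_city(sim$series)
  assoc <- reduce_to_overall(ct$fit, ct$cb, sim$series$temp)
  ab <- attribute_burden(sim$series, assoc, n_mc = 200, seed = 5)
  expect_s3_class(ab, "attribution_result")
  expect_equal(ab$point[["af_total"]],
               ab$point[["af_cold"]] + ab$point[["af_heat"]],
               tolerance = 1e-12)
  expect_true(ab$eci["total", 1] <= ab$eci["total", 2])
  expect_identical(formals(attribute_burden)$n_mc, 1000L)
})
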