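test_that("a single study passes through unchanged under a fixed-effects fit", {
  set.seed(30)
  eta <- rnorm(4)
  inp <- meta_input(list(eta), list(rand_psd(4)))
  fit <- mvmeta_fit(inp, method = "fixed")
  expect_equal(unname(drop(fit$mu[1, ])), eta, tolerance = 1e-10)
  expect_identical(unname(fit$Psi), matrix(0, 4, 4))
})

test_that("scalar fixed-effects pooling equals the inverse-variance mean", {
  set.seed(31)
  y <- rnorm(10, 2)
  s2 <- runif(10, 0.05, 0.3)
  inp <- meta_input(as.list(y), lapply(s2, function(s) matrix(s, 1, 1)))
  fit <- mvmeta_fit(inp, method = "fixed")
  o <- oracle_ivw(y, s2)
  expect_equal(drop(fit$mu[1, 1]), o[["mu"]], tolerance = 1e-8)
  expect_equal(drop(fit$mu_vcov[1, 1]), o[["var"]], tolerance = 1e-8)
})

test_that("scalar ML random-effects fit matches an established reference", {
  skip_if_not_installed("metafor")
  set.seed(32)
  k <- 20
  tau2 <- 0.4
  s2 <- runif(k, 0.1, 0.5)
  y <- rnorm(k, 1.5, sqrt(tau2 + s2))
  inp <- meta_input(as.list(y), lapply(s2, function(s) matrix(s, 1, 1)))
  fit <- mvmeta_fit(inp)
  ref <- metafor::rma(yi = y, vi = s2, method = "ML")
  expect_equal(drop(fit$mu[1, 1]), as.numeric(ref$beta), tolerance = 1e-4)
  expect_equal(fit$Psi[1, 1], ref$tau2, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
})

test_that("Q degrees of freedom follow k*v - p*v for any configuration", {
  set.seed(33)
  for (rep in 1:12) {
    k <- sample(3:10, 1)
    v <- sample(1:4, 1)
    with_pred <- runif(1) < 0.5
    preds <- if (with_pred) data.frame(z = rnorm(k)) else NULL
    inp <- rand_meta_input(k, v, predictors = preds)
    q <- cochran_q(inp, predictor = if (with_pred) "z" else NULL)
    p <- 1L + as.integer(with_pred)
    expect_identical(unname(q[["df"]]), as.numeric(k * v - p * v))
  }
})

test_that("identical estimates give Q = 0 and complete shrinkage reproduces the mean", {
  eta <- c(1, -2, 0.5)
  S <- rand_psd(3, 0.2)
  inp <- meta_input(replicate(6, eta, simplify = FALSE),
                    replicate(6, S, simplify = FALSE))
  q <- cochran_q(inp)
  expect_equal(unname(q[["Q"]]), 0, tolerance = 1e-10)
  fit <- mvmeta_fit(inp, method = "fixed")
  b <- blup(inp, fit)
  for (ci in b) expect_equal(unname(ci$eta), eta, tolerance = 1e-8)
})

test_that("I-squared reproduces printed heterogeneity values from (Q, df)", {
  expect_equal(round(i_squared(115.8, 60), 1), 48.2)
  expect_equal(round(i_squared(83.0, 56), 1), 32.5)
  expect_equal(round(i_squared(87.6, 56), 1), 36.1)
  expect_equal(round(i_squared(109.3, 56), 1), 48.8)
  expect_equal(round(i_squared(90.0, 56), 1), 37.8)
  expect_identical(i_squared(40, 56), 0)   # floored at zero when Q <= df
})

test_that("the Wald test is null at zero effect and matches the scalar z-test", {
  # identical etas: the predictor coefficient is exactly zero
  eta <- c(0.3, -1)
  inp <- meta_input(replicate(5, eta, simplify = FALSE),
                    replicate(5, rand_psd(2, 0.1), simplify = FALSE),
                    predictors = data.frame(z = 1:5))
  fit <- mvmeta_fit(inp, predictor = "z", method = "fixed")
  expect_equal(unname(fit$wald[["W"]]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$wald[["p"]]), 1, tolerance = 1e-6)
  expect_identical(unname(fit$wald[["df"]]), 2)

  # scalar case: W = (estimate / se)^2
  set.seed(34)
  y <- rnorm(12) + 0.8 * (1:12)
  inp1 <- meta_input(as.list(y),
                     replicate(12, matrix(0.2, 1, 1), simplify = FALSE),
                     predictors = data.frame(z = 1:12))
  fit1 <- mvmeta_fit(inp1, predictor = "z")
  b <- fit1$mu[2, 1]
  se <- sqrt(fit1$mu_vcov[2, 2])
  expect_equal(unname(fit1$wald[["W"]]), (b / se)^2, tolerance = 1e-8)
})

test_that("AIC is definitional and deterministic", {
  set.seed(35)
  inp <- rand_meta_input(10, 2, psi_scale = 0.3,
                         predictors = data.frame(z = rnorm(10)))
  f0 <- mvmeta_fit(inp)
  f0b <- mvmeta_fit(inp)
  expect_identical(f0$AIC, f0b$AIC)
  f1 <- mvmeta_fit(inp, predictor = "z")
  expect_equal(f1$AIC - f0$AIC,
               -2 * (f1$loglik - f0$loglik) + 2 * (f1$n_par - f0$n_par),
               tolerance = 1e-10)
})

test_that("a useless meta-predictor usually worsens AIC", {
  set.seed(36)
  worse <- vapply(1:60, function(r) {
    inp <- rand_meta_input(12, 2, psi_scale = 0.2,
                           predictors = data.frame(z = rnorm(12)))
    mvmeta_fit(inp, predictor = "z")$AIC > mvmeta_fit(inp)$AIC
  }, logical(1))
  expect_gt(mean(worse), 0.5)
})

test_that("BLUPs interpolate between city estimates and the pooled mean", {
  set.seed(37)
  inp <- rand_meta_input(8, 3, psi_scale = 0.5)
  fit <- mvmeta_fit(inp)
  b <- blup(inp, fit)
  mu <- drop(fit$mu[1, ])
  for (i in 1:8) {
    K <- fit$Psi %*% solve(fit$Psi + inp$vcovs[[i]])
    ev <- Re(eigen(K, only.values = TRUE)$values)
    expect_true(all(ev >= -1e-8 & ev <= 1 + 1e-8))
    expect_equal(unname(b[[i]]$eta),
                 unname(mu + drop(K %*% (inp$etas[[i]] - mu))),
                 tolerance = 1e-10)
  }
  # vanishing within-city variance: BLUP converges to the city's own estimate
  inp2 <- inp
  inp2$vcovs[[1]] <- diag(1e-10, 3)
  fit2 <- mvmeta_fit(inp2)
  b2 <- blup(inp2, fit2)
  expect_equal(unname(b2[[1]]$eta), unname(inp2$etas[[1]]), tolerance = 1e-3)
})

test_that("scalar BLUPs match the empirical-Bayes closed form", {
  set.seed(38)
  y <- rnorm(9, 1, 1)
  s2 <- runif(9, 0.1, 0.4)
  inp <- meta_input(as.list(y), lapply(s2, function(s) matrix(s, 1, 1)))
  fit <- mvmeta_fit(inp)
  b <- blup(inp, fit)
  mu <- fit$mu[1, 1]
  psi <- fit$Psi[1, 1]
  for (i in 1:9) {
    want <- oracle_scalar_blup(y[i], s2[i], mu, psi)
    expect_equal(unname(b[[i]]$eta), want, tolerance = 1e-8)
    # scalar BLUP lies between the estimate and the pooled mean
    expect_true(b[[i]]$eta >= min(y[i], mu) - 1e-12 &&
                  b[[i]]$eta <= max(y[i], mu) + 1e-12)
  }
  # univariate fallback agrees coefficient-wise in the scalar case
  bu <- blup(inp, fit, type = "univariate")
  for (i in 1:9) expect_equal(bu[[i]]$eta, unname(b[[i]]$eta), tolerance = 1e-6)
})

test_that("ML near-homogeneous data collapses to the fixed-effects solution", {
  set.seed(39)
  eta <- c(1, 2)
  inp <- meta_input(replicate(8, eta + rnorm(2, 0, 1e-4), simplify = FALSE),
                    replicate(8, diag(0.3, 2), simplify = FALSE))
  ml <- mvmeta_fit(inp)
  fe <- mvmeta_fit(inp, method = "fixed")
  expect_equal(unname(ml$mu), unname(fe$mu), tolerance = 1e-3)
  expect_lt(max(abs(ml$Psi)), 1e-3)
})

test_that("the heterogeneity table carries one row per tested predictor", {
  set.seed(40)
  preds <- data.frame(urbanization_rate = runif(10), longitude = runif(10, 97, 106))
  inp <- rand_meta_input(10, 2, psi_scale = 0.3, predictors = preds)
  tab <- heterogeneity_table(inp)
  expect_identical(tab$predictor,
                   c("(intercept)", "urbanization_rate", "longitude"))
  expect_true(is.na(tab$W[1]) && all(!is.na(tab$W[-1])))
  expect_identical(tab$Q_df, c(18L, 16L, 16L))
  expect_true(all(tab$I2 >= 0 & tab$I2 <= 100))
})

test_that("degenerate meta inputs are rejected with clear errors", {
  expect_error(meta_input(list(c(1, 2), c(1, 2, 3)),
                          list(diag(2), diag(3))), "same length")
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(meta_input(list(c(1, 2)), list(bad)), "semidefinite")
  inp <- meta_input(list(1, 2), list(matrix(0.1), matrix(0.1)),
                    predictors = data.frame(z = c(0, 1)))
  expect_error(mvmeta_fit(inp, predictor = "z"), "more cities")
})
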