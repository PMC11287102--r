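#' First-stage model configuration
#'
#' Settings of the city-level Gaussian time-series regression: daily YLL on
#' the temperature-lag cross-basis, a long-term/seasonality spline on the
#' date index with `time_df_per_year` degrees of freedom per year, natural
#' cubic splines with `covariate_df` df on relative humidity, wind speed,
#' sunshine duration and air pressure, day-of-week indicators and a holiday
#' indicator. Defaults mirror the usual choices for daily mortality series:
#' 7 df/year, 3 df per covariate, maximum lag 21 days, temperature knots at
#' the 27.5th/72.5th percentiles.
#'
#' @param time_df_per_year df per year of the time spline (>= 1).
#' @param covariate_df df of each meteorological covariate spline (>= 1).
#' @param max_lag maximum lag in days (>= 0).
#' @param var_percentiles percentiles of the temperature-basis internal knots.
#' @param lag_knots number of internal knots of the lag spline.
#' @return list of class `first_stage_config`.
#' @export
first_stage_config <- function(time_df_per_year = 7, covariate_df = 3,
                               max_lag = 21L, var_percentiles = c(27.5, 72.5),
                               lag_knots = 2L) {
  stopifnot(time_df_per_year >= 1, covariate_df >= 1, max_lag >= 0)
  structure(list(time_df_per_year = time_df_per_year,
                 covariate_df = covariate_df, max_lag = as.integer(max_lag),
                 var_percentiles = var_percentiles,
                 lag_knots = as.integer(lag_knots)),
            class = "first_stage_config")
}

#' Build the first-stage design matrix
#'
#' Assembles intercept, cross-basis block, time spline
#' (`round(time_df_per_year * n_years)` df over the date index, knots at
#' equally spaced quantiles of time), one natural cubic spline per
#' meteorological covariate, six day-of-week indicators (Monday reference)
#' and a holiday indicator. Rows with incomplete lag history or missing
#' values are excluded.
#'
#' @param series a [city_series()].
#' @param cb a [cross_basis()] built from `series$temp`.
#' @param config a [first_stage_config()].
#' @return list: `X` (design, complete rows only), `y` (response), `blocks`
#'   (block label per column), `rows` (row indices of `series` kept),
#'   `n_dropped_missing` (rows lost beyond the lag burn-in).
#' @export
build_design <- function(series, cb, config = first_stage_config()) {
  stopifnot(inherits(series, "city_series"), inherits(cb, "cross_basis"))
  n <- nrow(series)
  if (nrow(cb$values) != n) stop("series and cross-basis are not aligned")
  n_years <- n / 365.25
  if (n_years < 1) stop("series must cover at least one year")
  time_df <- max(2L, round(config$time_df_per_year * n_years))
  time_ns <- splines::ns(seq_len(n), df = time_df)
  cov_ns <- lapply(series[c("rh", "ws", "sunshine", "ap")], function(x)
    splines::ns(x, df = config$covariate_df))
  wd <- factor(format(series$date, "%u"), levels = as.character(1:7))  # 1 = Monday
  dow <- stats::model.matrix(~wd)[, -1L, drop = FALSE]

  X <- cbind(1, cb$values, time_ns, cov_ns$rh, cov_ns$ws, cov_ns$sunshine,
             cov_ns$ap, dow, as.numeric(series$holiday))
  blocks <- c("intercept", rep("crossbasis", ncol(cb$values)),
              rep("time", time_df),
              rep("rh", config$covariate_df), rep("ws", config$covariate_df),
              rep("sunshine", config$covariate_df), rep("ap", config$covariate_df),
              rep("dow", ncol(dow)), "holiday")
  colnames(X) <- c("(Intercept)", colnames(cb$values),
                   paste0("time", seq_len(time_df)),
                   paste0("rh", seq_len(config$covariate_df)),
                   paste0("ws", seq_len(config$covariate_df)),
                   paste0("sunshine", seq_len(config$covariate_df)),
                   paste0("ap", seq_len(config$covariate_df)),
                   paste0("dow", 2:7), "holiday")

  complete <- rowSums(is.na(X)) == 0 & is.finite(series$yll)
  lag_ok <- seq_len(n) >= cb$valid_from
  rows <- which(complete & lag_ok)
  n_dropped <- sum(lag_ok) - length(rows)
  X <- X[rows, , drop = FALSE]

  qq <- qr(X)
  if (qq$rank < ncol(X)) {
    bad <- unique(blocks[qq$pivot[(qq$rank + 1L):ncol(X)]])
    stop(sprintf("design matrix is rank deficient; collinear block(s): %s",
                 paste(bad, collapse = ", ")))
  }
  list(X = X, y = series$yll[rows], blocks = blocks, rows = rows,
       n_dropped_missing = n_dropped)
}

#' Gaussian-link general linear model (ordinary least squares)
#'
#' The identity-link Gaussian GLM coincides with ordinary least squares, so
#' the fit is a single QR solve: coefficients minimize the residual sum of
#' squares, and the coefficient covariance is
#' `sigma2 * (X'X)^-1` with `sigma2 = RSS / (n - p)`.
#'
#' @param y numeric response.
#' @param X full-column-rank design matrix with more rows than columns.
#' @param blocks optional block label per column, carried into the fit.
#' @return object of class `first_stage_fit`: `coefficients`, `vcov`,
#'   `sigma2`, `df_residual`, `n_used`, `blocks`, `fitted`, `residuals`.
#' @export
fit_gaussian_glm <- function(y, X, blocks = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop("y and X must be finite")
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  qq <- qr(X)
  if (qq$rank < p) stop("X is not of full column rank")
  coef <- qr.coef(qq, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(qq)
  piv <- qq$pivot
  Rinv <- backsolve(R, diag(p))
  xtx_inv <- tcrossprod(Rinv)
  xtx_inv[piv, piv] <- xtx_inv
  vc <- sigma2 * xtx_inv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = coef, vcov = vc, sigma2 = sigma2,
                 df_residual = n - p, n_used = n, blocks = blocks,
                 fitted = fitted, residuals = res),
            class = "first_stage_fit")
}

#' Fit the first stage for one city
#'
#' Convenience wrapper: builds the default temperature basis from the city's
#' observed temperatures, the cross-basis, the design matrix, and runs the
#' least-squares fit.
#'
#' @param series a [city_series()].
#' @param config a [first_stage_config()].
#' @return list: `fit` (a `first_stage_fit`), `cb` (the [cross_basis()]),
#'   `design` (the [build_design()] output).
#' @export
fit_city <- function(series, config = first_stage_config()) {
  var_spec <- default_var_spec(series$temp, config$var_percentiles)
  lag_spec <- default_lag_spec(config$max_lag, config$lag_knots)
  cb <- cross_basis(series$temp, var_spec, lag_spec, config$max_lag)
  d <- build_design(series, cb, config)
  fit <- fit_gaussian_glm(d$y, d$X, d$blocks)
  list(fit = fit, cb = cb, design = d)
}

#' Reduce a first-stage fit to the overall cumulative exposure-response
#'
#' Sums the lag dimension out of the cross-basis coefficient block: with
#' `S_k = sum_{l = 0..L} Blag_k(l)`, the overall curve's coefficients are
#' `eta_j = sum_k beta_(j,k) * S_k`, and the covariance is transported
#' through the same linear map. For any temperature `x`, `Bvar(x) . eta`
#' (relative to the reference) is the model's cumulative YLL change for
#' sustained exposure at `x` over the whole lag window.
#'
#' @param fit a `first_stage_fit` produced with `cb`'s columns.
#' @param cb the [cross_basis()] used in the fit.
#' @param temps the city's observed temperatures (for the reference
#'   percentile and the stored temperature distribution).
#' @param reference centering temperature; default the 50th percentile of
#'   `temps`. Must lie inside the basis boundary knots.
#' @return object of class `reduced_association`: `eta` (length v), `vcov`
#'   (v x v), `var_spec`, `reference`, `temp_quantiles` (percentiles
#'   0..100), `temp_range`.
#' @export
reduce_to_overall <- function(fit, cb, temps, reference = NULL) {
  stopifnot(inherits(fit, "first_stage_fit"), inherits(cb, "cross_basis"))
  idx <- which(fit$blocks == "crossbasis")
  v <- spline_ncol(cb$var_spec)
  m <- spline_ncol(cb$lag_spec)
  if (length(idx) != v * m) stop("fit does not carry this cross-basis block")
  S <- cb$lag_col_sums
  M <- matrix(0, v, v * m)
  for (j in seq_len(v)) M[j, (j - 1L) * m + seq_len(m)] <- S
  eta <- drop(M %*% fit$coefficients[idx])
  vc <- M %*% fit$vcov[idx, idx, drop = FALSE] %*% t(M)
  vc <- (vc + t(vc)) / 2
  qs <- stats::quantile(temps, probs = 0:100 / 100, type = 7, names = FALSE)
  bk <- cb$var_spec$boundary_knots
  if (is.null(reference)) reference <- qs[51]
  if (reference < bk[1] || reference > bk[2]) {
    stop("reference temperature lies outside the basis boundary knots")
  }
  structure(list(eta = eta, vcov = vc, var_spec = cb$var_spec,
                 reference = reference, temp_quantiles = qs,
                 temp_range = range(temps)),
            class = "reduced_association")
}

#' Predict the cumulative exposure-response curve
#'
#' Evaluates the reduced association at given temperatures, centered so the
#' effect at the reference temperature is exactly zero, with pointwise
#' normal 95% confidence bands.
#'
#' @param assoc a [reduce_to_overall()] result.
#' @param temps temperatures inside the basis boundary knots.
#' @return data frame: `temp`, `effect` (person-years of cumulative YLL
#'   change), `se`, `lo`, `hi`.
#' @export
predict_curve <- function(assoc, temps) {
  stopifnot(inherits(assoc, "reduced_association"))
  bk <- assoc$var_spec$boundary_knots
  if (any(temps < bk[1] | temps > bk[2])) {
    stop("temperatures outside the basis boundary knots")
  }
  B <- spline_basis(temps, assoc$var_spec)
  Bref <- spline_basis(assoc$reference, assoc$var_spec)
  D <- sweep(B, 2L, drop(Bref))
  effect <- drop(D %*% assoc$eta)
  se <- sqrt(pmax(0, rowSums((D %*% assoc$vcov) * D)))
  data.frame(temp = temps, effect = effect, se = se,
             lo = effect - 1.96 * se, hi = effect + 1.96 * se)
}
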