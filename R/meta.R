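#' Meta-analysis input
#'
#' City-level estimates for pooling: one coefficient vector (the reduced
#' cumulative exposure-response curve) and its covariance per city, with an
#' optional table of city-level meta-predictors.
#'
#' @param etas list of length-v numeric vectors, one per city.
#' @param vcovs list of v x v positive semidefinite matrices.
#' @param predictors optional data frame of city-level covariates (one row
#'   per city).
#' @param city_ids optional character labels.
#' @return object of class `meta_input`.
#' @export
meta_input <- function(etas, vcovs, predictors = NULL, city_ids = NULL) {
  k <- length(etas)
  if (length(vcovs) != k) stop("etas and vcovs must have the same length")
  v <- length(etas[[1]])
  for (i in seq_len(k)) {
    if (length(etas[[i]]) != v) stop("all etas must have the same length")
    S <- vcovs[[i]]
    if (!is.matrix(S) || any(dim(S) != v)) stop("vcov dimension mismatch")
    if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S)))) {
      stop(sprintf("vcov of city %d is not symmetric", i))
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(sprintf("vcov of city %d is not positive semidefinite", i))
    }
  }
  if (!is.null(predictors) && nrow(predictors) != k) {
    stop("predictors must have one row per city")
  }
  if (is.null(city_ids)) city_ids <- sprintf("city%02d", seq_len(k))
  structure(list(etas = etas, vcovs = vcovs, predictors = predictors,
                 city_ids = city_ids, k = k, v = v),
            class = "meta_input")
}

# design row per city: intercept plus optionally one z-standardized predictor
meta_design <- function(input, predictor = NULL) {
  k <- input$k
  if (is.null(predictor)) return(matrix(1, k, 1, dimnames = list(NULL, "(Intercept)")))
  if (!predictor %in% names(input$predictors)) {
    stop(sprintf("no meta-predictor '%s'", predictor))
  }
  z <- input$predictors[[predictor]]
  if (any(!is.finite(z))) stop("meta-predictor values must be finite")
  z <- as.numeric(scale(z))
  cbind("(Intercept)" = rep(1, k), z = z)
}

# profile GLS for the mean given Psi: returns mu (p*v), its vcov, residuals,
# and the log-likelihood. Ulist (per-city v x p*v designs, kronecker of the
# predictor row with I_v) can be precomputed by the caller and reused across
# likelihood evaluations.
meta_gls <- function(input, X, Psi, Ulist = NULL) {
  k <- input$k; v <- input$v; p <- ncol(X)
  if (is.null(Ulist)) Ulist <- meta_ulist(input, X)
  UtWU <- matrix(0, p * v, p * v)
  UtWy <- numeric(p * v)
  Wi <- vector("list", k)
  ldet <- 0
  for (i in seq_len(k)) {
    Sig <- input$vcovs[[i]] + Psi
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- chol(Sig + diag(1e-10 * (1 + max(abs(diag(Sig)))), v))
    }
    W <- chol2inv(ch)
    Wi[[i]] <- W
    ldet <- ldet + 2 * sum(log(diag(ch)))
    U <- Ulist[[i]]
    WU <- W %*% U
    UtWU <- UtWU + crossprod(U, WU)
    UtWy <- UtWy + drop(crossprod(WU, input$etas[[i]]))
  }
  mu_vcov <- unname(solve(UtWU))
  mu <- unname(drop(mu_vcov %*% UtWy))
  quad <- 0
  resid <- vector("list", k)
  for (i in seq_len(k)) {
    r <- input$etas[[i]] - drop(Ulist[[i]] %*% mu)
    resid[[i]] <- r
    quad <- quad + drop(t(r) %*% Wi[[i]] %*% r)
  }
  loglik <- -0.5 * (k * v * log(2 * pi) + ldet + quad)
  list(mu = mu, mu_vcov = mu_vcov, resid = resid, W = Wi,
       loglik = loglik, quad = quad)
}

meta_ulist <- function(input, X) {
  lapply(seq_len(input$k), function(i)
    kronecker(X[i, , drop = FALSE], diag(input$v)))
}

chol_to_psi <- function(theta, v) {
  L <- matrix(0, v, v)
  L[lower.tri(L, diag = TRUE)] <- theta
  tcrossprod(L)
}

#' Multivariate random-effects meta-regression (maximum likelihood)
#'
#' Pools the city-specific coefficient vectors under the marginal model
#' `eta_i ~ N(X_i %*% mu, S_i + Psi)`, maximizing the joint normal
#' likelihood over the mean coefficients and the between-city covariance
#' `Psi` (Cholesky-parameterized, so it stays positive semidefinite; the
#' mean is profiled out by generalized least squares at each `Psi`).
#' Meta-predictors are z-standardized internally; the reported Wald
#' statistic is invariant to this. Heterogeneity statistics (Cochran Q from
#' the fixed-effects residuals, I2), AIC and the predictor Wald test are
#' attached.
#'
#' @param input a [meta_input()].
#' @param predictor optional name of one meta-predictor column; `NULL` fits
#'   the intercept-only model.
#' @param method `"ml"` (random effects, default) or `"fixed"`
#'   (`Psi` fixed at zero, i.e. the fixed-effects GLS fit).
#' @param control list: `maxit` (default 500), `reltol` (1e-12),
#'   `grad_tol` (1e-6, gradient-norm warning threshold).
#' @return object of class `meta_fit`: `mu` (p x v matrix), `mu_vcov`,
#'   `Psi`, `Q`, `Q_df`, `Q_p`, `I2` (percent), `loglik`, `AIC`,
#'   `wald` (`W`, `df`, `p`; `NULL` without predictor), `converged`,
#'   `grad_norm`, plus the design and input dimensions.
#' @export
mvmeta_fit <- function(input, predictor = NULL, method = c("ml", "fixed"),
                       control = list()) {
  stopifnot(inherits(input, "meta_input"))
  method <- match.arg(method)
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-6),
                           control)
  X <- meta_design(input, predictor)
  k <- input$k; v <- input$v; p <- ncol(X)
  if (method == "ml" && k <= p) stop("need more cities than predictor terms")
  if (method == "fixed" && k < p) stop("need at least as many cities as predictor terms")

  Ulist <- meta_ulist(input, X)
  converged <- TRUE; grad_norm <- 0
  if (method == "fixed" || k == 1L) {
    Psi <- matrix(0, v, v)
    gls <- meta_gls(input, X, Psi, Ulist)
  } else {
    # moment start: covariance of etas in excess of the mean within-city vcov
    E <- do.call(rbind, input$etas)
    Sbar <- Reduce(`+`, input$vcovs) / k
    Psi0 <- stats::cov(E) - Sbar
    ev <- eigen((Psi0 + t(Psi0)) / 2, symmetric = TRUE)
    Psi0 <- ev$vectors %*% diag(pmax(ev$values, 1e-4), v) %*% t(ev$vectors)
    L0 <- t(chol(Psi0))
    theta0 <- L0[lower.tri(L0, diag = TRUE)]
    nll <- function(theta) {
      -meta_gls(input, X, chol_to_psi(theta, v), Ulist)$loglik
    }
    # BFGS with restarts: near the Psi = 0 boundary the Cholesky
    # parameterization has flat directions and a single pass can exhaust
    # maxit; restarting from the incumbent resets the Hessian approximation
    opt <- NULL
    theta <- theta0
    for (round in 1:4) {
      opt <- stats::optim(theta, nll, method = "BFGS",
                          control = list(maxit = ctl$maxit, reltol = ctl$reltol))
      theta <- opt$par
      if (opt$convergence == 0L) break
    }
    # numerical gradient at the optimum as a convergence diagnostic
    g <- vapply(seq_along(opt$par), function(j) {
      h <- 1e-5 * (1 + abs(opt$par[j]))
      e <- numeric(length(opt$par)); e[j] <- h
      (nll(opt$par + e) - nll(opt$par - e)) / (2 * h)
    }, numeric(1))
    grad_norm <- sqrt(sum(g^2))
    # gradient tolerance is relative to the likelihood's scale
    converged <- opt$convergence == 0L ||
      grad_norm < ctl$grad_tol * max(1, abs(opt$value))
    if (!converged) {
      stop(sprintf(
        "ML optimizer did not converge (code %d, nll %.4f, |grad| %.2e)",
        opt$convergence, opt$value, grad_norm))
    }
    Psi <- chol_to_psi(opt$par, v)
    gls <- meta_gls(input, X, Psi, Ulist)
  }

  # Cochran Q always from the fixed-effects (Psi = 0) fit of the same design
  fe <- if (method == "fixed") gls else meta_gls(input, X, matrix(0, v, v), Ulist)
  Q <- fe$quad
  Q_df <- k * v - p * v
  Q_p <- if (Q_df >= 1) stats::pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_
  n_par <- p * v + if (method == "ml") v * (v + 1) / 2 else 0
  fit <- structure(
    list(mu = matrix(gls$mu, p, v, byrow = TRUE),
         mu_vec = gls$mu, mu_vcov = gls$mu_vcov, Psi = Psi,
         Q = Q, Q_df = Q_df, Q_p = Q_p,
         I2 = if (Q_df >= 1) i_squared(Q, Q_df) else NA_real_,
         loglik = gls$loglik, AIC = -2 * gls$loglik + 2 * n_par,
         n_par = n_par, method = method, predictor = predictor, X = X,
         k = k, v = v, p = p, converged = converged, grad_norm = grad_norm),
    class = "meta_fit")
  if (!is.null(predictor)) fit$wald <- wald_test(fit)
  fit
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf(
    "multivariate meta-%s (%s): k=%d cities, v=%d outcomes\nQ=%.2f (df=%d, p=%.3g), I2=%.1f%%, AIC=%.1f\n",
    if (x$p > 1) "regression" else "analysis", x$method, x$k, x$v,
    x$Q, x$Q_df, x$Q_p, x$I2, x$AIC))
  invisible(x)
}

#' Cochran Q heterogeneity test
#'
#' Residual heterogeneity against the fixed-effects fit of the same design:
#' `Q = sum_i r_i' S_i^-1 r_i`, with `r_i` the residual from the
#' `Psi = 0` generalized least-squares fit; `df = k*v - p*v`, p-value from
#' the upper chi-square tail.
#'
#' @param input a [meta_input()].
#' @param predictor optional meta-predictor name (matching the design the
#'   heterogeneity is residual to).
#' @return named numeric: `Q`, `df`, `p`.
#' @export
cochran_q <- function(input, predictor = NULL) {
  X <- meta_design(input, predictor)
  for (i in seq_len(input$k)) {
    if (rcond(input$vcovs[[i]]) < 1e-14) {
      stop(sprintf("within-city covariance of %s is singular", input$city_ids[i]))
    }
  }
  fe <- meta_gls(input, X, matrix(0, input$v, input$v))
  df <- input$k * input$v - ncol(X) * input$v
  c(Q = fe$quad, df = df,
    p = stats::pchisq(fe$quad, df, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - df) / Q) * 100`: the share of total variation in the
#' city estimates attributed to true between-city differences.
#'
#' @param Q Cochran Q statistic (>= 0).
#' @param df its degrees of freedom (>= 1).
#' @return percentage in `[0, 100]`.
#' @export
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  max(0, (Q - df) / Q) * 100
}

#' Wald test of a meta-predictor
#'
#' Joint chi-square test of the v coefficients of the (single) non-intercept
#' meta-predictor: `W = b' V_b^-1 b`, `df = v`.
#'
#' @param fit a [mvmeta_fit()] with exactly one non-intercept predictor.
#' @return named numeric: `W`, `df`, `p`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  if (fit$p != 2L) stop("fit must contain exactly one non-intercept predictor")
  v <- fit$v
  idx <- v + seq_len(v)  # second row of mu in the vectorized (row-major) layout
  b <- fit$mu_vec[idx]
  Vb <- fit$mu_vcov[idx, idx, drop = FALSE]
  if (rcond(Vb) < 1e-14) stop("predictor coefficient covariance is singular")
  W <- drop(t(b) %*% solve(Vb, b))
  c(W = W, df = v, p = stats::pchisq(W, v, lower.tail = FALSE))
}

#' Best linear unbiased predictions per city
#'
#' Shrinks each city's estimate toward its fitted meta-regression mean in
#' proportion to the relative sizes of between- and within-city variability:
#' `blup_i = mean_i + Psi (Psi + S_i)^-1 (eta_i - mean_i)`, with covariance
#' `Psi - Psi (Psi + S_i)^-1 Psi`. With `Psi = 0` every BLUP equals the
#' pooled mean; as `S_i -> 0` a city's BLUP tends to its own estimate.
#'
#' A univariate fallback (`type = "univariate"`) applies the scalar
#' empirical-Bayes formula coefficient by coefficient, each from its own
#' scalar ML random-effects fit.
#'
#' @param input the [meta_input()] the fit was computed from.
#' @param fit the corresponding [mvmeta_fit()] (ML).
#' @param type `"multivariate"` (default) or `"univariate"`.
#' @return list per city: `eta` (BLUP coefficients), `vcov`.
#' @export
blup <- function(input, fit, type = c("multivariate", "univariate")) {
  stopifnot(inherits(input, "meta_input"), inherits(fit, "meta_fit"))
  type <- match.arg(type)
  k <- input$k; v <- input$v
  if (type == "univariate") {
    out <- replicate(k, list(eta = numeric(v), vcov = matrix(0, v, v)),
                     simplify = FALSE)
    for (j in seq_len(v)) {
      uni <- meta_input(lapply(input$etas, function(e) e[j]),
                        lapply(input$vcovs, function(S) S[j, j, drop = FALSE]),
                        predictors = input$predictors,
                        city_ids = input$city_ids)
      ufit <- mvmeta_fit(uni, predictor = fit$predictor, method = fit$method)
      ub <- blup(uni, ufit, type = "multivariate")
      for (i in seq_len(k)) {
        out[[i]]$eta[j] <- ub[[i]]$eta
        out[[i]]$vcov[j, j] <- ub[[i]]$vcov
      }
    }
    names(out) <- input$city_ids
    return(out)
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    U <- kronecker(fit$X[i, , drop = FALSE], diag(v))
    mean_i <- drop(U %*% fit$mu_vec)
    K <- fit$Psi %*% solve(fit$Psi + input$vcovs[[i]])
    e <- unname(mean_i + drop(K %*% (input$etas[[i]] - mean_i)))
    Vc <- fit$Psi - K %*% fit$Psi
    out[[i]] <- list(eta = e, vcov = (Vc + t(Vc)) / 2)
  }
  names(out) <- input$city_ids
  out
}

#' Meta-regression heterogeneity table
#'
#' Fits the intercept-only model and then each named meta-predictor singly,
#' collecting Wald test, AIC, Cochran Q and I2 per model — the standard
#' spatial-heterogeneity summary of a two-stage analysis.
#'
#' @param input a [meta_input()] carrying a predictor table.
#' @param predictors character vector of predictor column names; default all.
#' @return data frame: `predictor, W, W_df, W_p, AIC, Q, Q_df, Q_p, I2`.
#' @export
heterogeneity_table <- function(input, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(input$predictors), "city")
  }
  base <- mvmeta_fit(input)
  rows <- list(data.frame(predictor = "(intercept)", W = NA_real_,
                          W_df = NA_real_, W_p = NA_real_, AIC = base$AIC,
                          Q = base$Q, Q_df = base$Q_df, Q_p = base$Q_p,
                          I2 = base$I2))
  for (pr in predictors) {
    f <- mvmeta_fit(input, predictor = pr)
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = pr, W = f$wald[["W"]], W_df = f$wald[["df"]],
      W_p = f$wald[["p"]], AIC = f$AIC, Q = f$Q, Q_df = f$Q_df,
      Q_p = f$Q_p, I2 = f$I2)
  }
  do.call(rbind, rows)
}
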