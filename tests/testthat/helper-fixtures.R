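# Shared fixture builders. Everything is generated in code at test time.

# short simulation window for fast tests (n_days from 2014-01-01)
tiny_cfg <- function(n_days = 400, ...) {
  sim_config(window = c("2014-01-01",
                        as.character(as.Date("2014-01-01") + n_days - 1L)),
             ...)
}

# a small strictly-decreasing life table over ages 0..top
toy_life_table <- function(top = 10L, e0_male = 50, e0_female = 55) {
  ages <- 0:top
  life_table(age = rep(ages, 2L),
             sex = rep(c("male", "female"), each = top + 1L),
             e = c(e0_male - 4 * ages, e0_female - 4 * ages))
}

# a hand-built reduced_association with arbitrary coefficients, for
# attribution tests that do not need a regression behind them
toy_assoc <- function(eta, vcov = NULL, lo = 0, hi = 30,
                      knots = c(10, 20), degree = 2L, intercept = FALSE,
                      temps = NULL) {
  spec <- spline_spec("bspline", degree = degree, internal_knots = knots,
                      boundary_knots = c(lo, hi), intercept = intercept)
  v <- spline_ncol(spec)
  stopifnot(length(eta) == v)
  if (is.null(vcov)) vcov <- matrix(0, v, v)
  if (is.null(temps)) temps <- seq(lo, hi, length.out = 200)
  structure(list(eta = eta, vcov = vcov, var_spec = spec,
                 reference = (lo + hi) / 2,
                 temp_quantiles = stats::quantile(temps, 0:100 / 100,
                                                  type = 7, names = FALSE),
                 temp_range = range(temps)),
            class = "reduced_association")
}

# random PSD matrix
rand_psd <- function(v, scale = 1) {
  A <- matrix(stats::rnorm(v * v), v)
  scale * (crossprod(A) + diag(0.1, v))
}

# quick meta input: k cities around a common mean with optional Psi
rand_meta_input <- function(k, v, psi_scale = 0, s_scale = 0.05,
                            predictors = NULL) {
  mu <- stats::rnorm(v)
  etas <- vector("list", k)
  vcovs <- vector("list", k)
  for (i in seq_len(k)) {
    S <- rand_psd(v, s_scale)
    dev <- if (psi_scale > 0) stats::rnorm(v, 0, sqrt(psi_scale)) else 0
    ch <- chol(S)
    etas[[i]] <- mu + dev + drop(t(ch) %*% stats::rnorm(v))
    vcovs[[i]] <- S
  }
  meta_input(etas, vcovs, predictors = predictors)
}
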