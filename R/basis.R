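#' Spline basis specification
#'
#' Describes a one-dimensional spline basis on a variable's own scale, either
#' a natural cubic spline (C2 inside the boundary knots, linear outside) or a
#' B-spline of given degree (non-negative columns with local support).
#'
#' The number of basis columns is fully determined by the specification:
#' `length(internal_knots) + degree + intercept` for a B-spline and
#' `length(internal_knots) + 1 + intercept` for a natural cubic spline.
#'
#' @param family `"natural_cubic"` or `"bspline"`.
#' @param degree polynomial degree, B-splines only (default 2, i.e. quadratic).
#' @param internal_knots knot values strictly inside the boundary knots,
#'   strictly increasing. May be empty.
#' @param boundary_knots length-2 numeric, the boundary of the spline domain.
#' @param intercept logical; keep the full-rank basis including the constant
#'   direction (`TRUE`) or drop it (`FALSE`).
#' @return An object of class `spline_spec`.
#' @seealso [spline_basis()], [cross_basis()], [quantile_knots()]
#' @export
spline_spec <- function(family = c("natural_cubic", "bspline"), degree = 2L,
                        internal_knots = numeric(0), boundary_knots,
                        intercept = FALSE) {
  family <- match.arg(family)
  degree <- as.integer(degree)
  if (family == "bspline" && degree < 1L) {
    stop("B-spline degree must be >= 1")
  }
  if (length(boundary_knots) != 2L || !is.numeric(boundary_knots) ||
      any(!is.finite(boundary_knots)) || boundary_knots[1] >= boundary_knots[2]) {
    stop("boundary_knots must be two finite, strictly increasing values")
  }
  internal_knots <- as.numeric(internal_knots)
  if (length(internal_knots)) {
    if (any(diff(internal_knots) <= 0)) {
      stop("internal knots must be strictly increasing")
    }
    if (min(internal_knots) <= boundary_knots[1] ||
        max(internal_knots) >= boundary_knots[2]) {
      stop("internal knots must lie strictly inside the boundary knots")
    }
  }
  structure(
    list(family = family, degree = degree, internal_knots = internal_knots,
         boundary_knots = as.numeric(boundary_knots),
         intercept = isTRUE(intercept)),
    class = "spline_spec"
  )
}

#' Number of columns a spline specification generates
#'
#' @param spec a [spline_spec()].
#' @return integer column count.
#' @export
spline_ncol <- function(spec) {
  stopifnot(inherits(spec, "spline_spec"))
  k <- length(spec$internal_knots)
  n <- if (spec$family == "bspline") k + spec$degree else k + 1L
  n + as.integer(spec$intercept)
}

#' Empirical quantile knots
#'
#' Places knots at empirical percentiles of a variable using linear
#' interpolation between order statistics (type-7 quantiles, the common
#' statistical default). Used to put the temperature-basis knots at the
#' 27.5th and 72.5th percentiles of the observed daily mean temperature.
#'
#' @param x numeric vector, non-empty, finite values.
#' @param percentiles percentages in (0, 100), strictly increasing.
#'   Default `c(27.5, 72.5)`.
#' @return numeric vector of knot values, strictly increasing.
#' @export
quantile_knots <- function(x, percentiles = c(27.5, 72.5)) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("x has no finite values")
  if (!length(percentiles) || any(percentiles <= 0) || any(percentiles >= 100)) {
    stop("percentiles must lie strictly inside (0, 100)")
  }
  if (any(diff(percentiles) <= 0)) {
    stop("percentiles must be strictly increasing")
  }
  k <- unname(stats::quantile(x, probs = percentiles / 100, type = 7))
  if (length(k) > 1L && any(diff(k) <= 0)) {
    stop("quantile knots are not strictly increasing (near-constant x?)")
  }
  k
}

#' Evaluate a spline basis
#'
#' Returns the basis matrix of `spec` evaluated at `x`. Natural cubic splines
#' extrapolate linearly beyond the boundary knots; B-splines are only defined
#' on the closed boundary interval and evaluating outside it is an error
#' (callers clamp where the science calls for it).
#'
#' @param x numeric vector of evaluation points.
#' @param spec a [spline_spec()].
#' @return numeric matrix, `length(x)` rows and [spline_ncol()] columns.
#' @export
spline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (any(!is.finite(x))) stop("x must be finite")
  bk <- spec$boundary_knots
  if (spec$family == "natural_cubic") {
    b <- splines::ns(x, knots = spec$internal_knots, Boundary.knots = bk,
                     intercept = spec$intercept)
    b <- unclass(b)
    attributes(b)[setdiff(names(attributes(b)), "dim")] <- NULL
  } else {
    if (any(x < bk[1] | x > bk[2])) {
      stop("B-spline basis evaluated outside its boundary knots")
    }
    ord <- spec$degree + 1L
    knots <- c(rep(bk[1], ord), spec$internal_knots, rep(bk[2], ord))
    b <- splines::splineDesign(knots, x, ord = ord)
    if (!spec$intercept) b <- b[, -1L, drop = FALSE]
  }
  stopifnot(ncol(b) == spline_ncol(spec))
  dimnames(b) <- NULL
  b
}

#' Default lag-dimension spline specification
#'
#' Natural cubic spline over lags `0..L` with an intercept and internal knots
#' equally spaced on the `log(lag + 1)` scale, the established default for
#' the lag-response dimension of a distributed lag nonlinear model. With the
#' default 2 internal knots this yields 4 columns.
#'
#' @param max_lag maximum lag in days (default 21).
#' @param n_knots number of internal knots (default 2).
#' @return a [spline_spec()].
#' @export
default_lag_spec <- function(max_lag = 21L, n_knots = 2L) {
  stopifnot(max_lag >= 1L, n_knots >= 0L)
  lg <- seq(0, log(max_lag + 1), length.out = n_knots + 2L)
  internal <- exp(lg[-c(1L, n_knots + 2L)]) - 1
  spline_spec("natural_cubic", internal_knots = internal,
              boundary_knots = c(0, max_lag), intercept = TRUE)
}

#' Default temperature-dimension spline specification
#'
#' Quadratic B-spline with internal knots at the 27.5th and 72.5th
#' percentiles of the observed temperatures, boundary knots at the observed
#' minimum and maximum, no intercept: a 4-column basis for the
#' exposure-response dimension.
#'
#' @param temp observed daily mean temperatures.
#' @param percentiles knot percentiles (default `c(27.5, 72.5)`).
#' @return a [spline_spec()].
#' @export
default_var_spec <- function(temp, percentiles = c(27.5, 72.5)) {
  temp <- temp[is.finite(temp)]
  spline_spec("bspline", degree = 2L,
              internal_knots = quantile_knots(temp, percentiles),
              boundary_knots = range(temp), intercept = FALSE)
}

#' Temperature-lag cross-basis
#'
#' Builds the bi-dimensional design block of a distributed lag nonlinear
#' model: row `t`, column `(j, k)` holds
#' `sum_{l = 0..L} Bvar_j(temp[t - l]) * Blag_k(l)`,
#' the tensor product of the exposure-response basis evaluated at the lagged
#' temperatures with the lag-response basis evaluated at the lag indices.
#' The first `L` rows have incomplete lag history and are returned as `NA`;
#' model fitting drops them rather than fabricating pre-study exposure.
#'
#' Columns are ordered with the temperature-basis index varying slowest:
#' column `(j - 1) * m + k` pairs temperature column `j` with lag column `k`.
#'
#' @param temp numeric vector of daily mean temperatures, length `> max_lag`.
#' @param var_spec [spline_spec()] for the temperature dimension.
#' @param lag_spec [spline_spec()] for the lag dimension.
#' @param max_lag maximum lag L in days (`>= 0`).
#' @return An object of class `cross_basis` with elements `values`
#'   (the n x (v*m) matrix), `var_spec`, `lag_spec`, `max_lag`, `valid_from`
#'   (first row with complete lag history), `basis_lag` (the (L+1) x m lag
#'   basis) and `lag_col_sums` (its column sums, used by the reduction).
#' @export
cross_basis <- function(temp,
                        var_spec = default_var_spec(temp),
                        lag_spec = default_lag_spec(max_lag),
                        max_lag = 21L) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0")
  n <- length(temp)
  if (n <= max_lag) stop("series length must exceed max_lag")
  b_var <- spline_basis(temp, var_spec)
  b_lag <- spline_basis(0:max_lag, lag_spec)
  v <- ncol(b_var)
  m <- ncol(b_lag)
  cb <- matrix(0, n, v * m)
  for (l in 0:max_lag) {
    idx <- seq_len(n) - l
    shifted <- matrix(NA_real_, n, v)
    ok <- idx >= 1L
    shifted[ok, ] <- b_var[idx[ok], , drop = FALSE]
    cb <- cb + shifted[, rep(seq_len(v), each = m), drop = FALSE] *
      rep(b_lag[l + 1L, ], v)[col(cb)]
  }
  colnames(cb) <- paste0("v", rep(seq_len(v), each = m),
                         ".l", rep(seq_len(m), v))
  structure(
    list(values = cb, var_spec = var_spec, lag_spec = lag_spec,
         max_lag = max_lag, valid_from = max_lag + 1L,
         basis_lag = b_lag, lag_col_sums = colSums(b_lag)),
    class = "cross_basis"
  )
}

#' @export
print.cross_basis <- function(x, ...) {
  v <- spline_ncol(x$var_spec)
  m <- spline_ncol(x$lag_spec)
  cat(sprintf(
    "cross_basis: %d days x (%d temperature x %d lag) = %d columns, max lag %d\n",
    nrow(x$values), v, m, v * m, x$max_lag))
  invisible(x)
}
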