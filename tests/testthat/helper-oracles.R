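# Independent textbook implementations used as oracles. These deliberately
# share no code with the package: B-splines by the Cox-de Boor recursion,
# natural cubic splines by the truncated-power construction, least squares
# by the normal equations, scalar meta-analysis by its closed forms.

# Cox-de Boor recursion over a full (padded) knot vector; valid for x
# strictly inside the boundary (half-open interval convention).
oracle_bspline <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  rec <- function(i, d, x) {
    if (d == 0L) return(as.numeric(knots[i] <= x & x < knots[i + 1L]))
    t1 <- 0
    den1 <- knots[i + d] - knots[i]
    if (den1 > 0) t1 <- (x - knots[i]) / den1 * rec(i, d - 1L, x)
    t2 <- 0
    den2 <- knots[i + d + 1L] - knots[i + 1L]
    if (den2 > 0) t2 <- (knots[i + d + 1L] - x) / den2 * rec(i + 1L, d - 1L, x)
    t1 + t2
  }
  vapply(seq_len(nb), function(i) rec(i, degree, x), numeric(length(x)))
}

# Truncated-power natural cubic spline basis (all knots incl. boundary);
# spans the same function space as any natural cubic basis on those knots.
oracle_natural_basis <- function(x, all_knots) {
  K <- length(all_knots)
  d <- function(k) {
    (pmax(x - all_knots[k], 0)^3 - pmax(x - all_knots[K], 0)^3) /
      (all_knots[K] - all_knots[k])
  }
  cbind(1, x, vapply(seq_len(K - 2L), function(k) d(k) - d(K - 1L),
                     numeric(length(x))))
}

# direct double-loop cross-basis summation
oracle_cross_basis <- function(bvar, blag, L) {
  n <- nrow(bvar); v <- ncol(bvar); m <- ncol(blag)
  out <- matrix(NA_real_, n, v * m)
  for (t in (L + 1L):n) {
    for (j in seq_len(v)) {
      for (k in seq_len(m)) {
        s <- 0
        for (l in 0:L) s <- s + bvar[t - l, j] * blag[l + 1L, k]
        out[t, (j - 1L) * m + k] <- s
      }
    }
  }
  out
}

oracle_ols <- function(y, X) solve(t(X) %*% X, t(X) %*% y)

# inverse-variance-weighted common-effect mean (scalar fixed-effects meta)
oracle_ivw <- function(y, s2) {
  w <- 1 / s2
  c(mu = sum(w * y) / sum(w), var = 1 / sum(w))
}

# scalar empirical-Bayes shrinkage
oracle_scalar_blup <- function(y, s2, mu, psi) {
  mu + psi / (psi + s2) * (y - mu)
}

# type-7 quantile by explicit order-statistic interpolation
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# exhaustive fine-grid curve minimum
oracle_fine_mmt <- function(assoc, lo, hi) {
  grid <- seq(lo, hi, by = 0.001)
  vals <- drop(tempburden::spline_basis(grid, assoc$var_spec) %*% assoc$eta)
  grid[which.min(vals)]
}
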