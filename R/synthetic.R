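# Evaluate code with a temporary RNG state so generators are deterministic
# under their own seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smoothed hinge: 0 for u <= 0, quadratic on (0, delta), linear (slope 1) beyond;
# C1 everywhere so the true curve is a smooth V, as pooled curves are in practice
smooth_hinge <- function(u, delta) {
  ifelse(u <= 0, 0, ifelse(u < delta, u^2 / (2 * delta), u - delta / 2))
}

#' One city's aligned daily series
#'
#' Bundles a city's daily outcome, exposure and covariate vectors with
#' calendar metadata and validates the basic physical constraints.
#'
#' @param df data frame with columns `date`, `yll` (person-years/day),
#'   `temp` (deg C), `rh` (%), `ws` (m/s), `sunshine` (h), `ap` (hPa),
#'   `holiday` (logical).
#' @param city_id character label.
#' @param temp_burnin optional numeric vector of pre-window temperatures
#'   (most recent last), carried for oracle computations.
#' @return object of class `city_series` (a data frame).
#' @export
city_series <- function(df, city_id = "city01", temp_burnin = NULL) {
  need <- c("date", "yll", "temp", "rh", "ws", "sunshine", "ap", "holiday")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  df$date <- as.Date(df$date)
  if (nrow(df) > 1L && any(diff(as.integer(df$date)) != 1L)) {
    gaps <- df$date[which(diff(as.integer(df$date)) != 1L)]
    stop(sprintf("dates must be strictly consecutive; gap after %s",
                 paste(utils::head(gaps, 3L), collapse = ", ")))
  }
  ok_rh <- all(df$rh >= 0 & df$rh <= 100, na.rm = TRUE)
  ok_sun <- all(df$sunshine >= 0 & df$sunshine <= 24, na.rm = TRUE)
  ok_ws <- all(df$ws >= 0, na.rm = TRUE)
  if (!ok_rh || !ok_sun || !ok_ws) {
    stop("covariates out of physical range (rh in [0,100], sunshine in [0,24], ws >= 0)")
  }
  structure(df[need], class = c("city_series", "data.frame"),
            city_id = city_id, temp_burnin = temp_burnin)
}

#' Simulation configuration
#'
#' Defaults emulate a 7-year (2014-01-01 to 2020-12-31, 2557 days) daily
#' series from a subtropical-plateau climate: mean temperature 17.4 deg C
#' with SD about 5.6, annual sinusoid plus AR(1) noise; correlated
#' meteorological covariates; daily YLL averaging about 546 person-years
#' composed of a smooth seasonal baseline, weekday and holiday structure, a
#' lagged temperature contribution from a smooth V-shaped cumulative curve
#' (distinct cold and heat slopes around a 19 deg C minimum, lag weights
#' decaying geometrically over 0..21 days) and Gaussian noise.
#'
#' @param window first and last day of the study period.
#' @param temp_mean,temp_amp annual mean and sinusoidal amplitude (deg C).
#' @param temp_ar,temp_noise_sd AR(1) coefficient and innovation SD of the
#'   temperature noise.
#' @param mmt_true temperature of minimum YLL of the true curve (deg C).
#' @param slope_cold,slope_heat person-years of excess daily YLL per deg C
#'   below/above `mmt_true` (asymptotic slopes of the smooth V).
#' @param smooth hinge-smoothing radius in deg C (C1 rounding of the V's kink).
#' @param effect_scale global multiplier on the true curve; 0 gives a null
#'   (no temperature effect) simulation.
#' @param max_lag maximum lag L in days; `lag_decay` the geometric decay
#'   scale of the (normalized) lag weights.
#' @param baseline_mean mean of the non-temperature YLL baseline
#'   (person-years/day); `seasonal_amp` its winter-peaking annual amplitude;
#'   `weekend_effect`, `holiday_effect` additive bumps.
#' @param noise_sd SD of the additive Gaussian YLL noise (person-years).
#' @param holidays month-day strings marked as public holidays every year,
#'   in addition to Jan 1-3.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(window = c("2014-01-01", "2020-12-31"),
                       temp_mean = 17.4, temp_amp = 7.0,
                       temp_ar = 0.7, temp_noise_sd = 1.87,
                       mmt_true = 19, slope_cold = 8, slope_heat = 12,
                       smooth = 2, effect_scale = 1,
                       max_lag = 21L, lag_decay = 5,
                       baseline_mean = 505, seasonal_amp = 30,
                       weekend_effect = 12, holiday_effect = 18,
                       noise_sd = 60,
                       holidays = c("02-15", "02-16", "02-17", "04-05",
                                    "05-01", "05-02", "06-20", "10-01",
                                    "10-02", "10-03")) {
  cfg <- as.list(environment())
  cfg$max_lag <- as.integer(max_lag)
  stopifnot(cfg$max_lag >= 0L, noise_sd >= 0, smooth > 0,
            slope_cold >= 0, slope_heat >= 0)
  structure(cfg, class = "sim_config")
}

# cold/heat halves of the true cumulative curve (each vanishes at mmt_true
# and on the other side of it); their sum is the full curve
truth_curves <- function(config) {
  sc <- config$effect_scale
  list(
    cold = function(x) sc * config$slope_cold *
      smooth_hinge(config$mmt_true - x, config$smooth),
    heat = function(x) sc * config$slope_heat *
      smooth_hinge(x - config$mmt_true, config$smooth)
  )
}

seasonal <- function(dates, amp, peak_doy) {
  doy <- as.integer(format(dates, "%j"))
  amp * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Simulate one city's daily series with known truth
#'
#' Generates temperature as an annual sinusoid plus AR(1) noise (including a
#' pre-window burn-in of `max_lag` days so every study day has full lag
#' history), correlated meteorological covariates, and daily YLL as a smooth
#' seasonal/weekly/holiday baseline plus the lagged temperature contribution
#' `sum_l w_l * f(temp[t - l])` plus Gaussian noise, where `f` is the true
#' cumulative exposure-response curve and `w` the normalized lag weights.
#' Identical `(config, seed)` give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param city_id character label.
#' @return list with elements `series` (a [city_series()]) and `truth`
#'   (class `sim_truth`: the cold/heat curve halves, combined curve,
#'   `lag_weights`, `mmt_true`, `noise_sd`, `temp_burnin`, `config`).
#' @export
simulate_city_series <- function(config = sim_config(), seed = 1L,
                                 city_id = "city01") {
  stopifnot(inherits(config, "sim_config"))
  dates <- seq(as.Date(config$window[1]), as.Date(config$window[2]), by = "day")
  n <- length(dates)
  L <- config$max_lag
  if (n < 2L * (L + 1L)) stop("window must span at least 2 * (max_lag + 1) days")
  with_seed(seed, {
    dates_ext <- seq(dates[1] - L, dates[n], by = "day")
    ar <- stats::filter(stats::rnorm(n + L, 0, config$temp_noise_sd),
                        config$temp_ar, method = "recursive")
    temp_ext <- config$temp_mean +
      seasonal(dates_ext, config$temp_amp, 196) + as.numeric(ar)
    temp <- temp_ext[(L + 1):(n + L)]

    rh <- pmin(100, pmax(0, 71.6 + seasonal(dates, 10, 196) + stats::rnorm(n, 0, 6)))
    ws <- pmax(0.05, 1.8 + seasonal(dates, 0.5, 60) + stats::rnorm(n, 0, 0.5))
    sunshine <- pmin(24, pmax(0, 5.7 + seasonal(dates, 2, 350) + stats::rnorm(n, 0, 1.5)))
    ap <- 844.4 + seasonal(dates, 3, 15) + stats::rnorm(n, 0, 2)

    md <- format(dates, "%m-%d")
    holiday <- md %in% c("01-01", "01-02", "01-03", config$holidays)

    w <- exp(-(0:L) / config$lag_decay)
    w <- w / sum(w)
    crv <- truth_curves(config)
    f_tot <- function(x) crv$cold(x) + crv$heat(x)
    contrib <- as.numeric(stats::filter(f_tot(temp_ext), w, method = "convolution",
                                        sides = 1))[(L + 1):(n + L)]

    dow <- as.POSIXlt(dates)$wday  # 0 = Sunday
    yll <- config$baseline_mean + seasonal(dates, config$seasonal_amp, 15) +
      config$weekend_effect * (dow %in% c(0, 6)) +
      config$holiday_effect * holiday +
      contrib + stats::rnorm(n, 0, config$noise_sd)

    series <- city_series(
      data.frame(date = dates, yll = yll, temp = temp, rh = rh, ws = ws,
                 sunshine = sunshine, ap = ap, holiday = holiday),
      city_id = city_id, temp_burnin = temp_ext[seq_len(L)])
    truth <- structure(
      list(curve_cold = crv$cold, curve_heat = crv$heat,
           curve = f_tot, lag_weights = w, mmt_true = config$mmt_true,
           noise_sd = config$noise_sd, temp_burnin = temp_ext[seq_len(L)],
           config = config),
      class = "sim_truth")
    list(series = series, truth = truth)
  })
}

#' True attributable fraction of a simulated series
#'
#' Exact oracle: sums the noise-free lagged temperature contributions of
#' every study day relative to a history held at the true minimum-YLL
#' temperature (where the true curve is zero), splits each lagged term into
#' cold (`temp < mmt_true`) and heat (`temp > mmt_true`) parts, and divides
#' by the total simulated YLL. By construction
#' `af_total == af_cold + af_heat` exactly.
#'
#' @param series a [city_series()] produced by [simulate_city_series()].
#' @param truth the matching `sim_truth`.
#' @return named numeric: `af_total`, `af_cold`, `af_heat` (fractions).
#' @export
true_attributable_fraction <- function(series, truth) {
  stopifnot(inherits(series, "city_series"), inherits(truth, "sim_truth"))
  L <- length(truth$lag_weights) - 1L
  burn <- attr(series, "temp_burnin")
  if (is.null(burn)) burn <- truth$temp_burnin
  temp_ext <- c(burn, series$temp)
  n <- nrow(series)
  if (length(temp_ext) != n + L) {
    stop("series length does not match the truth's lag structure")
  }
  w <- truth$lag_weights
  cold_ext <- truth$curve_cold(temp_ext)
  heat_ext <- truth$curve_heat(temp_ext)
  lagsum <- function(v) {
    sum(as.numeric(stats::filter(v, w, method = "convolution",
                                 sides = 1))[(L + 1):(n + L)])
  }
  tot_yll <- sum(series$yll)
  cold <- lagsum(cold_ext)
  heat <- lagsum(heat_ext)
  c(af_total = (cold + heat) / tot_yll,
    af_cold = cold / tot_yll, af_heat = heat / tot_yll)
}

#' Simulate a multi-city study
#'
#' Draws per-city seeds deterministically from the master seed, simulates
#' each city with [simulate_city_series()], and generates a city-level
#' meta-predictor table (geography, demography, economy, health resources).
#' With `heterogeneity = "predictor"`, each city's true curve is scaled by
#' `1 + het_strength * z_i`, where `z_i` is that city's standardized
#' urbanization rate, so the true burden varies monotonically with a known
#' meta-predictor; with `"none"` all cities share one truth.
#'
#' @param n_cities number of cities (>= 1).
#' @param config a [sim_config()] shared by all cities.
#' @param seed master integer seed.
#' @param heterogeneity `"none"` (shared truth) or `"predictor"`.
#' @param het_strength scale of the per-city multiplier (default 0.35).
#' @return list: `cities` (list of `list(series, truth)`), `meta`
#'   (data frame of meta-predictors, one row per city), `multipliers`.
#' @export
simulate_multicity <- function(n_cities, config = sim_config(), seed = 1L,
                               heterogeneity = c("none", "predictor"),
                               het_strength = 0.35) {
  heterogeneity <- match.arg(heterogeneity)
  n_cities <- as.integer(n_cities)
  if (n_cities < 1L) stop("n_cities must be >= 1")
  with_seed(seed, {
    ids <- sprintf("city%02d", seq_len(n_cities))
    city_seeds <- sample.int(.Machine$integer.max - 1L, n_cities)
    urban <- stats::runif(n_cities, 0.30, 0.75)
    meta <- data.frame(
      city = ids,
      longitude = stats::runif(n_cities, 97.5, 105.5),
      latitude = stats::runif(n_cities, 21.5, 28.5),
      altitude = stats::runif(n_cities, 500, 3200),
      pop_density = stats::runif(n_cities, 30, 650),
      pop_growth_rate = stats::runif(n_cities, 2, 9),
      urbanization_rate = urban,
      gdp_per_capita = stats::runif(n_cities, 18000, 95000),
      gdp_growth_rate = stats::runif(n_cities, 2, 11),
      employment_rate = stats::runif(n_cities, 88, 97),
      health_technicians_per_1000 = stats::runif(n_cities, 4, 12),
      hospital_beds_per_1000 = stats::runif(n_cities, 3.5, 8.5)
    )
    mult <- rep(1, n_cities)
    if (heterogeneity == "predictor" && n_cities > 1L) {
      z <- as.numeric(scale(urban))
      mult <- pmax(0.1, 1 + het_strength * z)
    }
    cities <- lapply(seq_len(n_cities), function(i) {
      cfg_i <- config
      cfg_i$effect_scale <- config$effect_scale * mult[i]
      simulate_city_series(cfg_i, seed = city_seeds[i], city_id = ids[i])
    })
    list(cities = cities, meta = meta, multipliers = mult)
  })
}

#' Simulate individual death records
#'
#' Draws deaths uniformly over a window with ages from a truncated normal
#' (mean 72, SD 15, clamped to 0..105) and a configurable sex ratio, plus a
#' cause label; intended to exercise the record-to-daily-YLL path end to end.
#'
#' @param n_deaths number of records.
#' @param window length-2 date window.
#' @param seed integer seed.
#' @param p_male probability a record is male.
#' @return data frame `date, age, sex, cause`.
#' @export
simulate_death_records <- function(n_deaths, window = c("2014-01-01", "2014-12-31"),
                                   seed = 1L, p_male = 0.55) {
  window <- as.Date(window)
  with_seed(seed, {
    days <- seq(window[1], window[2], by = "day")
    data.frame(
      date = sample(days, n_deaths, replace = TRUE),
      age = pmin(105, pmax(0, round(stats::rnorm(n_deaths, 72, 15)))),
      sex = sample(c("male", "female"), n_deaths, replace = TRUE,
                   prob = c(p_male, 1 - p_male)),
      cause = sample(c("cardiovascular", "respiratory", "heart", "stroke", "other"),
                     n_deaths, replace = TRUE)
    )
  })
}
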