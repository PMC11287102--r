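#' Reference life table
#'
#' A sex- and age-specific table of residual life expectancy e(age, sex) in
#' years, ages in completed years from 0 to a top (open-ended) age band.
#' Every age from 0 to the top must be present for both sexes, values are
#' non-negative and non-increasing in age within each sex.
#'
#' @param age integer vector of ages in completed years.
#' @param sex character vector, `"male"` or `"female"`.
#' @param e residual life expectancy in years, same length.
#' @return An object of class `life_table`: a data frame with columns
#'   `sex`, `age`, `e` plus a `top_age` attribute.
#' @export
life_table <- function(age, sex, e) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  age <- as.integer(age)
  if (any(age < 0L)) stop("ages must be non-negative")
  if (any(!is.finite(e)) || any(e < 0)) {
    stop("life expectancy must be finite and non-negative")
  }
  d <- data.frame(sex = sex, age = age, e = as.numeric(e))
  if (anyDuplicated(d[c("sex", "age")])) {
    stop("duplicated (sex, age) cells in life table")
  }
  top <- max(d$age)
  for (s in c("male", "female")) {
    sub <- d[d$sex == s, ]
    miss <- setdiff(0:top, sub$age)
    if (length(miss)) {
      stop(sprintf("life table missing (%s, age %s)", s,
                   paste(utils::head(miss, 5L), collapse = ", ")))
    }
    sub <- sub[order(sub$age), ]
    if (any(diff(sub$e) > 1e-9)) {
      stop(sprintf("life expectancy must be non-increasing in age (%s)", s))
    }
  }
  d <- d[order(d$sex, d$age), ]
  rownames(d) <- NULL
  structure(d, class = c("life_table", "data.frame"), top_age = top)
}

#' Average two reference life tables
#'
#' Elementwise mean of two life tables over the same (sex, age) domain; used
#' to approximate a study period's life expectancy from tables bracketing it
#' (for instance a 2010 and a 2019 national table).
#'
#' @param table_a,table_b [life_table()] objects over identical domains.
#' @return a [life_table()] with `e = (e_a + e_b) / 2`.
#' @export
average_life_tables <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "life_table"), inherits(table_b, "life_table"))
  key_a <- paste(table_a$sex, table_a$age)
  key_b <- paste(table_b$sex, table_b$age)
  only_a <- setdiff(key_a, key_b)
  only_b <- setdiff(key_b, key_a)
  if (length(only_a) || length(only_b)) {
    stop(sprintf(
      "life table domains differ; missing cells: %s",
      paste(utils::head(c(only_a, only_b), 6L), collapse = "; ")))
  }
  m <- match(key_a, key_b)
  life_table(table_a$age, table_a$sex, (table_a$e + table_b$e[m]) / 2)
}

#' Years of life lost for a single death
#'
#' Looks up residual life expectancy at the decedent's sex and age in
#' completed years. Non-integer ages are floored to completed years; ages
#' above the table's top open-ended band clamp to that band's value, the
#' standard abridged-life-table convention.
#'
#' @param age age at death (years).
#' @param sex `"male"` or `"female"`.
#' @param lt a [life_table()].
#' @return residual life expectancy in years (non-negative). Vectorized over
#'   `age` and `sex`.
#' @export
yll_for_death <- function(age, sex, lt) {
  stopifnot(inherits(lt, "life_table"))
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop(sprintf("unknown sex code: %s",
                 paste(unique(setdiff(sex, c("male", "female"))), collapse = ", ")))
  }
  if (any(!is.finite(age)) || any(age < 0)) stop("ages must be finite and >= 0")
  a <- pmin(floor(age), attr(lt, "top_age"))
  idx <- match(paste(sex, a), paste(lt$sex, lt$age))
  lt$e[idx]
}

#' Daily YLL series from death records
#'
#' Sums the years of life lost of all deaths occurring on each calendar day
#' of a study window; days with no deaths contribute zero. The series total
#' equals the sum of per-death YLL exactly, and is invariant to record order.
#'
#' @param records data frame with columns `date` (Date or ISO-8601 string),
#'   `age`, `sex`; extra columns may carry subgroup labels.
#' @param lt a [life_table()].
#' @param window length-2 Date (or string) vector, first and last day.
#' @param by optional name of a subgroup column in `records`; one extra
#'   column per subgroup level is appended (levels partition the total, so
#'   the subgroup columns sum to `yll` on every day).
#' @return data frame with one row per day in `window`: columns `date`, `yll`
#'   and, with `by`, `yll_<level>` per subgroup level.
#' @export
daily_yll <- function(records, lt, window, by = NULL) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  days <- seq(window[1], window[2], by = "day")
  out <- data.frame(date = days, yll = 0)
  if (nrow(records)) {
    dates <- as.Date(records$date)
    bad <- dates < window[1] | dates > window[2]
    if (any(bad)) {
      stop(sprintf("death records outside the study window on: %s",
                   paste(utils::head(unique(dates[bad]), 5L), collapse = ", ")))
    }
    y <- yll_for_death(records$age, records$sex, lt)
    agg <- tapply(y, as.character(dates), sum)
    out$yll[match(names(agg), as.character(days))] <- as.numeric(agg)
    if (!is.null(by)) {
      if (!by %in% names(records)) stop(sprintf("no column '%s' in records", by))
      g <- as.character(records[[by]])
      for (lev in sort(unique(g))) {
        col <- rep(0, length(days))
        sel <- g == lev
        agg <- tapply(y[sel], as.character(dates[sel]), sum)
        col[match(names(agg), as.character(days))] <- as.numeric(agg)
        out[[paste0("yll_", lev)]] <- col
      }
    }
  } else if (!is.null(by)) {
    stop("subgroup split requested but there are no records")
  }
  out
}

#' Synthetic sex- and age-specific life table
#'
#' A smooth stand-in for a national complete life table (the real reference
#' table is not redistributable): residual life expectancy declines from a
#' birth value to a small open-ended value at age 100 following a
#' Gompertz-like profile, with women living a few years longer than men and
#' a configurable secular improvement used to emulate two calendar editions.
#'
#' @param e0_male,e0_female life expectancy at birth in years.
#' @param top_age top (open-ended) age band, default 100.
#' @param shift uniform additive shift in years (emulates a later edition).
#' @return a [life_table()] over ages `0..top_age` for both sexes.
#' @export
synthetic_life_table <- function(e0_male = 74.5, e0_female = 79.9,
                                 top_age = 100L, shift = 0) {
  ages <- 0:top_age
  mk <- function(e0) {
    # residual expectancy decays like (1 - age/omega)^1.5, which tracks a
    # modern national complete life table to within a few years at all ages
    e <- (e0 + shift) * (1 - ages / (top_age + 10))^1.5
    cummin(pmax(e, 1.6))
  }
  life_table(
    age = rep(ages, 2L),
    sex = rep(c("male", "female"), each = length(ages)),
    e = c(mk(e0_male), mk(e0_female))
  )
}
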