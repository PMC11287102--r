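# rolling polynomial hash of a string (mod a 32-bit prime; all arithmetic
# stays well inside double precision), for tagging outputs with their config
string_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 4294967291
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Hash of a configuration object
#'
#' Stable hexadecimal tag of any configuration list, written into output
#' headers so every result file records the settings that produced it.
#'
#' @param config any R object serializable by [yaml::as.yaml()].
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  string_hash(yaml::as.yaml(unclass(config)))
}

header_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  lines[startsWith(lines, "#")]
}

#' Write a city series CSV
#'
#' Columns `date,yll,temp,rh,ws,sunshine,ap,holiday` (ISO dates, holiday as
#' 0/1), preceded by `#` header comments carrying the city id, seed, config
#' hash and, when present, the pre-window temperature burn-in at full
#' precision, so write-then-read is an identity.
#'
#' @param series a [city_series()].
#' @param path output file.
#' @param seed,hash optional provenance tags recorded in the header.
#' @export
write_series <- function(series, path, seed = NA, hash = NA) {
  stopifnot(inherits(series, "city_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tempburden city series; city=%s; seed=%s; config=%s",
                     attr(series, "city_id"), seed, hash), con)
  burn <- attr(series, "temp_burnin")
  if (!is.null(burn)) {
    writeLines(paste0("# temp_burnin=",
                      paste(formatC(burn, digits = 17, format = "g"),
                            collapse = ";")), con)
  }
  df <- as.data.frame(series)
  df$holiday <- as.integer(df$holiday)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read a city series CSV
#'
#' Inverse of [write_series()]: validates the schema, strictly consecutive
#' dates and physical ranges, restoring the city id and temperature burn-in
#' from the header comments.
#'
#' @param path input file.
#' @return a [city_series()].
#' @export
read_series <- function(path) {
  comments <- header_comments(path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("date", "yll", "temp", "rh", "ws", "sunshine", "ap", "holiday")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  dates <- as.Date(df$date)
  if (anyNA(dates)) {
    stop(sprintf("%s: unparseable dates on data line(s) %s", path,
                 paste(utils::head(which(is.na(dates)), 5L), collapse = ", ")))
  }
  if (anyDuplicated(dates)) {
    stop(sprintf("%s: duplicate dates (%s)", path,
                 dates[anyDuplicated(dates)]))
  }
  df$date <- dates
  df$holiday <- df$holiday > 0
  city_id <- sub(".*city=([^;]*);.*", "\\1",
                 grep("city=", comments, value = TRUE)[1])
  if (is.na(city_id)) city_id <- basename(path)
  burn_line <- grep("temp_burnin=", comments, value = TRUE)
  burn <- if (length(burn_line)) {
    as.numeric(strsplit(sub(".*temp_burnin=", "", burn_line[1]), ";")[[1]])
  }
  city_series(df, city_id = city_id, temp_burnin = burn)
}

#' Read a reference life table CSV
#'
#' Accepts either `sex,age,e` (pre-averaged) or `sex,age,e2010,e2019`, in
#' which case the two editions are averaged with [average_life_tables()].
#'
#' @param path input file.
#' @return a [life_table()].
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (all(c("sex", "age", "e") %in% names(df))) {
    return(life_table(df$age, df$sex, df$e))
  }
  if (all(c("sex", "age", "e2010", "e2019") %in% names(df))) {
    return(average_life_tables(life_table(df$age, df$sex, df$e2010),
                               life_table(df$age, df$sex, df$e2019)))
  }
  stop(sprintf("%s: expected columns sex,age,e or sex,age,e2010,e2019", path))
}

#' Write / read the city meta-predictor table
#'
#' One row per city: `city` plus numeric city-level covariate columns.
#'
#' @param meta data frame with a `city` column.
#' @param path file path.
#' @param seed,hash optional provenance tags.
#' @export
write_meta_predictors <- function(meta, path, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tempburden meta-predictors; seed=%s; config=%s",
                     seed, hash), con)
  utils::write.csv(meta, con, row.names = FALSE, quote = FALSE)
}

#' @rdname write_meta_predictors
#' @return `read_meta_predictors`: the data frame.
#' @export
read_meta_predictors <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"city" %in% names(df)) stop(sprintf("%s: missing 'city' column", path))
  num <- setdiff(names(df), "city")
  bad <- num[!vapply(df[num], is.numeric, logical(1))]
  if (length(bad)) {
    stop(sprintf("%s: non-numeric predictor column(s) %s", path,
                 paste(bad, collapse = ", ")))
  }
  df
}

#' Serialize a simulation truth to a YAML sidecar
#'
#' Records the generating parameters (curve slopes and minimum, lag weights,
#' noise SD, effect scale) next to a simulated series so downstream checks
#' can recover the generating conditions without rerunning the generator.
#'
#' @param truth a `sim_truth`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  yaml::write_yaml(list(
    mmt_true = cfg$mmt_true, slope_cold = cfg$slope_cold,
    slope_heat = cfg$slope_heat, smooth = cfg$smooth,
    effect_scale = cfg$effect_scale, noise_sd = cfg$noise_sd,
    max_lag = cfg$max_lag, lag_decay = cfg$lag_decay,
    lag_weights = as.numeric(truth$lag_weights),
    temp_burnin = as.numeric(truth$temp_burnin)), path)
}
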