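#' Read an abstracted dive table
#'
#' Reads a CSV of abstracted dive profiles. Two dialects of the
#' inflection-time columns exist in the wild: plain seconds from dive
#' start (`t1_s`..`t4_s`), and the satellite-relay logger convention of
#' percentages of dive duration (`t1_pct`..`t4_pct`), which is converted
#' to seconds as `t/100 * duration_s`. Rows violating basic invariants
#' (non-increasing inflection times, negative depths, non-positive
#' duration, unparseable timestamps) are skipped with a message giving
#' the count.
#'
#' @param path CSV file with header `individual_id, dive_id, start_utc,
#'   duration_s, d1_m..d4_m, t1_s..t4_s` (or `t1_pct..t4_pct`), `lon`
#'   and optionally `lat`.
#' @param dialect `"seconds"` or `"percent"`.
#' @return Tibble of valid profiles in the seconds dialect.
#' @export
read_abstracted <- function(path, dialect = c("seconds", "percent")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tcols <- if (dialect == "seconds") paste0("t", 1:4, "_s")
           else paste0("t", 1:4, "_pct")
  header <- readr::read_csv(path, n_max = 0, show_col_types = FALSE)
  assert_columns(header, c("individual_id", "dive_id", "start_utc",
                           "duration_s", paste0("d", 1:4, "_m"), tcols,
                           "lon"),
                 sprintf("abstracted table '%s'", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           individual_id = "c", dive_id = "c",
                           start_utc = "c", .default = "d"))
  start <- parse_utc(raw$start_utc)
  tmat <- as.matrix(raw[, tcols])
  if (dialect == "percent") tmat <- tmat / 100 * raw$duration_s
  zmat <- as.matrix(raw[, paste0("d", 1:4, "_m")])
  ok <- !is.na(start) &
    is.finite(raw$duration_s) & raw$duration_s > 0 &
    apply(cbind(0, tmat, raw$duration_s), 1,
          function(r) all(is.finite(r)) && all(diff(r) > 0)) &
    apply(zmat, 1, function(r) all(is.finite(r) & r >= 0))
  if (any(!ok)) {
    inform(sprintf("read_abstracted: skipped %d invalid row(s).", sum(!ok)))
  }
  out <- tibble(
    individual_id = raw$individual_id, dive_id = raw$dive_id,
    start_utc = start, duration_s = raw$duration_s,
    d1_m = as.numeric(zmat[, 1]), d2_m = as.numeric(zmat[, 2]),
    d3_m = as.numeric(zmat[, 3]), d4_m = as.numeric(zmat[, 4]),
    t1_s = as.numeric(tmat[, 1]), t2_s = as.numeric(tmat[, 2]),
    t3_s = as.numeric(tmat[, 3]), t4_s = as.numeric(tmat[, 4]),
    lon = raw$lon,
    lat = if ("lat" %in% names(raw)) raw$lat else NA_real_)
  out[ok, , drop = FALSE]
}

#' Write an abstracted dive table
#'
#' @param profiles Abstracted profiles (seconds dialect).
#' @param path Output CSV path.
#' @param dialect Write inflection times as `"seconds"` or `"percent"`
#'   of dive duration.
#' @return `path`, invisibly.
#' @export
write_abstracted <- function(profiles, path,
                             dialect = c("seconds", "percent")) {
  dialect <- match.arg(dialect)
  assert_columns(profiles, c("individual_id", "dive_id", "start_utc",
                             "duration_s", paste0("d", 1:4, "_m"),
                             paste0("t", 1:4, "_s"), "lon"), "`profiles`")
  out <- profiles
  out$start_utc <- format_utc(parse_utc(out$start_utc))
  if (dialect == "percent") {
    for (i in 1:4) {
      out[[paste0("t", i, "_pct")]] <-
        out[[paste0("t", i, "_s")]] / out$duration_s * 100
      out[[paste0("t", i, "_s")]] <- NULL
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write high-resolution records
#'
#' CSV with columns `individual_id, dive_id, timestamp_utc (ISO 8601),
#' depth_m`.
#'
#' @param path CSV path.
#' @return `read_hires()`: samples tibble with `individual_id, dive_id,
#'   time_utc, depth_m`.
#' @export
read_hires <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           individual_id = "c", dive_id = "c",
                           timestamp_utc = "c", depth_m = "d"))
  assert_columns(raw, c("individual_id", "dive_id", "timestamp_utc",
                        "depth_m"), sprintf("hi-res table '%s'", path))
  tibble(individual_id = raw$individual_id, dive_id = raw$dive_id,
         time_utc = parse_utc(raw$timestamp_utc), depth_m = raw$depth_m)
}

#' @rdname read_hires
#' @param samples Samples tibble.
#' @export
write_hires <- function(samples, path) {
  assert_columns(samples, c("individual_id", "dive_id", "time_utc",
                            "depth_m"), "`samples`")
  readr::write_csv(tibble(
    individual_id = samples$individual_id, dive_id = samples$dive_id,
    timestamp_utc = format_utc(samples$time_utc),
    depth_m = samples$depth_m), path)
  invisible(path)
}

#' Read / write drift-rate series
#'
#' CSV with columns `individual_id, timestamp_utc (ISO 8601),
#' drift_rate_ms, dive_id`; the drift rate is written with six decimal
#' places.
#'
#' @param series Drift-rate series tibble (must be time-ordered within
#'   individual).
#' @param path CSV path.
#' @export
write_drift_series <- function(series, path) {
  assert_columns(series, c("individual_id", "time_utc", "drift_rate_ms",
                           "dive_id"), "`series`")
  if (nrow(series) > 1 &&
      any(unlist(tapply(as.numeric(series$time_utc), series$individual_id,
                        function(t) diff(t) < 0)),
          na.rm = TRUE)) {
    abort("`series` must be time-ordered within individual.")
  }
  out <- tibble(
    individual_id = series$individual_id,
    timestamp_utc = format_utc(series$time_utc),
    drift_rate_ms = sprintf("%.6f", series$drift_rate_ms),
    dive_id = series$dive_id)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_drift_series
#' @export
read_drift_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           individual_id = "c", timestamp_utc = "c",
                           drift_rate_ms = "d", dive_id = "c"))
  assert_columns(raw, c("individual_id", "timestamp_utc", "drift_rate_ms",
                        "dive_id"), sprintf("drift series '%s'", path))
  tibble(individual_id = raw$individual_id,
         time_utc = parse_utc(raw$timestamp_utc),
         drift_rate_ms = raw$drift_rate_ms,
         dive_id = raw$dive_id)
}

#' Read / write ground-truth label tables
#'
#' CSV with columns `dive_id, dive_type, true_drift_rate, drift_start_s,
#' drift_end_s, detectable`.
#'
#' @param labels Label tibble.
#' @param path CSV path.
#' @export
write_labels <- function(labels, path) {
  assert_columns(labels, c("dive_id", "dive_type", "true_drift_rate",
                           "drift_start_s", "drift_end_s", "detectable"),
                 "`labels`")
  readr::write_csv(labels, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    dive_id = "c", dive_type = "c", detectable = "l",
                    .default = "d"))
}
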