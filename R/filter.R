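#' Configuration of the seven-step drift filter
#'
#' Default thresholds encode the selection criteria established for
#' adult southern elephant seals:
#' retained drift fragments sink at between -0.6 and -0.05 m s^-1, start
#' and end between 100 and 550 m, last longer than 8 min and at least
#' 40% of the dive, are followed by active ascent (>= 0.2 m s^-1),
#' preceded by active descent (<= -0.6 m s^-1), and do not start in the
#' 13:30-19:30 local-time lull of drift behaviour.
#'
#' Boundary conventions: every numeric boundary is inclusive except the
#' minimum fragment length (strict, "longer than 8 min") and the
#' local-time exclusion window, which is half-open `[13:30, 19:30)`.
#'
#' @param speed_min,speed_max Retained vertical-speed band, m s^-1
#'   (negative = sinking). Defaults -0.6 and -0.05.
#' @param depth_min,depth_max Retained start/end depth band, m. Defaults
#'   100 and 550.
#' @param min_duration Minimum fragment length, s (strict). Default 480.
#' @param min_pct Minimum percentage of the dive duration. Default 40.
#' @param next_speed_min Minimum vertical speed of the following
#'   fragment, m s^-1. Default 0.2.
#' @param prev_speed_max Maximum vertical speed of the preceding
#'   fragment, m s^-1. Default -0.6.
#' @param lt_excl_start,lt_excl_end Local-time exclusion window, decimal
#'   hours; may wrap midnight. Defaults 13.5 and 19.5.
#' @param allow_positive If `TRUE`, `speed_max` may be positive (e.g.
#'   recently weaned pups or late-gestation females, which can be
#'   positively buoyant); the default `FALSE` enforces a non-positive
#'   band.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(speed_min = -0.6, speed_max = -0.05,
                          depth_min = 100, depth_max = 550,
                          min_duration = 480, min_pct = 40,
                          next_speed_min = 0.2, prev_speed_max = -0.6,
                          lt_excl_start = 13.5, lt_excl_end = 19.5,
                          allow_positive = FALSE) {
  if (!allow_positive && speed_max > 0) {
    abort("`speed_max` > 0 requires `allow_positive = TRUE`.")
  }
  if (speed_min >= speed_max) abort("`speed_min` must be < `speed_max`.")
  if (depth_min >= depth_max) abort("`depth_min` must be < `depth_max`.")
  if (min_duration <= 0) abort("`min_duration` must be > 0.")
  if (min_pct <= 0 || min_pct > 100) abort("`min_pct` must be in (0, 100].")
  structure(list(speed_min = speed_min, speed_max = speed_max,
                 depth_min = depth_min, depth_max = depth_max,
                 min_duration = min_duration, min_pct = min_pct,
                 next_speed_min = next_speed_min,
                 prev_speed_max = prev_speed_max,
                 lt_excl_start = lt_excl_start, lt_excl_end = lt_excl_end,
                 allow_positive = allow_positive),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<filter_config> speed [%g, %g] m/s, depth [%g, %g] m, ",
    "duration > %g s, pct >= %g%%, next >= %g, prev <= %g, ",
    "lt excluded [%.2f, %.2f)\n"),
    x$speed_min, x$speed_max, x$depth_min, x$depth_max,
    x$min_duration, x$min_pct, x$next_speed_min, x$prev_speed_max,
    x$lt_excl_start, x$lt_excl_end))
  invisible(x)
}

#' Individual selection criteria
#'
#' Vectorised pass/fail decisions for each of the seven selection
#' criteria, evaluated on a fragment table from [fragment_dives()].
#' Fragments with a missing neighbour speed fail the corresponding
#' neighbour criterion (edge fragments cannot demonstrate the required
#' context).
#'
#' @param fragments Fragment tibble (see [fragment_dives()]).
#' @param config A [filter_config()].
#' @return Logical vector, `TRUE` = retained by this criterion.
#' @name criteria
NULL

#' @rdname criteria
#' @export
criterion_speed <- function(fragments, config = filter_config()) {
  fragments$vspeed_ms >= config$speed_min &
    fragments$vspeed_ms <= config$speed_max
}

#' @rdname criteria
#' @export
criterion_depth <- function(fragments, config = filter_config()) {
  fragments$depth_start_m >= config$depth_min &
    fragments$depth_start_m <= config$depth_max &
    fragments$depth_end_m >= config$depth_min &
    fragments$depth_end_m <= config$depth_max
}

#' @rdname criteria
#' @export
criterion_length <- function(fragments, config = filter_config()) {
  fragments$duration_s > config$min_duration
}

#' @rdname criteria
#' @export
criterion_pct <- function(fragments, config = filter_config()) {
  fragments$pct_duration >= config$min_pct
}

#' @rdname criteria
#' @export
criterion_next_ascent <- function(fragments, config = filter_config()) {
  !is.na(fragments$next_speed_ms) &
    fragments$next_speed_ms >= config$next_speed_min
}

#' @rdname criteria
#' @export
criterion_prev_descent <- function(fragments, config = filter_config()) {
  !is.na(fragments$prev_speed_ms) &
    fragments$prev_speed_ms <= config$prev_speed_max
}

#' @rdname criteria
#' @export
criterion_time <- function(fragments, config = filter_config()) {
  lt <- fragments$lt_hours
  if (anyNA(lt)) {
    abort("`lt_hours` contains NA (missing longitude); cannot apply the diel criterion.")
  }
  a <- config$lt_excl_start; b <- config$lt_excl_end
  inside <- if (a <= b) lt >= a & lt < b else lt >= a | lt < b
  !inside
}

criterion_registry <- function() {
  list(speed = criterion_speed,
       depth = criterion_depth,
       length = criterion_length,
       pct = criterion_pct,
       next_ascent = criterion_next_ascent,
       time = criterion_time,
       prev_descent = criterion_prev_descent)
}

#' Apply the step-wise drift filter
#'
#' Evaluates the seven selection criteria on the candidate fragments
#' (indices 2-4 surviving the preparation exclusions) and retains those
#' passing all of them. Because the criteria are conjunctive, the final
#' drift set is identical for every ordering of `order`; the ordering
#' only affects the step-wise retention trace of the report.
#'
#' @param fragments Fragment tibble from [fragment_dives()].
#' @param config A [filter_config()].
#' @param order Character vector naming the criteria in application
#'   order; a permutation of `speed`, `depth`, `length`, `pct`,
#'   `next_ascent`, `time`, `prev_descent` (a subset is allowed, e.g. to
#'   drop the length criterion for diagnostics).
#' @return An object of class `drift_filter_result`: list with `drift`
#'   (tibble of retained fragments), and `report` (class
#'   `filter_report`) containing `n_input_fragments`, `n_candidates`,
#'   `single` (per-criterion retention when applied alone, with both the
#'   all-fragments and the candidates-only denominator), `stepwise`
#'   (cumulative retention in `order`), `final_ids`, and
#'   `pct_dives_drift` (share of dives containing a retained fragment).
#' @examples
#' # see the package vignette for an end-to-end simulate -> filter run
#' @export
apply_filters <- function(fragments, config = filter_config(),
                          order = c("speed", "depth", "length", "pct",
                                    "next_ascent", "time", "prev_descent")) {
  assert_columns(fragments,
                 c("dive_id", "vspeed_ms", "depth_start_m", "depth_end_m",
                   "duration_s", "pct_duration", "lt_hours",
                   "prev_speed_ms", "next_speed_ms", "candidate"),
                 "`fragments`")
  registry <- criterion_registry()
  unknown <- setdiff(order, names(registry))
  if (length(unknown) > 0) {
    abort(sprintf("unknown criterion name(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(order)) abort("`order` must not repeat criteria.")

  cand <- fragments[fragments$candidate, , drop = FALSE]
  n_input <- nrow(fragments)
  n_cand <- nrow(cand)

  pass <- lapply(registry[order], function(f) f(cand, config))
  pass_mat <- if (n_cand > 0) do.call(cbind, pass) else
    matrix(logical(0), 0, length(order), dimnames = list(NULL, order))

  n_pass <- unname(colSums(pass_mat))
  single <- tibble(
    criterion = order,
    retained = if (n_cand > 0) n_pass else rep(0, length(order)),
    pct_of_candidates = if (n_cand > 0) 100 * n_pass / n_cand
                        else rep(NA_real_, length(order)),
    pct_of_all = if (n_input > 0) 100 * n_pass / n_input
                 else rep(NA_real_, length(order)))

  keep <- rep(TRUE, n_cand)
  step_counts <- integer(length(order))
  for (i in seq_along(order)) {
    keep <- keep & pass_mat[, i]
    step_counts[i] <- sum(keep)
  }
  stepwise <- tibble(
    step = seq_along(order), criterion = order, retained = step_counts,
    pct_of_candidates = if (n_cand > 0) 100 * step_counts / n_cand
                        else NA_real_)

  drift <- cand[keep, , drop = FALSE]
  n_dives <- length(unique(fragments$dive_id))
  report <- structure(list(
    n_input_fragments = n_input,
    n_candidates = n_cand,
    single = single,
    stepwise = stepwise,
    final_ids = paste(drift$dive_id, drift$fragment_index, sep = ":"),
    n_drift = nrow(drift),
    pct_dives_drift = if (n_dives > 0)
      100 * length(unique(drift$dive_id)) / n_dives else NA_real_,
    order = order,
    config = config), class = "filter_report")

  structure(list(drift = drift, report = report),
            class = "drift_filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d fragments (%d candidates) -> %d drift fragments (%.2f%% of dives)\n",
              x$n_input_fragments, x$n_candidates, x$n_drift,
              x$pct_dives_drift))
  cat("single-criterion retention (candidates denominator):\n")
  print(as.data.frame(x$single), row.names = FALSE)
  invisible(x)
}

#' @export
print.drift_filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @describeIn apply_filters Tidy per-criterion retention table of a
#'   `filter_report` (or of a whole `drift_filter_result`).
#' @param x A `filter_report` or `drift_filter_result`.
#' @param ... Unused.
#' @export
tidy.filter_report <- function(x, ...) x$single

#' @export
tidy.drift_filter_result <- function(x, ...) tidy(x$report)

#' @export
glance.filter_report <- function(x, ...) {
  tibble(n_input_fragments = x$n_input_fragments,
         n_candidates = x$n_candidates,
         n_drift = x$n_drift,
         pct_dives_drift = x$pct_dives_drift)
}

#' @export
glance.drift_filter_result <- function(x, ...) glance(x$report)

#' Extract the drift-rate time series
#'
#' One observation per retained drift fragment: the fragment's absolute
#' start time and its vertical speed (= the drift rate), ordered in time
#' within each individual.
#'
#' @param drift Retained drift fragments (the `drift` element of an
#'   [apply_filters()] result, or any fragment tibble).
#' @return Tibble with columns `individual_id`, `time_utc`,
#'   `drift_rate_ms`, `dive_id`.
#' @export
extract_drift_series <- function(drift) {
  if (inherits(drift, "drift_filter_result")) drift <- drift$drift
  if (nrow(drift) == 0) {
    return(tibble(individual_id = character(),
                  time_utc = as.POSIXct(character(), tz = "UTC"),
                  drift_rate_ms = numeric(), dive_id = character()))
  }
  assert_columns(drift, c("individual_id", "start_utc", "vspeed_ms", "dive_id"),
                 "`drift`")
  drift %>%
    mutate(time_utc = .data$start_utc, drift_rate_ms = .data$vspeed_ms) %>%
    arrange(.data$individual_id, .data$time_utc) %>%
    dplyr::select("individual_id", "time_utc", "drift_rate_ms", "dive_id")
}
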