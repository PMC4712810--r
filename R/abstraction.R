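#' Broken-stick abstraction of a single dive
#'
#' Re-implements the on-board abstraction used by satellite-relay data
#' loggers: starting from the two surface endpoints, the sample with the
#' largest vertical deviation from the current polyline is added
#' iteratively until `n_points` at-depth inflection points are selected.
#' The dive is then summarised by 6 points (2 surface + 4 at depth) and
#' can be reconstructed by linear interpolation.
#'
#' Ties in the maximal residual are broken by earliest time. The residual
#' is measured vertically (depth difference), the standard choice for
#' iterative end-point fits on time series.
#'
#' @param times Sample times in seconds from dive start (strictly
#'   increasing).
#' @param depths Sample depths in metres, positive down.
#' @param n_points Number of at-depth inflection points. Default 4.
#' @param surface_threshold Maximum depth (m) tolerated at the dive's
#'   first and last sample. Default 2.
#' @return A list of class `broken_stick` with elements
#'   `inflection_times`, `inflection_depths` (length `n_points`,
#'   time-ordered), `duration`, `selection_order` (sample indices in the
#'   order chosen), `residual_path` (max residual after each addition)
#'   and `max_residual` (largest remaining deviation).
#' @examples
#' t <- seq(0, 100, by = 2)
#' z <- approx(c(0, 50, 100), c(0, 120, 0), xout = t)$y  # V-dive
#' abstract_dive(t, z)$max_residual
#' @export
abstract_dive <- function(times, depths, n_points = 4,
                          surface_threshold = 2) {
  n <- length(times)
  if (n != length(depths)) abort("`times` and `depths` must have equal length.")
  if (n < n_points + 2) {
    abort(sprintf("dive has %d samples; need at least n_points + 2 = %d.",
                  n, n_points + 2))
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (depths[1] > surface_threshold || depths[n] > surface_threshold) {
    abort("dive must start and end at the surface (within `surface_threshold`).")
  }
  sel <- c(1L, n)
  picks <- integer(0)
  residual_path <- numeric(0)
  for (k in seq_len(n_points)) {
    fit <- approx(times[sel], depths[sel], xout = times)$y
    res <- abs(depths - fit)
    res[sel] <- -Inf
    pick <- which.max(res)           # earliest index on ties
    picks <- c(picks, pick)
    sel <- sort(c(sel, pick))
    fit2 <- approx(times[sel], depths[sel], xout = times)$y
    residual_path <- c(residual_path, max(abs(depths - fit2)))
  }
  interior <- setdiff(sel, c(1L, n))
  structure(list(
    inflection_times = times[interior],
    inflection_depths = depths[interior],
    duration = times[n] - times[1],
    selection_order = picks,
    residual_path = residual_path,
    max_residual = residual_path[length(residual_path)]),
    class = "broken_stick")
}

#' Abstract every dive of a deployment
#'
#' Applies [abstract_dive()] per dive to a high-resolution sample table
#' and returns the abstracted dive table in the seconds dialect, one row
#' per dive, suitable for [prepare_dives()] and [fragment_dives()].
#'
#' @param samples Tibble with columns `individual_id`, `dive_id`,
#'   `time_utc`, `depth_m` (regularly sampled within each dive).
#' @param dives Optional per-dive metadata tibble with columns `dive_id`,
#'   `lon` (and optionally `lat`), joined onto the output; without it
#'   longitude is `NA` and local-time filtering is not possible
#'   downstream.
#' @inheritParams abstract_dive
#' @return Tibble with columns `individual_id`, `dive_id`, `start_utc`,
#'   `duration_s`, `d1_m`..`d4_m`, `t1_s`..`t4_s`, `lon`, `lat`,
#'   `max_residual_m`.
#' @export
abstract_dives <- function(samples, dives = NULL, n_points = 4,
                           surface_threshold = 2) {
  assert_columns(samples, c("individual_id", "dive_id", "time_utc", "depth_m"),
                 "`samples`")
  ids <- unique(samples$dive_id)
  t_num <- as.numeric(samples$time_utc)
  idx_by_dive <- split(seq_len(nrow(samples)), samples$dive_id)[ids]
  rows <- lapply(ids, function(id) {
    i <- idx_by_dive[[id]]
    tt <- t_num[i]
    o <- order(tt)
    i <- i[o]; tt <- tt[o]
    bs <- abstract_dive(tt - tt[1], samples$depth_m[i], n_points,
                        surface_threshold)
    tibble(
      individual_id = samples$individual_id[i[1]],
      dive_id = id,
      start_utc = as.POSIXct(tt[1], origin = "1970-01-01", tz = "UTC"),
      duration_s = bs$duration,
      d1_m = bs$inflection_depths[1], d2_m = bs$inflection_depths[2],
      d3_m = bs$inflection_depths[3], d4_m = bs$inflection_depths[4],
      t1_s = bs$inflection_times[1], t2_s = bs$inflection_times[2],
      t3_s = bs$inflection_times[3], t4_s = bs$inflection_times[4],
      max_residual_m = bs$max_residual)
  })
  out <- bind_rows(rows)
  if (!is.null(dives)) {
    assert_columns(dives, c("dive_id", "lon"), "`dives`")
    meta <- dives[, intersect(c("dive_id", "lon", "lat"), names(dives))]
    out <- left_join(out, meta, by = "dive_id")
  }
  if (!"lon" %in% names(out)) out$lon <- NA_real_
  if (!"lat" %in% names(out)) out$lat <- NA_real_
  out
}

#' Reconstruct depths from an abstracted profile
#'
#' Linear interpolation through the six inflection points (the two
#' surface points are implicit at `(0, 0)` and `(duration_s, 0)`).
#'
#' @param profile A one-row data frame (or list) with fields `duration_s`,
#'   `t1_s`..`t4_s`, `d1_m`..`d4_m`.
#' @param at_times Times (s from dive start) at which to evaluate; must
#'   lie in `[0, duration_s]`.
#' @return Depths in metres.
#' @export
reconstruct <- function(profile, at_times) {
  p <- as.list(profile)
  dur <- p$duration_s
  if (any(at_times < 0 | at_times > dur)) {
    abort("`at_times` must lie within [0, duration_s].")
  }
  tt <- c(0, p$t1_s, p$t2_s, p$t3_s, p$t4_s, dur)
  zz <- c(0, p$d1_m, p$d2_m, p$d3_m, p$d4_m, 0)
  approx(tt, zz, xout = at_times)$y
}
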