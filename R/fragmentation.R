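#' Remove invalid dives before filtering
#'
#' Drops abstracted dive profiles whose recorded duration is zero (or
#' negative, which can only arise from corrupted transmissions) and
#' reports how many were removed.
#'
#' @param profiles Abstracted dive table as returned by
#'   [abstract_dives()] or [read_abstracted()].
#' @return The retained profiles (tibble).
#' @export
prepare_dives <- function(profiles) {
  assert_columns(profiles, "duration_s", "`profiles`")
  bad <- !is.finite(profiles$duration_s) | profiles$duration_s <= 0
  if (any(bad)) {
    inform(sprintf("prepare_dives: removed %d dive(s) with non-positive duration.",
                   sum(bad)))
  }
  as_tibble(profiles[!bad, , drop = FALSE])
}

#' Solar local time from longitude
#'
#' Local time is defined as solar mean time, `UTC + longitude/15` hours.
#' No civil time zones or daylight saving are involved: the animals
#' carry no political clock, and the diel criterion of the drift filter
#' is about the sun.
#'
#' @param utc POSIXct timestamps (UTC).
#' @param longitude Degrees east in `[-180, 180]` (vectorised).
#' @return POSIXct values shifted to solar local time (still printed in
#'   the UTC zone; only the clock reading matters).
#' @examples
#' local_time(as.POSIXct("2009-02-01 12:00:00", tz = "UTC"), 70.2)
#' @export
local_time <- function(utc, longitude) {
  if (any(longitude < -180 | longitude > 180, na.rm = TRUE)) {
    abort("`longitude` must be within [-180, 180] degrees east.")
  }
  utc + longitude / 15 * 3600
}

# decimal hour of day of a (local) POSIXct
hour_of_day <- function(t) {
  (as.numeric(t) %% 86400) / 3600
}

#' Split abstracted dives into five fragments
#'
#' Each abstracted profile is divided into the five segments between its
#' six inflection points. Fragment vertical speed is
#' `(depth_start - depth_end) / (t_end - t_start)` with depth positive
#' down, so a sinking drift has negative speed. Percentage duration is
#' the fragment's share of the total dive duration. Fragments 1 and 5
#' (descent and ascent) and fragments whose two inflection points have
#' the same recorded depth (flat bottoms) are marked `candidate = FALSE`;
#' they are never drift candidates but still provide the `prev_speed_ms`
#' / `next_speed_ms` context of their neighbours.
#'
#' @param profiles Abstracted dive table (seconds dialect) with columns
#'   `individual_id`, `dive_id`, `start_utc`, `duration_s`, `d1_m`..`d4_m`,
#'   `t1_s`..`t4_s`, `lon`.
#' @param lt_reference Which instant of a fragment defines its local
#'   time for the diel criterion: its `"start"` (default) or its
#'   `"midpoint"`.
#' @return Tibble with one row per fragment: `individual_id`, `dive_id`,
#'   `fragment_index`, `t_start_s`, `t_end_s`, `depth_start_m`,
#'   `depth_end_m`, `vspeed_ms`, `duration_s`, `pct_duration`,
#'   `start_utc` (absolute fragment start), `lt_hours` (decimal local
#'   hour used by the diel criterion), `prev_speed_ms`, `next_speed_ms`,
#'   `candidate`.
#' @export
fragment_dives <- function(profiles, lt_reference = c("start", "midpoint")) {
  lt_reference <- match.arg(lt_reference)
  assert_columns(profiles,
                 c("individual_id", "dive_id", "start_utc", "duration_s",
                   paste0("d", 1:4, "_m"), paste0("t", 1:4, "_s"), "lon"),
                 "`profiles`")
  if (nrow(profiles) == 0) {
    return(tibble(individual_id = character(), dive_id = character(),
                  fragment_index = integer(), t_start_s = numeric(),
                  t_end_s = numeric(), depth_start_m = numeric(),
                  depth_end_m = numeric(), vspeed_ms = numeric(),
                  duration_s = numeric(), pct_duration = numeric(),
                  start_utc = as.POSIXct(character(), tz = "UTC"),
                  lt_hours = numeric(), prev_speed_ms = numeric(),
                  next_speed_ms = numeric(), candidate = logical()))
  }
  tmat <- cbind(0, profiles$t1_s, profiles$t2_s, profiles$t3_s,
                profiles$t4_s, profiles$duration_s)
  if (any(t(apply(tmat, 1, diff)) <= 0)) {
    abort("non-monotone inflection times in `profiles`.")
  }
  zmat <- cbind(0, profiles$d1_m, profiles$d2_m, profiles$d3_m,
                profiles$d4_m, 0)
  n <- nrow(profiles)
  frag <- tibble(
    individual_id = rep(profiles$individual_id, each = 5),
    dive_id = rep(profiles$dive_id, each = 5),
    fragment_index = rep(1:5, n),
    t_start_s = as.vector(t(tmat[, 1:5, drop = FALSE])),
    t_end_s = as.vector(t(tmat[, 2:6, drop = FALSE])),
    depth_start_m = as.vector(t(zmat[, 1:5, drop = FALSE])),
    depth_end_m = as.vector(t(zmat[, 2:6, drop = FALSE])),
    dive_duration_s = rep(profiles$duration_s, each = 5),
    dive_start_utc = rep(profiles$start_utc, each = 5),
    lon = rep(profiles$lon, each = 5))
  frag <- frag %>%
    mutate(
      duration_s = .data$t_end_s - .data$t_start_s,
      vspeed_ms = (.data$depth_start_m - .data$depth_end_m) / .data$duration_s,
      pct_duration = 100 * .data$duration_s / .data$dive_duration_s,
      start_utc = .data$dive_start_utc + .data$t_start_s,
      lt_ref_utc = .data$dive_start_utc +
        if (lt_reference == "start") .data$t_start_s
        else (.data$t_start_s + .data$t_end_s) / 2,
      lt_hours = hour_of_day(local_time(.data$lt_ref_utc, .data$lon))) %>%
    group_by(.data$dive_id) %>%
    mutate(prev_speed_ms = lag(.data$vspeed_ms),
           next_speed_ms = lead(.data$vspeed_ms)) %>%
    ungroup() %>%
    mutate(candidate = .data$fragment_index %in% 2:4 &
             .data$depth_start_m != .data$depth_end_m)
  frag %>%
    dplyr::select("individual_id", "dive_id", "fragment_index",
                  "t_start_s", "t_end_s", "depth_start_m", "depth_end_m",
                  "vspeed_ms", "duration_s", "pct_duration", "start_utc",
                  "lt_hours", "prev_speed_ms", "next_speed_ms", "candidate")
}
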