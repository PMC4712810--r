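#' Configuration of the high-resolution sliding-window drift detector
#'
#' Defaults follow the statistical verification algorithm: 2-s records
#' are decimated to 40-s samples, and an 8-min sliding window (stride =
#' one downsampled sample) over data deeper than 50 m is flagged as
#' drifting when the window's mean vertical speed is below 1 m s^-1 in
#' absolute value and its standard deviation is below 0.05 m s^-1 (the
#' sd gate is what separates passive drifting from stroking; it was
#' raised to 0.075 or 0.1 for some individuals in the original analysis,
#' hence the per-individual override).
#'
#' @param target_interval Downsampled sampling interval, s. Default 40.
#' @param window Window length, s; must be a multiple of
#'   `target_interval`. Default 480.
#' @param min_depth Depth gate in m; every sample of a window must be
#'   deeper. Default 50.
#' @param max_abs_mean_speed Mean-speed gate, m s^-1 (strict `<`).
#'   Default 1.
#' @param max_speed_sd Speed-sd gate, m s^-1 (strict `<`). Default 0.05.
#' @return An object of class `hires_config`.
#' @export
hires_config <- function(target_interval = 40, window = 480,
                         min_depth = 50, max_abs_mean_speed = 1,
                         max_speed_sd = 0.05) {
  if (window %% target_interval != 0) {
    abort("`window` must be a multiple of `target_interval`.")
  }
  if (any(c(target_interval, window, min_depth, max_abs_mean_speed,
            max_speed_sd) <= 0)) {
    abort("all detector thresholds must be > 0.")
  }
  structure(list(target_interval = target_interval, window = window,
                 min_depth = min_depth,
                 max_abs_mean_speed = max_abs_mean_speed,
                 max_speed_sd = max_speed_sd),
            class = "hires_config")
}

#' Decimate a high-resolution record
#'
#' Keeps every k-th sample per dive, starting at the first, where
#' `k = target_interval / native interval`; the target must be an
#' integer multiple of the native sampling step.
#'
#' @param samples Tibble with `individual_id`, `dive_id`, `time_utc`,
#'   `depth_m`.
#' @param target_interval Target step in seconds.
#' @return The decimated samples tibble.
#' @export
downsample_record <- function(samples, target_interval = 40) {
  assert_columns(samples, c("dive_id", "time_utc", "depth_m"), "`samples`")
  out <- lapply(split(seq_len(nrow(samples)), samples$dive_id), function(i) {
    tt <- as.numeric(samples$time_utc[i])
    i <- i[order(tt)]
    tt <- sort(tt)
    if (length(i) < 2) return(i)
    native <- tt[2] - tt[1]
    k <- target_interval / native
    if (abs(k - round(k)) > 1e-8) {
      abort(sprintf(
        "target interval %g s is not a multiple of the native %g s step.",
        target_interval, native))
    }
    i[seq(1, length(i), by = round(k))]
  })
  res <- samples[sort(unlist(out)), , drop = FALSE]
  res[order(res$dive_id, res$time_utc), ]
}

#' Detect drift phases in high-resolution records
#'
#' Computes vertical speeds from consecutive downsampled depth
#' differences (same sign convention as the fragment table: getting
#' deeper = negative), slides a window of `config$window` seconds in
#' steps of one sample, and flags windows in which all samples are
#' deeper than `min_depth`, `|mean speed| < max_abs_mean_speed` and
#' `sd(speed) < max_speed_sd`. Overlapping or adjacent flagged windows
#' are merged into maximal drift segments; windows never span dives.
#'
#' @param samples High-resolution sample tibble (native rate; it is
#'   decimated internally).
#' @param config A [hires_config()].
#' @return Tibble of drift segments: `individual_id`, `dive_id`,
#'   `start_utc`, `end_utc`, `duration_s`, `mean_vspeed_ms`,
#'   `n_windows`. Zero rows (with a warning) if no dive is at least one
#'   window long.
#' @export
detect_drift_hires <- function(samples, config = hires_config()) {
  ds <- downsample_record(samples, config$target_interval)
  w <- as.integer(config$window / config$target_interval)  # speeds per window
  segs <- lapply(split(seq_len(nrow(ds)), ds$dive_id), function(i) {
    tt <- as.numeric(ds$time_utc[i])
    o <- order(tt); i <- i[o]; tt <- tt[o]
    z <- ds$depth_m[i]
    n <- length(z)
    if (n < w + 1) return(NULL)
    v <- (z[-n] - z[-1]) / diff(tt)          # deeper => negative
    # window j covers speeds j..j+w-1, i.e. samples j..j+w
    nw <- n - w
    cs <- cumsum(c(0, v))
    cs2 <- cumsum(c(0, v^2))
    m <- (cs[(w + 1):(nw + w)] - cs[1:nw]) / w
    s2 <- (cs2[(w + 1):(nw + w)] - cs2[1:nw]) / w - m^2
    s <- sqrt(pmax(s2 * w / (w - 1), 0))
    deep <- z > config$min_depth
    cd <- cumsum(c(0, deep))
    all_deep <- (cd[(w + 2):(nw + w + 1)] - cd[1:nw]) == (w + 1)
    flag <- all_deep & abs(m) < config$max_abs_mean_speed &
      s < config$max_speed_sd
    if (!any(flag)) return(NULL)
    # merge overlapping/adjacent flagged windows into maximal segments
    j <- which(flag)
    brk <- c(0, which(diff(j) > w), length(j))
    purrr::map_dfr(seq_len(length(brk) - 1), function(b) {
      jj <- j[(brk[b] + 1):brk[b + 1]]
      first <- min(jj); last <- max(jj) + w   # sample index range
      sp <- v[min(jj):(max(jj) + w - 1)]
      tibble(individual_id = ds$individual_id[i[1]],
             dive_id = ds$dive_id[i[1]],
             start_utc = as.POSIXct(tt[first], origin = "1970-01-01",
                                    tz = "UTC"),
             end_utc = as.POSIXct(tt[last], origin = "1970-01-01",
                                  tz = "UTC"),
             duration_s = tt[last] - tt[first],
             mean_vspeed_ms = mean(sp),
             n_windows = length(jj))
    })
  })
  out <- bind_rows(segs)
  if (nrow(out) == 0) {
    if (all(vapply(split(ds$dive_id, ds$dive_id), length, integer(1)) < w + 1)) {
      warn("every record is shorter than one detector window; empty result.")
    }
    return(tibble(individual_id = character(), dive_id = character(),
                  start_utc = as.POSIXct(character(), tz = "UTC"),
                  end_utc = as.POSIXct(character(), tz = "UTC"),
                  duration_s = numeric(), mean_vspeed_ms = numeric(),
                  n_windows = integer()))
  }
  arrange(out, .data$start_utc)
}
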