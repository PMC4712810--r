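#' Simulator configuration
#'
#' Bundles every tunable of the synthetic deployment generator. The
#' defaults describe a multi-month southern elephant seal foraging trip:
#' about 40 dives per day, a small fraction of drift dives whose drift
#' rate follows a known buoyancy trajectory, and V-shaped (transit),
#' U-shaped (benthic/flat-bottomed) and D-type (descending bottom
#' oscillation) dives as confounders. All distributions are artifact
#' choices of this package -- there is no community-standard generative
#' model for dive records -- and are documented in the methods vignette.
#'
#' @param n_days Trip length in days. Default 200.
#' @param dives_per_day Dives per day. Default 40 (roughly continuous
#'   diving with ~25 min dive cycles and some rest).
#' @param type_mix Named proportions of dive types `drift`, `V`, `U`, `D`;
#'   must sum to 1.
#' @param drift_noise_sd Per-dive Gaussian noise on the realised drift
#'   rate around the trajectory value, m s^-1. Default 0.03.
#' @param sample_interval High-resolution sampling step in seconds.
#'   Default 2 (the native TDR rate of the loggers being emulated).
#' @param depth_quantization Depth sensor resolution in metres (depths
#'   are rounded to this grid; 0 disables). Default 0.5.
#' @param diel_peak_window Local-time window (decimal hours) holding 60%
#'   of drift-dive start times; default `c(2, 7)`, reproducing the
#'   observed early-morning peak of drift behaviour.
#' @param longitude_track Function mapping day (numeric, vectorised) to
#'   longitude in degrees east; default a constant 70.2 (Kerguelen).
#' @param individual_id Identifier stamped on all output. Default "sim01".
#' @param start_date UTC date-time of day 0. Default 2009-02-01 00:00 UTC.
#' @param seed Integer RNG seed; `NULL` uses the current RNG stream.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_days = 200,
                       dives_per_day = 40,
                       type_mix = c(drift = 0.05, V = 0.35, U = 0.50, D = 0.10),
                       drift_noise_sd = 0.03,
                       sample_interval = 2,
                       depth_quantization = 0.5,
                       diel_peak_window = c(2, 7),
                       longitude_track = function(day) rep(70.2, length(day)),
                       individual_id = "sim01",
                       start_date = as.POSIXct("2009-02-01 00:00:00", tz = "UTC"),
                       seed = NULL) {
  if (!is.numeric(n_days) || n_days < 1) abort("`n_days` must be >= 1.")
  if (!is.numeric(dives_per_day) || dives_per_day < 1) {
    abort("`dives_per_day` must be >= 1.")
  }
  if (is.null(names(type_mix)) ||
      !setequal(names(type_mix), c("drift", "V", "U", "D"))) {
    abort("`type_mix` must be named with exactly: drift, V, U, D.")
  }
  if (abs(sum(type_mix) - 1) > 1e-8 || any(type_mix < 0)) {
    abort("`type_mix` proportions must be non-negative and sum to 1.")
  }
  if (!is.numeric(sample_interval) || sample_interval <= 0) {
    abort("`sample_interval` must be > 0.")
  }
  if (depth_quantization < 0) abort("`depth_quantization` must be >= 0.")
  if (!is.function(longitude_track)) abort("`longitude_track` must be a function.")
  structure(list(
    n_days = n_days, dives_per_day = dives_per_day,
    type_mix = type_mix[c("drift", "V", "U", "D")],
    drift_noise_sd = drift_noise_sd,
    sample_interval = sample_interval,
    depth_quantization = depth_quantization,
    diel_peak_window = diel_peak_window,
    longitude_track = longitude_track,
    individual_id = individual_id,
    start_date = start_date,
    seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %g days x %g dives/day, mix: %s, dt = %gs, quant = %gm\n",
              x$n_days, x$dives_per_day,
              paste(sprintf("%s %.2f", names(x$type_mix), x$type_mix),
                    collapse = ", "),
              x$sample_interval, x$depth_quantization))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dive geometry templates.
#
# Every dive is a piecewise-linear time-depth skeleton (vertices) plus a
# per-segment stroking oscillation: an endpoint-pinned sinusoid
# A * sin(pi * m * s / L) with ~80 s effective period. Pinning keeps the
# skeleton vertices exact so that the broken-stick abstraction recovers
# them, while the oscillation gives active-swimming phases the
# vertical-speed variability that separates them from passive drifting
# in the high-resolution sliding-window detector.
#
# A template returns vertices (t, z), per-segment oscillation amplitude
# and period, and (for drift dives) the planted drift phase.

# Guard margins used when declaring a planted drift "detectable": the
# nominal phase must pass each criterion with enough slack that depth
# quantization and sample-grid snapping cannot flip the decision.
DETECT_GUARD <- list(speed = 0.02, depth = 15, duration = 60, pct = 3,
                     lt_min = 5)

drift_geometry <- function(v) {
  t_drift <- runif(1, 560, 840)
  if (v < 0) t_drift <- min(t_drift, 385 / abs(v))
  z0_hi <- if (v >= 0) 450 else min(450, 535 - abs(v) * t_drift)
  z0_lo <- if (v >= 0) 250 else 150
  z0 <- runif(1, z0_lo, max(z0_lo, z0_hi))
  z1 <- z0 - v * t_drift          # v negative (sinking) => deeper
  zA <- z1 - 30
  zB <- 0.35 * zA
  t1 <- z0 / 1.0
  t2 <- t1 + t_drift
  t3 <- t2 + 30 / 0.45
  t4 <- t3 + (zA - zB) / 0.7
  t5 <- t4 + zB / 0.9
  list(vertices_t = c(0, t1, t2, t3, t4, t5),
       vertices_z = c(0, z0, z1, zA, zB, 0),
       osc_amp = c(3, 0.15, 1.0, 3, 3),
       osc_period = c(80, 80, 60, 80, 80),
       noise_sd = c(3, 0.05, 1.5, 3, 3),
       drift_start = t1, drift_end = t2)
}

v_geometry <- function() {
  z <- runif(1, 100, 400)
  list(vertices_t = c(0, z / 1.2, z / 1.2 + z / 1.0),
       vertices_z = c(0, z, 0),
       osc_amp = c(3, 3), osc_period = c(80, 80),
       noise_sd = c(3, 3),
       drift_start = NA_real_, drift_end = NA_real_)
}

u_geometry <- function() {
  z <- runif(1, 120, 350)
  t_b <- runif(1, 400, 900)
  t1 <- z / 1.1
  list(vertices_t = c(0, t1, t1 + t_b, t1 + t_b + z / 0.9),
       vertices_z = c(0, z, z, 0),
       osc_amp = c(3, 4, 3), osc_period = c(80, 80, 80),
       noise_sd = c(3, 3, 3),
       drift_start = NA_real_, drift_end = NA_real_)
}

d_geometry <- function() {
  z0 <- runif(1, 150, 250)
  e <- runif(1, -0.5, -0.05)      # descending bottom envelope
  t_b <- runif(1, 500, 900)
  t_b <- min(t_b, (535 - z0) / abs(e))
  z_end <- z0 + abs(e) * t_b
  t1 <- z0 / 1.1
  list(vertices_t = c(0, t1, t1 + t_b, t1 + t_b + z_end / 0.9),
       vertices_z = c(0, z0, z_end, 0),
       osc_amp = c(3, 25, 3), osc_period = c(80, 160, 80),
       noise_sd = c(3, 3, 3),
       drift_start = NA_real_, drift_end = NA_real_)
}

# Sample a geometry on the regular time grid, adding pinned oscillations.
sample_dive <- function(geom, interval, quant) {
  duration <- geom$vertices_t[length(geom$vertices_t)]
  t <- seq(0, duration, by = interval)
  depth <- approx(geom$vertices_t, geom$vertices_z, xout = t)$y
  n_seg <- length(geom$vertices_t) - 1
  for (i in seq_len(n_seg)) {
    t0 <- geom$vertices_t[i]; t1 <- geom$vertices_t[i + 1]
    L <- t1 - t0
    if (L <= 0) next
    idx <- which(t > t0 & t < t1)
    if (length(idx) == 0) next
    m <- max(1, round(2 * L / geom$osc_period[i]))
    amp <- geom$osc_amp[i] * runif(1, 0.85, 1.15) * sample(c(-1, 1), 1)
    # broadband stroking noise, faded out within 6 s of the segment ends
    # so the skeleton vertices stay recoverable by the broken stick
    interior <- pmin(t[idx] - t0, t1 - t[idx]) > 6
    depth[idx] <- depth[idx] + amp * sin(pi * m * (t[idx] - t0) / L) +
      rnorm(length(idx), 0, geom$noise_sd[i]) * interior
  }
  depth <- pmax(depth, 0)
  depth[c(1, length(depth))] <- 0
  if (quant > 0) depth <- round(depth / quant) * quant
  list(t = t, depth = depth, duration = duration)
}

# ---------------------------------------------------------------------------

#' Simulate a synthetic deployment
#'
#' Generates a multi-month high-resolution dive record for one individual
#' in which drift dives carry a passive drift phase whose rate follows
#' `trajectory` plus per-dive Gaussian noise, alongside V-, U- and D-type
#' confounder dives. The ground-truth label table records, for every
#' drift dive, the planted rate and phase, and whether the phase is
#' `detectable`: i.e. it satisfies all seven selection criteria of the
#' step-wise filter by construction (with guard margins so that depth
#' quantization cannot flip the decision).
#'
#' Drift-dive start times follow a diel pattern: 60% fall in the
#' early-morning local-time window of `config$diel_peak_window`, the rest
#' are uniform over the day. All other dives start uniformly. Dives are
#' scheduled sequentially with exponential surface intervals (mean 2 min)
#' so records never overlap.
#'
#' @param config A [sim_config()].
#' @param trajectory A [buoyancy_trajectory()].
#' @return An object of class `dive_simulation`: a list with tibbles
#'   `samples` (individual_id, dive_id, time_utc, depth_m),
#'   `dives` (dive_id, individual_id, dive_type, day, start_utc,
#'   duration_s, lon) and `labels` (dive_id, dive_type, true_drift_rate,
#'   drift_start_s, drift_end_s, detectable), plus the `config` and
#'   `trajectory` used.
#' @examples
#' sim <- simulate_deployment(sim_config(n_days = 2, seed = 1),
#'                            buoyancy_trajectory())
#' head(sim$labels)
#' @export
simulate_deployment <- function(config, trajectory) {
  stopifnot(inherits(config, "sim_config"),
            inherits(trajectory, "buoyancy_trajectory"))
  with_seed(config$seed, simulate_deployment_impl(config, trajectory))
}

simulate_deployment_impl <- function(config, trajectory) {
  n_dive <- config$n_days * config$dives_per_day
  day <- rep(seq_len(config$n_days) - 1L, each = config$dives_per_day)
  type <- sample(names(config$type_mix), n_dive, replace = TRUE,
                 prob = config$type_mix)
  lon <- config$longitude_track(day)
  if (length(lon) == 1) lon <- rep(lon, n_dive)

  # start offsets within the day (hours): diel mixture for drift dives
  off_h <- runif(n_dive, 0, 24)
  is_drift <- type == "drift"
  peaked <- is_drift & runif(n_dive) < 0.6
  lo <- config$diel_peak_window[1]; hi <- config$diel_peak_window[2]
  lt_h <- runif(sum(peaked), lo, hi)
  off_h[peaked] <- (lt_h - lon[peaked] / 15) %% 24

  v_real <- rep(NA_real_, n_dive)
  v_real[is_drift] <- trajectory_value(trajectory, day[is_drift] +
                                         off_h[is_drift] / 24) +
    rnorm(sum(is_drift), 0, config$drift_noise_sd)

  # geometry + samples per dive (drawn in dive order for determinism)
  ord <- order(day, off_h)
  geoms <- vector("list", n_dive)
  sampled <- vector("list", n_dive)
  for (k in ord) {
    geoms[[k]] <- switch(type[k],
                         drift = drift_geometry(v_real[k]),
                         V = v_geometry(),
                         U = u_geometry(),
                         D = d_geometry())
    sampled[[k]] <- sample_dive(geoms[[k]], config$sample_interval,
                                config$depth_quantization)
  }
  duration <- vapply(sampled, function(s) s$duration, numeric(1))

  # sequential scheduling: nominal start, pushed past the previous dive
  nominal <- as.numeric(config$start_date) + day * 86400 + off_h * 3600
  start_s <- numeric(n_dive)
  prev_end <- -Inf
  surf <- rexp(n_dive, rate = 1 / 120)
  for (j in seq_along(ord)) {
    k <- ord[j]
    start_s[k] <- max(nominal[k], prev_end + surf[j])
    prev_end <- start_s[k] + duration[k]
  }

  dive_id <- character(n_dive)
  dive_id[ord] <- sprintf("%s_d%05d", config$individual_id, seq_along(ord))

  start_utc <- as.POSIXct(start_s, origin = "1970-01-01", tz = "UTC")

  dives <- tibble(
    dive_id = dive_id, individual_id = config$individual_id,
    dive_type = type, day = day, start_utc = start_utc,
    duration_s = duration, lon = lon)[order(start_s), ]

  # labels with by-construction detectability
  drift_start <- vapply(geoms, function(g) g$drift_start, numeric(1))
  drift_end <- vapply(geoms, function(g) g$drift_end, numeric(1))
  detectable <- rep(FALSE, n_dive)
  if (any(is_drift)) {
    i <- which(is_drift)
    z0 <- vapply(geoms[i], function(g) g$vertices_z[2], numeric(1))
    z1 <- vapply(geoms[i], function(g) g$vertices_z[3], numeric(1))
    t_d <- drift_end[i] - drift_start[i]
    pct <- 100 * t_d / duration[i]
    frag_lt <- ((start_s[i] + drift_start[i]) / 3600 + lon[i] / 15) %% 24
    g <- DETECT_GUARD
    in_excl <- frag_lt >= (13.5 - g$lt_min / 60) & frag_lt < (19.5 + g$lt_min / 60)
    detectable[i] <-
      v_real[i] <= (-0.05 - g$speed) & v_real[i] >= (-0.6 + g$speed) &
      z0 >= (100 + g$depth) & z0 <= (550 - g$depth) &
      z1 >= (100 + g$depth) & z1 <= (550 - g$depth) &
      t_d > (480 + g$duration) &
      pct >= (40 + g$pct) &
      !in_excl
  }
  labels <- tibble(
    dive_id = dive_id, dive_type = type,
    true_drift_rate = v_real,
    drift_start_s = drift_start, drift_end_s = drift_end,
    detectable = detectable)[order(start_s), ]

  n_samp <- vapply(sampled, function(s) length(s$t), integer(1))
  samples <- tibble(
    individual_id = config$individual_id,
    dive_id = rep(dive_id, n_samp),
    time_utc = as.POSIXct(rep(start_s, n_samp) +
                            unlist(lapply(sampled, `[[`, "t")),
                          origin = "1970-01-01", tz = "UTC"),
    depth_m = unlist(lapply(sampled, `[[`, "depth")))
  samples <- samples[order(samples$time_utc), ]

  structure(list(samples = samples, dives = dives, labels = labels,
                 config = config, trajectory = trajectory),
            class = "dive_simulation")
}

#' @export
print.dive_simulation <- function(x, ...) {
  cat(sprintf("<dive_simulation> %d dives (%d drift, %d detectable), %d samples\n",
              nrow(x$dives), sum(x$labels$dive_type == "drift"),
              sum(x$labels$detectable), nrow(x$samples)))
  invisible(x)
}

#' Simulate a fragment-length / speed-noise mixture
#'
#' Generates candidate dive fragments whose vertical-speed noise depends
#' on fragment length: fragments shorter than `break_min` minutes carry
#' large noise (`sd_short`) around the buoyancy trajectory, longer ones
#' small noise (`sd_long`). This is the construction used to exercise the
#' statistics-based minimum-fragment-length procedure: the goodness of
#' fit of a smoothing spline to the speed time series improves sharply
#' once short, noisy fragments are excluded, so the procedure should
#' recover `break_min`.
#'
#' @param n_individuals Number of synthetic individuals. Default 5.
#' @param n_per_individual Fragments per individual. Default 300.
#' @param break_min Length (minutes) below which fragments are noisy.
#'   Default 8.
#' @param sd_short,sd_long Speed noise sd (m s^-1) for short / long
#'   fragments. Defaults 0.3 and 0.02.
#' @param n_days Span of fragment times in days. Default 200.
#' @param trajectory A [buoyancy_trajectory()] giving the underlying
#'   speed trend.
#' @param seed Optional integer seed.
#' @return Tibble with columns individual_id, time_days, duration_s,
#'   vspeed_ms.
#' @export
simulate_fragment_mixture <- function(n_individuals = 5,
                                      n_per_individual = 300,
                                      break_min = 8,
                                      sd_short = 0.3, sd_long = 0.02,
                                      n_days = 200,
                                      trajectory = buoyancy_trajectory(),
                                      seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_individuals), function(i) {
      dur <- runif(n_per_individual, 60, 900)
      t <- sort(runif(n_per_individual, 0, n_days))
      noise_sd <- ifelse(dur <= break_min * 60, sd_short, sd_long)
      tibble(
        individual_id = sprintf("ind%02d", i),
        time_days = t,
        duration_s = dur,
        vspeed_ms = trajectory_value(trajectory, t) +
          rnorm(n_per_individual, 0, noise_sd))
    })
  })
}
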