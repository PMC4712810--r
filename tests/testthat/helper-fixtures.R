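# Fixture builders and a lazy cache for the expensive simulations, so
# several test files can share one deployment without re-generating it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small deployment reused by several behavioural tests.
small_sim <- function() {
  cached("small_sim", simulate_deployment(
    sim_config(n_days = 6, dives_per_day = 30, seed = 421),
    buoyancy_trajectory()))
}

# The full-scale deployment used by the recovery experiments.
recovery_sim <- function() {
  cached("recovery_sim", simulate_deployment(
    sim_config(seed = 101), buoyancy_trajectory()))
}

recovery_filtered <- function() {
  cached("recovery_filtered", {
    sim <- recovery_sim()
    profiles <- prepare_dives(abstract_dives(sim$samples, sim$dives))
    apply_filters(fragment_dives(profiles))
  })
}

# One-row abstracted profile; defaults give a well-formed drift-like dive.
make_profile <- function(dive_id = "d1",
                         start_utc = as.POSIXct("2009-02-01 05:00:00",
                                                tz = "UTC"),
                         duration_s = 1500,
                         depths = c(250, 420, 390, 140),
                         times = c(250, 950, 1030, 1380),
                         lon = 0) {
  tibble::tibble(individual_id = "ind1", dive_id = dive_id,
                 start_utc = start_utc, duration_s = duration_s,
                 d1_m = depths[1], d2_m = depths[2], d3_m = depths[3],
                 d4_m = depths[4],
                 t1_s = times[1], t2_s = times[2], t3_s = times[3],
                 t4_s = times[4], lon = lon, lat = NA_real_)
}

# A single candidate fragment that passes all seven criteria by default;
# individual fields can be overridden to break exactly one criterion.
make_fragment <- function(id = "f1", vspeed = -0.3, depth_start = 150,
                          depth_end = 380, duration = 600, pct = 50,
                          next_speed = 0.5, prev_speed = -1.0,
                          lt_hours = 5.5, candidate = TRUE,
                          fragment_index = 2L) {
  tibble::tibble(
    individual_id = "ind1", dive_id = id,
    fragment_index = fragment_index,
    t_start_s = 250, t_end_s = 250 + duration,
    depth_start_m = depth_start, depth_end_m = depth_end,
    vspeed_ms = vspeed, duration_s = duration, pct_duration = pct,
    start_utc = as.POSIXct("2009-02-01 05:30:00", tz = "UTC"),
    lt_hours = lt_hours, prev_speed_ms = prev_speed,
    next_speed_ms = next_speed, candidate = candidate)
}

# Eight fragments: one violating each criterion, plus one compliant.
eight_fragment_fixture <- function() {
  dplyr::bind_rows(
    make_fragment("ok"),
    make_fragment("bad_speed", vspeed = -0.7),
    make_fragment("bad_depth", depth_start = 90),
    make_fragment("bad_length", duration = 400),
    make_fragment("bad_pct", pct = 30),
    make_fragment("bad_next", next_speed = 0.1),
    make_fragment("bad_time", lt_hours = 14.0),
    make_fragment("bad_prev", prev_speed = -0.4))
}

# Random fragment table for order-invariance checks: fields drawn wide
# enough that each criterion bites on a nontrivial subset.
random_fragments <- function(n = 40) {
  tibble::tibble(
    individual_id = "ind1",
    dive_id = sprintf("d%03d", seq_len(n)),
    fragment_index = sample(2:4, n, replace = TRUE),
    t_start_s = runif(n, 100, 400),
    t_end_s = NA_real_,
    depth_start_m = runif(n, 50, 600),
    depth_end_m = runif(n, 50, 600),
    vspeed_ms = runif(n, -0.9, 0.3),
    duration_s = runif(n, 200, 1000),
    pct_duration = runif(n, 10, 80),
    start_utc = as.POSIXct("2009-02-01", tz = "UTC") + runif(n, 0, 86400),
    lt_hours = runif(n, 0, 24),
    prev_speed_ms = runif(n, -1.5, 0.2),
    next_speed_ms = runif(n, -0.5, 1.2),
    candidate = runif(n) < 0.9) |>
    dplyr::mutate(t_end_s = t_start_s + duration_s)
}

# Piecewise-linear dive sampled on a regular grid.
piecewise_dive <- function(vertices_t, vertices_z, by = 2) {
  t <- seq(0, max(vertices_t), by = by)
  list(t = t, z = approx(vertices_t, vertices_z, xout = t)$y)
}

# Independent brute-force broken-stick oracle: recomputes every
# interpolation residual with plain loops at each iteration.
oracle_broken_stick <- function(times, depths, n_points = 4) {
  sel <- c(1, length(times))
  picks <- integer(0)
  for (k in seq_len(n_points)) {
    best_i <- NA_integer_
    best_r <- -Inf
    for (i in seq_along(times)) {
      if (i %in% sel) next
      ss <- sort(sel)
      j <- max(which(times[ss] <= times[i]))
      t0 <- times[ss[j]]; t1 <- times[ss[j + 1]]
      z0 <- depths[ss[j]]; z1 <- depths[ss[j + 1]]
      fit <- z0 + (z1 - z0) * (times[i] - t0) / (t1 - t0)
      r <- abs(depths[i] - fit)
      if (r > best_r + 1e-12) { best_r <- r; best_i <- i }
    }
    picks <- c(picks, best_i)
    sel <- c(sel, best_i)
  }
  picks
}
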