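cfg <- filter_config()

test_that("criterion boundaries follow the stated conventions", {
  # speed band inclusive on both sides
  f <- function(v) criterion_speed(make_fragment(vspeed = v), cfg)
  expect_true(f(-0.17)); expect_true(f(-0.05)); expect_true(f(-0.6))
  expect_false(f(-0.04)); expect_false(f(-0.7))
  # depth band inclusive, both endpoints of the fragment
  g <- function(a, b) criterion_depth(make_fragment(depth_start = a,
                                                    depth_end = b), cfg)
  expect_true(g(150, 380)); expect_true(g(100, 550))
  expect_false(g(90, 200)); expect_false(g(400, 560))
  # length strictly greater than 8 min
  h <- function(d) criterion_length(make_fragment(duration = d), cfg)
  expect_true(h(811.8)); expect_false(h(480)); expect_false(h(300))
  # percentage of dive duration: equality retained
  expect_true(criterion_pct(make_fragment(pct = 51.6), cfg))
  expect_true(criterion_pct(make_fragment(pct = 40), cfg))
  expect_false(criterion_pct(make_fragment(pct = 39.9), cfg))
  # following fragment must ascend at >= 0.2; missing neighbour fails
  expect_true(criterion_next_ascent(make_fragment(next_speed = 0.5), cfg))
  expect_false(criterion_next_ascent(make_fragment(next_speed = 0.1), cfg))
  expect_false(criterion_next_ascent(make_fragment(next_speed = -0.3), cfg))
  expect_false(criterion_next_ascent(make_fragment(next_speed = NA), cfg))
  # preceding fragment must descend at <= -0.6 (inclusive)
  expect_true(criterion_prev_descent(make_fragment(prev_speed = -1.0), cfg))
  expect_true(criterion_prev_descent(make_fragment(prev_speed = -0.6), cfg))
  expect_false(criterion_prev_descent(make_fragment(prev_speed = -0.4), cfg))
  # local-time window half-open [13:30, 19:30)
  expect_true(criterion_time(make_fragment(lt_hours = 5.5), cfg))
  expect_false(criterion_time(make_fragment(lt_hours = 14.0), cfg))
  expect_true(criterion_time(make_fragment(lt_hours = 19.5), cfg))
  expect_false(criterion_time(make_fragment(lt_hours = 13.5), cfg))
})

test_that("a wrapped local-time window excludes across midnight", {
  c2 <- filter_config(lt_excl_start = 22, lt_excl_end = 2)
  expect_false(criterion_time(make_fragment(lt_hours = 23), c2))
  expect_false(criterion_time(make_fragment(lt_hours = 1), c2))
  expect_true(criterion_time(make_fragment(lt_hours = 12), c2))
})

test_that("one compliant fragment among seven single-criterion violators survives", {
  fx <- eight_fragment_fixture()
  res <- apply_filters(fx)
  expect_equal(res$drift$dive_id, "ok")
  expect_true(all(res$report$single$retained == 7))
  expect_true(all(diff(res$report$stepwise$retained) <= 0))
  # the time violator is removed at the diel step
  step_time <- which(res$report$stepwise$criterion == "time")
  before <- c(8, res$report$stepwise$retained)[step_time]
  expect_lt(res$report$stepwise$retained[step_time], before)
})

test_that("the final drift set is invariant to the criterion order", {
  set.seed(55)
  all_crit <- c("speed", "depth", "length", "pct", "next_ascent", "time",
                "prev_descent")
  for (fix in 1:20) {
    fx <- random_fragments(40)
    ref <- sort(apply_filters(fx, cfg, all_crit)$report$final_ids)
    for (p in 1:8) {
      perm <- sample(all_crit)
      expect_identical(sort(apply_filters(fx, cfg, perm)$report$final_ids),
                       ref)
    }
  }
})

test_that("retained drift rates always lie in the speed band", {
  set.seed(66)
  for (fix in 1:10) {
    res <- apply_filters(random_fragments(60), cfg)
    if (nrow(res$drift) > 0) {
      expect_true(all(res$drift$vspeed_ms >= cfg$speed_min &
                        res$drift$vspeed_ms <= cfg$speed_max))
    }
  }
})

test_that("non-candidates are never retained and misconfiguration errors", {
  fx <- dplyr::bind_rows(make_fragment("a"),
                         make_fragment("b", candidate = FALSE))
  res <- apply_filters(fx)
  expect_equal(res$drift$dive_id, "a")
  expect_equal(res$report$n_candidates, 1)
  expect_error(apply_filters(fx, order = c("speed", "banana")), "banana")
  expect_error(apply_filters(fx, order = c("speed", "speed")), "repeat")
  expect_error(filter_config(speed_max = 0.1), "allow_positive")
})

test_that("drift series extraction orders, names and filters correctly", {
  expect_equal(nrow(extract_drift_series(make_fragment()[0, ])), 0)
  fx <- dplyr::bind_rows(make_fragment("b"), make_fragment("a"))
  fx$start_utc <- as.POSIXct(c("2009-02-02", "2009-02-01"), tz = "UTC")
  ser <- extract_drift_series(fx)
  expect_equal(ser$dive_id, c("a", "b"))
  expect_named(ser, c("individual_id", "time_utc", "drift_rate_ms", "dive_id"))
})

test_that("filtering a zero-noise constant-buoyancy deployment recovers the rate", {
  cfg_sim <- sim_config(n_days = 2, dives_per_day = 10,
                        type_mix = c(drift = 1, V = 0, U = 0, D = 0),
                        drift_noise_sd = 0, depth_quantization = 0,
                        seed = 17)
  sim <- simulate_deployment(cfg_sim, buoyancy_trajectory(v0 = -0.2, v1 = -0.2))
  res <- apply_filters(fragment_dives(prepare_dives(
    abstract_dives(sim$samples, sim$dives))))
  ser <- extract_drift_series(res)
  expect_gt(nrow(ser), 0)
  expect_true(all(abs(ser$drift_rate_ms - (-0.2)) <= 0.02))
  # construction soundness: each detectable dive yields exactly one fragment
  det <- sim$labels$dive_id[sim$labels$detectable]
  counts <- table(res$drift$dive_id)
  expect_true(all(det %in% names(counts)))
  expect_true(all(counts[det] == 1))
})

test_that("tidy and glance expose the report tables", {
  res <- apply_filters(eight_fragment_fixture())
  expect_named(tidy(res), c("criterion", "retained", "pct_of_candidates",
                            "pct_of_all"))
  expect_equal(glance(res)$n_drift, 1)
})
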