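test_that("logistic trajectory has the midpoint, asymptote and monotonicity properties", {
  traj <- buoyancy_trajectory(v0 = -0.35, v1 = -0.02, t_mid = 75, scale = 15)
  expect_equal(trajectory_value(traj, 75), (-0.35 - 0.02) / 2)  # -0.185
  expect_equal(trajectory_value(traj, 1e7), -0.02, tolerance = 1e-9)
  tt <- seq(0, 300, by = 0.5)
  expect_true(all(diff(trajectory_value(traj, tt)) >= 0))
  # near departure the value is close to v0 (exactly v0 only at t -> -Inf)
  expect_lt(abs(trajectory_value(traj, 0) - (-0.35)), 3e-3)
  expect_error(buoyancy_trajectory(scale = 0), "scale")
  expect_error(trajectory_value(traj, -1), "non-negative")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_days = 2, dives_per_day = 15, seed = 42)
  s1 <- simulate_deployment(cfg, buoyancy_trajectory())
  s2 <- simulate_deployment(cfg, buoyancy_trajectory())
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$dives, s2$dives)
})

test_that("invalid type mixes are rejected", {
  expect_error(sim_config(type_mix = c(drift = 0.5, V = 0.2, U = 0.2, D = 0.2)),
               "sum to 1")
  expect_error(sim_config(type_mix = c(a = 1)), "named")
})

test_that("zero-noise constant trajectory plants drift phases at exactly that rate", {
  cfg <- sim_config(n_days = 2, dives_per_day = 10,
                    type_mix = c(drift = 1, V = 0, U = 0, D = 0),
                    drift_noise_sd = 0, depth_quantization = 0, seed = 7)
  traj <- buoyancy_trajectory(v0 = -0.2, v1 = -0.2)
  sim <- simulate_deployment(cfg, traj)
  expect_true(all(sim$labels$dive_type == "drift"))
  expect_true(all(sim$labels$true_drift_rate == -0.2))
  # the planted phase in the sampled record has exactly that slope at
  # its endpoints (the drift vertices carry no oscillation or noise)
  lab <- sim$labels[1, ]
  s <- sim$samples[sim$samples$dive_id == lab$dive_id, ]
  t_rel <- as.numeric(s$time_utc) - min(as.numeric(s$time_utc))
  inside <- which(t_rel >= lab$drift_start_s & t_rel <= lab$drift_end_s)
  i0 <- inside[1]; i1 <- inside[length(inside)]
  slope <- (s$depth_m[i0] - s$depth_m[i1]) / (t_rel[i1] - t_rel[i0])
  expect_lt(abs(slope - (-0.2)), 1e-3)
})

test_that("realised drift rates track the trajectory over the early trip", {
  cfg <- sim_config(n_days = 12, dives_per_day = 20,
                    type_mix = c(drift = 0.25, V = 0.25, U = 0.35, D = 0.15),
                    seed = 99)
  traj <- buoyancy_trajectory(v0 = -0.35, v1 = -0.02, t_mid = 50, scale = 10)
  sim <- simulate_deployment(cfg, traj)
  lab <- sim$labels[sim$labels$dive_type == "drift", ]
  meta <- sim$dives[match(lab$dive_id, sim$dives$dive_id), ]
  early <- meta$day <= 10
  expect_gt(sum(early), 20)
  # oracle: average the trajectory function at the dive times
  expected <- mean(trajectory_value(traj, meta$day[early]))
  se <- cfg$drift_noise_sd / sqrt(sum(early))
  expect_lt(abs(mean(lab$true_drift_rate[early]) - expected), 2 * se + 1e-3)
  expect_lt(abs(expected - (-0.35)), 0.01)
})

test_that("every dive starts and ends at the surface and labels are coherent", {
  sim <- small_sim()
  ends <- sim$samples |>
    dplyr::group_by(dive_id) |>
    dplyr::summarise(first = dplyr::first(depth_m),
                     last = dplyr::last(depth_m), .groups = "drop")
  expect_true(all(ends$first == 0 & ends$last == 0))
  lab <- sim$labels
  expect_true(all(is.na(lab$true_drift_rate) | lab$dive_type == "drift"))
  drift <- lab[lab$dive_type == "drift", ]
  expect_true(all(drift$drift_start_s < drift$drift_end_s))
  expect_true(all(!lab$detectable | lab$dive_type == "drift"))
})

test_that("fragment mixture generator separates noise regimes at the break", {
  mix <- simulate_fragment_mixture(n_individuals = 2, n_per_individual = 150,
                                   seed = 5)
  expect_setequal(unique(mix$individual_id), c("ind01", "ind02"))
  traj <- buoyancy_trajectory()
  resid <- mix$vspeed_ms - trajectory_value(traj, mix$time_days)
  expect_gt(sd(resid[mix$duration_s <= 480]), 5 * sd(resid[mix$duration_s > 480]))
})
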