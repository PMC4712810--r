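test_that("a perfect V-dive is recovered from its apex alone", {
  d <- piecewise_dive(c(0, 300, 600), c(0, 240, 0))
  bs <- abstract_dive(d$t, d$z)
  apex <- which.min(abs(d$t - 300))
  expect_equal(bs$selection_order[1], apex)
  expect_equal(bs$residual_path[1], 0, tolerance = 1e-9)
  expect_equal(bs$max_residual, 0, tolerance = 1e-9)
})

test_that("piecewise-linear dives with <= 4 interior breakpoints are exact", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    # vertices on the sample grid so the dive is exactly representable;
    # random depths make every breakpoint a genuine slope change a.s.
    vt <- c(0, sort(sample(seq(50, 950, by = 50), k)), 1000)
    vz <- c(0, runif(k, 50, 500), 0)
    d <- piecewise_dive(vt, vz, by = 1)
    bs <- abstract_dive(d$t, d$z)
    expect_lt(bs$max_residual, 1e-9)
    expect_true(all(vt[-c(1, k + 2)] %in% bs$inflection_times))
  }
})

test_that("selection matches the brute-force max-residual oracle", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(12:20, 1)
    t <- seq(0, (n - 1) * 10, by = 10)
    z <- c(0, runif(n - 2, 5, 300), 0)
    bs <- abstract_dive(t, z)
    expect_identical(bs$selection_order, as.integer(oracle_broken_stick(t, z)))
  }
})

test_that("refinement is monotone while structure dominates the residual", {
  # while the picks capture real dive structure the max residual can
  # only fall; once it reaches the stroking-noise floor a chord split
  # can raise it elsewhere on the chord (bounded by twice the floor),
  # so strict monotonicity is checked on noise-free profiles
  sim <- cached("clean_sim", simulate_deployment(
    sim_config(n_days = 2, dives_per_day = 15, depth_quantization = 0,
               seed = 77,
               type_mix = c(drift = 0.4, V = 0.2, U = 0.2, D = 0.2)),
    buoyancy_trajectory()))
  noise_floor <- 25 + 3  # largest oscillation amplitude + stroking sd (m)
  for (id in unique(sim$samples$dive_id)) {
    s <- sim$samples[sim$samples$dive_id == id, ]
    t <- as.numeric(s$time_utc) - min(as.numeric(s$time_utc))
    bs <- abstract_dive(t, s$depth_m, n_points = 6)
    path <- c(Inf, bs$residual_path)
    structural <- utils::head(path, -1) > 3 * noise_floor
    expect_true(all(diff(path)[structural] <= 1e-9))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(abstract_dive(c(0, 10, 20), c(0, 5, 0)), "samples")
  expect_error(abstract_dive(0:10 * 10, c(5, runif(9, 10, 50), 0)),
               "surface")
  expect_error(abstract_dive(c(0, 10, 10, 20, 30, 40),
                             c(0, 5, 6, 7, 8, 0)), "increasing")
})

test_that("reconstruction interpolates through the inflection points", {
  p <- make_profile(depths = c(200, 230, 210, 100),
                    times = c(100, 160, 400, 900),
                    duration_s = 1200)
  expect_equal(reconstruct(p, c(100, 160, 400, 900)), c(200, 230, 210, 100))
  expect_equal(reconstruct(p, c(0, 1200)), c(0, 0))
  expect_equal(reconstruct(p, 130), 215)  # linear midpoint of 200 -> 230
  expect_error(reconstruct(p, 1300), "within")
})

test_that("abstracting a whole deployment keeps one row per dive with metadata", {
  sim <- small_sim()
  prof <- abstract_dives(sim$samples, sim$dives)
  expect_equal(nrow(prof), nrow(sim$dives))
  expect_true(all(!is.na(prof$lon)))
  expect_true(all(prof$t1_s > 0 & prof$t4_s < prof$duration_s))
  expect_true(all(prof$t1_s < prof$t2_s & prof$t2_s < prof$t3_s &
                    prof$t3_s < prof$t4_s))
})
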