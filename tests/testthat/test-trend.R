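test_that("data on an exact quadratic are reproduced by the median spline", {
  t <- seq(0, 20, length.out = 300)
  y <- -0.3 + 0.012 * t - 0.0004 * t^2
  fit <- fit_trend(tibble::tibble(t_days = t, drift_rate_ms = y), tau = 0.5)
  expect_lt(max(abs(predict(fit, t) - y)), 1e-6)
})

test_that("quantile coverage matches tau under symmetric noise", {
  set.seed(21)
  t <- seq(0, 100, length.out = 1000)
  y <- trajectory_value(buoyancy_trajectory(), t) + rnorm(1000, 0, 0.05)
  s <- tibble::tibble(t_days = t, drift_rate_ms = y)
  for (tau in c(0.2, 0.5)) {
    fit <- fit_trend(s, tau = tau)
    expect_lt(abs(mean(y < predict(fit, t)) - tau), 0.05)
  }
})

test_that("the fitted check loss beats the best constant", {
  set.seed(22)
  t <- seq(0, 50, length.out = 400)
  y <- trajectory_value(buoyancy_trajectory(), t) + rnorm(400, 0, 0.04)
  for (tau in c(0.2, 0.5, 0.8)) {
    fit <- fit_trend(tibble::tibble(t_days = t, drift_rate_ms = y), tau = tau)
    r <- y - quantile(y, tau, names = FALSE)
    loss_const <- sum(r * (tau - (r < 0)))
    expect_lte(fit$checkloss, loss_const + 1e-8)
  }
})

test_that("shifting all drift rates by a constant shifts the curve exactly", {
  set.seed(23)
  t <- seq(0, 60, length.out = 300)
  y <- -0.25 + 0.002 * t + rnorm(300, 0, 0.03)
  f1 <- fit_trend(tibble::tibble(t_days = t, drift_rate_ms = y), tau = 0.2)
  f2 <- fit_trend(tibble::tibble(t_days = t, drift_rate_ms = y + 0.37),
                  tau = 0.2)
  expect_equal(predict(f2, t), predict(f1, t) + 0.37, tolerance = 1e-8)
})

test_that("daily predictions cover exactly the fitted days, constants stay flat", {
  t0 <- as.POSIXct("2009-03-01 06:00:00", tz = "UTC")
  s <- tibble::tibble(time_utc = t0 + seq(0, 10 * 86400 - 1,
                                          length.out = 240),
                      drift_rate_ms = -0.2)
  s$drift_rate_ms <- s$drift_rate_ms + rep(c(-1e-6, 1e-6), 120)
  fit <- fit_trend(s, tau = 0.5)
  pd <- predict_daily(fit)
  expect_equal(nrow(pd), 10)
  expect_true(all(abs(pd$drift_rate_pred + 0.2) < 1e-4))
  expect_error(predict(fit, 20), "domain")
})

test_that("haul-out splitting follows the gap rule and optional flags", {
  t0 <- as.POSIXct("2009-03-01", tz = "UTC")
  mk <- function(offsets) tibble::tibble(time_utc = t0 + offsets * 86400,
                                         drift_rate_ms = -0.2)
  expect_equal(unique(split_on_haulout(mk(seq(0, 10, by = 0.5)))$segment), 1L)
  s2 <- split_on_haulout(mk(c(0:5, 26:30)))
  expect_equal(unique(s2$segment), c(1L, 2L))
  expect_equal(sum(s2$segment == 1), 6)
  # two 1-day gaps stay below the threshold
  expect_equal(unique(split_on_haulout(mk(c(0, 0.2, 1.3, 2.5)))$segment), 1L)
  # a flag can veto a long gap (e.g. transmission outage, not a haul-out)
  s3 <- mk(c(0:5, 26:30))
  flags <- rep(FALSE, nrow(s3) - 1)
  expect_equal(unique(split_on_haulout(s3, haulout_gaps = flags)$segment), 1L)
})

test_that("undersized or degenerate series are rejected", {
  expect_error(fit_trend(tibble::tibble(t_days = 1:5,
                                        drift_rate_ms = rnorm(5))),
               ">= 10")
  expect_error(fit_trend(tibble::tibble(t_days = rep(1, 20),
                                        drift_rate_ms = rnorm(20))),
               "span|degenerate")
})
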