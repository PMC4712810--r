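#' Daily mean drift rate
#'
#' Averages a drift-rate series per calendar day (solar local day if a
#' longitude is supplied, UTC day otherwise). Days without observations
#' are absent, not zero-filled.
#'
#' @param series Drift-rate series tibble with `time_utc` and
#'   `drift_rate_ms` (and optionally `individual_id`).
#' @param longitude Longitude used to convert to local days; default 0
#'   (UTC days).
#' @return Tibble with `individual_id` (if present), `date` (Date),
#'   `drift_rate_ms` (daily mean) and `n` (observations).
#' @export
daily_mean <- function(series, longitude = 0) {
  assert_columns(series, c("time_utc", "drift_rate_ms"), "`series`")
  if (nrow(series) == 0) {
    return(tibble(date = as.Date(character()), drift_rate_ms = numeric(),
                  n = integer()))
  }
  series$date <- as.Date(local_time(series$time_utc, longitude), tz = "UTC")
  keys <- intersect("individual_id", names(series))
  series %>%
    group_by(across(all_of(c(keys, "date")))) %>%
    summarise(drift_rate_ms = mean(.data$drift_rate_ms), n = n(),
              .groups = "drop") %>%
    arrange(across(all_of(c(keys, "date"))))
}

# ---------------------------------------------------------------------------
# KPSS level-stationarity test (Bartlett-kernel long-run variance, short
# lag truncation). Implemented here because no installed package
# provides it; used only to choose the ARIMA differencing order.
kpss_statistic <- function(x, lags = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("KPSS needs >= 8 observations.")
  e <- x - mean(x)
  s <- cumsum(e)
  if (is.null(lags)) lags <- trunc(3 * sqrt(n) / 13)
  lrv <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      lrv <- lrv + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  sum(s^2) / (n^2 * max(lrv, 1e-12))
}

# 5% critical value for the level test
KPSS_CRIT_05 <- 0.463

#' Automatic ARIMA specification for a daily drift-rate series
#'
#' Chooses the differencing order `d` by repeated KPSS level-stationarity
#' testing (difference until the test no longer rejects at 5%, at most
#' `max_d` times), then selects `(p, q)` up to `(max_p, max_q)` by
#' corrected AIC with maximum-likelihood coefficient estimates. Among
#' orders within 2 AICc units of the optimum the most parsimonious
#' (smallest `p + q`) is preferred, the usual guard against spurious
#' near-cancelling AR/MA pairs.
#'
#' Interior gaps of at most `interp_gap` days are filled by linear
#' interpolation; at a longer gap the series is cut and the longest
#' contiguous run is modelled (with a message).
#'
#' @param x Numeric vector of daily means, or a [daily_mean()] tibble.
#' @param max_p,max_q Order caps for the AR and MA parts. Default 5.
#' @param max_d Cap on differencing steps. Default 2.
#' @param interp_gap Longest interior gap (days) bridged by linear
#'   interpolation. Default 3.
#' @return An object of class `arima_spec`: orders `p`, `d`, `q`, the
#'   `ar`/`ma` coefficient vectors, `innovation_sd`, `aicc`, `n`.
#' @export
select_arima <- function(x, max_p = 5, max_q = 5, max_d = 2,
                         interp_gap = 3) {
  x <- regularise_daily(x, interp_gap)
  if (length(x) < 20) abort("need >= 20 daily values to select an ARIMA model.")

  d <- 0L
  z <- x
  while (d < max_d && kpss_statistic(z) > KPSS_CRIT_05) {
    z <- diff(z)
    d <- d + 1L
  }

  fits <- list()
  n <- length(x)
  for (p in 0:max_p) for (q in 0:max_q) {
    fit <- tryCatch(
      suppressWarnings(arima(x, order = c(p, d, q), method = "ML",
                             include.mean = (d == 0))),
      error = function(e) NULL)
    if (is.null(fit)) next
    k <- p + q + (d == 0) + 1          # + intercept (if any) + variance
    ne <- n - d
    if (ne - k - 1 <= 0) next
    aicc <- fit$aic + 2 * k * (k + 1) / (ne - k - 1)
    cf <- fit$coef
    fits[[length(fits) + 1]] <- list(
      p = p, d = d, q = q,
      ar = unname(cf[grep("^ar", names(cf))]),
      ma = unname(cf[grep("^ma", names(cf))]),
      innovation_sd = sqrt(fit$sigma2), aicc = aicc, n = n)
  }
  if (length(fits) == 0) abort("no ARIMA order converged for this series.")
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  near <- which(aiccs <= min(aiccs) + 2)
  sizes <- vapply(fits[near], function(f) f$p + f$q, numeric(1))
  near <- near[sizes == min(sizes)]
  best <- fits[[near[which.min(aiccs[near])]]]
  structure(best, class = "arima_spec")
}

# Accepts a daily_mean() tibble or plain numeric; interpolates short
# gaps, keeps the longest run when longer gaps occur.
regularise_daily <- function(x, interp_gap = 3) {
  if (is.numeric(x)) return(as.numeric(x))
  assert_columns(x, c("date", "drift_rate_ms"), "`x`")
  x <- arrange(x, .data$date)
  days <- as.integer(x$date - x$date[1])
  gaps <- diff(days)
  run_id <- cumsum(c(1L, as.integer(gaps > interp_gap)))
  runs <- split(seq_len(nrow(x)), run_id)
  if (length(runs) > 1) {
    inform(sprintf(
      "series has %d gap(s) longer than %d days; modelling the longest contiguous run.",
      length(runs) - 1, interp_gap))
  }
  i <- runs[[which.max(vapply(runs, length, integer(1)))]]
  full <- seq(days[i[1]], days[i[length(i)]])
  approx(days[i], x$drift_rate_ms[i], xout = full)$y
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("<arima_spec> ARIMA(%d,%d,%d), sigma = %.4f, AICc = %.2f, n = %d\n",
              x$p, x$d, x$q, x$innovation_sd, x$aicc, x$n))
  invisible(x)
}

#' @export
tidy.arima_spec <- function(x, ...) {
  bind_rows(
    if (x$p > 0) tibble(term = paste0("ar", seq_len(x$p)), estimate = x$ar),
    if (x$q > 0) tibble(term = paste0("ma", seq_len(x$q)), estimate = x$ma))
}

#' @export
glance.arima_spec <- function(x, ...) {
  tibble(p = x$p, d = x$d, q = x$q, innovation_sd = x$innovation_sd,
         aicc = x$aicc, n = x$n)
}

#' d-fold first differencing
#'
#' @param x Numeric series.
#' @param d Number of differencing steps (>= 0).
#' @return The differenced series (length `length(x) - d`).
#' @export
difference_to_stationary <- function(x, d) {
  if (d < 0) abort("`d` must be >= 0.")
  if (length(x) < d + 2) abort("series too short for d differencing steps.")
  if (d == 0) return(x)
  diff(x, differences = d)
}

#' Pearson correlation of two day-matched series
#'
#' For numeric inputs the vectors are paired by index; for
#' [daily_mean()] tibbles they are matched on `date` (only overlapping
#' days are used).
#'
#' @param a,b Numeric vectors or daily tibbles with `date` and
#'   `drift_rate_ms`.
#' @return List with `r` (Pearson coefficient) and `n` (pairs used).
#' @export
correlate_pair <- function(a, b) {
  if (is.data.frame(a) || is.data.frame(b)) {
    assert_columns(a, c("date", "drift_rate_ms"), "`a`")
    assert_columns(b, c("date", "drift_rate_ms"), "`b`")
    m <- dplyr::inner_join(a[, c("date", "drift_rate_ms")],
                           b[, c("date", "drift_rate_ms")],
                           by = "date", suffix = c("_a", "_b"))
    a <- m$drift_rate_ms_a; b <- m$drift_rate_ms_b
  } else {
    if (length(a) != length(b)) abort("numeric series must have equal length.")
  }
  if (length(a) < 3) abort("need >= 3 overlapping observations.")
  if (sd(a) == 0 || sd(b) == 0) abort("zero variance; correlation undefined.")
  list(r = cor(a, b), n = length(a))
}

# Simulate one series from an arima_spec (ARMA innovations, then d-fold
# integration), length n after integration.
simulate_arima <- function(spec, n) {
  model <- list()
  if (spec$p > 0) model$ar <- spec$ar
  if (spec$q > 0) model$ma <- spec$ma
  z <- as.numeric(arima.sim(model, n = n, sd = spec$innovation_sd))
  if (spec$d > 0) for (i in seq_len(spec$d)) z <- cumsum(z)
  z
}

#' Empirical null distribution for a cross-series correlation
#'
#' Simulates `N` independent pairs of series from the two fitted ARIMA
#' specifications, differences each by its own `d`, and correlates them,
#' yielding the distribution of correlation coefficients expected from
#' autocorrelation alone. The empirical p-value of the observed
#' coefficient is `(1 + #{null >= r_observed}) / (N + 1)` (upper tail:
#' the working hypothesis is positive correlation between the two
#' detection methods; `alternative = "two.sided"` doubles the smaller
#' tail).
#'
#' @param spec_a,spec_b [select_arima()] specifications of the two
#'   observed series.
#' @param r_observed Observed Pearson coefficient on the differenced
#'   pair.
#' @param n_days Length of the simulated series (the observed overlap).
#' @param N Number of simulated pairs. Default 1000.
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `null_correlation`: `r_observed`,
#'   `null_r` (length `N`), `p_value`, `n_overlap`.
#' @export
null_correlation <- function(spec_a, spec_b, r_observed, n_days,
                             N = 1000, seed = NULL,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(spec_a, "arima_spec"), inherits(spec_b, "arima_spec"))
  for (s in list(spec_a, spec_b)) {
    if (s$p > 0 && min(Mod(polyroot(c(1, -s$ar)))) <= 1) {
      abort("non-stationary AR part; cannot simulate a stable null.")
    }
  }
  null_r <- with_seed(seed, vapply(seq_len(N), function(i) {
    za <- difference_to_stationary(simulate_arima(spec_a, n_days), spec_a$d)
    zb <- difference_to_stationary(simulate_arima(spec_b, n_days), spec_b$d)
    k <- min(length(za), length(zb))
    cor(za[seq(to = length(za), length.out = k)],
        zb[seq(to = length(zb), length.out = k)])
  }, numeric(1)))
  p_upper <- (1 + sum(null_r >= r_observed)) / (N + 1)
  p <- if (alternative == "greater") p_upper else {
    p_lower <- (1 + sum(null_r <= r_observed)) / (N + 1)
    min(1, 2 * min(p_upper, p_lower))
  }
  structure(list(r_observed = r_observed, null_r = null_r, p_value = p,
                 n_overlap = n_days, N = N, alternative = alternative),
            class = "null_correlation")
}

#' @export
print.null_correlation <- function(x, ...) {
  cat(sprintf("<null_correlation> r = %.3f, empirical P = %.4g (%s, N = %d)\n",
              x$r_observed, x$p_value, x$alternative, x$N))
  invisible(x)
}

#' @export
glance.null_correlation <- function(x, ...) {
  tibble(r_observed = x$r_observed, p_value = x$p_value,
         n_overlap = x$n_overlap, N = x$N,
         null_mean = mean(x$null_r), null_sd = sd(x$null_r))
}

#' Two-sample comparison of drift-dive counts
#'
#' Pearson goodness-of-fit test of two counts against equal expectation
#' `e = (n1 + n2)/2`, no continuity correction:
#' `chi2 = (n1-e)^2/e + (n2-e)^2/e` with 1 degree of freedom.
#'
#' @param n1,n2 Non-negative counts (`n1 + n2 > 0`).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @examples
#' compare_drift_counts(56, 36)  # chi2 = 4.348, P = 0.037
#' @export
compare_drift_counts <- function(n1, n2) {
  if (n1 < 0 || n2 < 0 || (n1 + n2) == 0) {
    abort("counts must be non-negative and not both zero.")
  }
  e <- (n1 + n2) / 2
  stat <- (n1 - e)^2 / e + (n2 - e)^2 / e
  tibble(statistic = stat, df = 1,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Verify selected drift fragments against labels
#'
#' Per-dive matching of filter output against a ground-truth (or visual
#' classification) label table: a selected fragment is confirmed iff its
#' dive is labelled a drift dive. Reports the counts a verification
#' table shows: selected, confirmed, falsely selected, missed drift
#' dives, and the confirmation percentage.
#'
#' @param drift Retained drift fragments (tibble with `dive_id`), or an
#'   [apply_filters()] result.
#' @param labels Label table with `dive_id` and `dive_type` (`"drift"`
#'   marks true drift dives), e.g. the simulator's label table.
#' @return An object of class `verification_summary` with fields
#'   `n_selected`, `n_confirmed`, `n_false_positive`, `n_missed`,
#'   `confirmation_pct`, and `false_positive_types` (table of dive types
#'   among false positives).
#' @export
verify_against_labels <- function(drift, labels) {
  if (inherits(drift, "drift_filter_result")) drift <- drift$drift
  assert_columns(drift, "dive_id", "`drift`")
  assert_columns(labels, c("dive_id", "dive_type"), "`labels`")
  unknown <- setdiff(drift$dive_id, labels$dive_id)
  if (length(unknown) > 0) {
    abort(sprintf("fragments reference %d dive id(s) absent from `labels`.",
                  length(unknown)))
  }
  selected <- unique(drift$dive_id)
  drift_dives <- labels$dive_id[labels$dive_type == "drift"]
  confirmed <- intersect(selected, drift_dives)
  false_pos <- setdiff(selected, drift_dives)
  missed <- setdiff(drift_dives, selected)
  fp_types <- table(labels$dive_type[match(false_pos, labels$dive_id)])
  structure(list(
    n_selected = length(selected),
    n_confirmed = length(confirmed),
    n_false_positive = length(false_pos),
    n_missed = length(missed),
    confirmation_pct = if (length(selected) > 0)
      100 * length(confirmed) / length(selected) else NA_real_,
    false_positive_types = fp_types),
    class = "verification_summary")
}

#' @export
print.verification_summary <- function(x, ...) {
  cat(sprintf("<verification_summary> selected %d | confirmed %d (%.1f%%) | false + %d | missed %d\n",
              x$n_selected, x$n_confirmed, x$confirmation_pct,
              x$n_false_positive, x$n_missed))
  invisible(x)
}

#' @export
glance.verification_summary <- function(x, ...) {
  tibble(n_selected = x$n_selected, n_confirmed = x$n_confirmed,
         n_false_positive = x$n_false_positive, n_missed = x$n_missed,
         confirmation_pct = x$confirmation_pct)
}
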