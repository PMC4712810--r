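#' Fit a quantile B-spline trend to a drift-rate series
#'
#' Estimates the buoyancy trend underlying a drift-rate time series by
#' quantile regression on a B-spline basis: the coefficients minimise
#' the check loss `sum(rho_tau(y - s(t)))` with no shape constraint and
#' no roughness penalty. Knots are placed at equally spaced empirical
#' quantiles of the observation times, and the number of knots is chosen
#' from 3 up to `max_knots` by a Schwarz-type information criterion on
#' the check loss, which guards against over-fitting in the same spirit
#' as a hard knot cap.
#'
#' The default `tau = 0.2` fits the lower quintile of the drift rates:
#' drift fragments contaminated by residual swimming are biased towards
#' zero, so a low quantile tracks the cleaner, most-negative drift
#' observations. Set `tau = 0.5` for a median trend.
#'
#' @param series Drift-rate series: tibble with `drift_rate_ms` and a
#'   time axis, either `time_utc` (POSIXct) or `t_days` (numeric).
#' @param tau Regression quantile level in (0, 1). Default 0.2.
#' @param max_knots Maximum number of knots (including the two boundary
#'   knots). Default 14.
#' @param degree B-spline degree; 2 (quadratic, default) or 3.
#' @return An object of class `drift_trend` with, among others, the knot
#'   vector (days), the basis coefficients, the fitted check loss and
#'   the Schwarz criterion of the selected model. Supports [predict()],
#'   [predict_daily()], [tidy()], [glance()] and [autoplot()].
#' @examples
#' s <- tibble::tibble(t_days = seq(0, 20, by = 0.25))
#' s$drift_rate_ms <- -0.3 + 0.01 * s$t_days
#' fit <- fit_trend(s, tau = 0.5)
#' glance(fit)
#' @export
fit_trend <- function(series, tau = 0.2, max_knots = 14, degree = 2) {
  if (tau <= 0 || tau >= 1) abort("`tau` must be in (0, 1).")
  xt <- trend_time_axis(series)
  y <- series$drift_rate_ms
  ok <- is.finite(xt$t) & is.finite(y)
  t <- xt$t[ok]; y <- y[ok]
  if (length(t) < 10) abort("need >= 10 observations to fit a trend.")
  if (diff(range(t)) <= 0) abort("degenerate time span.")

  best <- NULL
  n <- length(t)
  for (k in 3:max_knots) {
    knots <- unique(quantile(t, probs = seq(0, 1, length.out = k),
                             names = FALSE, type = 7))
    if (length(knots) < 3) next
    interior <- knots[-c(1, length(knots))]
    B <- splines::bs(t, knots = interior, degree = degree,
                     intercept = TRUE, Boundary.knots = range(t))
    p <- ncol(B)
    if (n <= p + 1) break
    # degenerate designs can make the LP solution non-unique; any
    # optimum has the same check loss, so the warning is benign here
    fit <- tryCatch(suppressWarnings(
      quantreg::rq.fit(as.matrix(B), y, tau = tau)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- y - as.vector(as.matrix(B) %*% fit$coefficients)
    rho <- sum(r * (tau - (r < 0)))
    sic <- log(max(rho / n, 1e-300)) + p * log(n) / (2 * n)
    if (is.null(best) || sic < best$sic) {
      best <- list(k = k, interior = interior, boundary = range(t),
                   coefficients = fit$coefficients, rho = rho, sic = sic,
                   p = p)
    }
  }
  if (is.null(best)) abort("trend fit failed at every knot count.")
  structure(list(
    tau = tau, degree = degree,
    knots = c(best$boundary[1], best$interior, best$boundary[2]),
    interior_knots = best$interior,
    boundary_knots = best$boundary,
    coefficients = unname(best$coefficients),
    n_knots = best$k, n_coef = best$p,
    checkloss = best$rho, sic = best$sic, n = n,
    fit_domain = range(t),
    t_origin = xt$origin,
    segment = attr(series, "segment") %||% "whole",
    data = tibble(t_days = t, drift_rate_ms = y)),
    class = "drift_trend")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve the time axis of a series to numeric days + POSIXct origin
# (midnight UTC of the first observation's day), so that "day d" means
# the d-th calendar day of the record.
trend_time_axis <- function(series) {
  if ("t_days" %in% names(series)) {
    return(list(t = series$t_days,
                origin = as.POSIXct("1970-01-01", tz = "UTC")))
  }
  assert_columns(series, c("time_utc", "drift_rate_ms"), "`series`")
  tt <- as.numeric(series$time_utc)
  origin <- floor(min(tt) / 86400) * 86400
  list(t = (tt - origin) / 86400,
       origin = as.POSIXct(origin, origin = "1970-01-01", tz = "UTC"))
}

#' @export
print.drift_trend <- function(x, ...) {
  cat(sprintf("<drift_trend> tau = %.2f, degree %d, %d knots, n = %d, check loss = %.4f\n",
              x$tau, x$degree, x$n_knots, x$n, x$checkloss))
  invisible(x)
}

#' @export
predict.drift_trend <- function(object, t_days, ...) {
  if (any(t_days < object$fit_domain[1] - 1e-9 |
          t_days > object$fit_domain[2] + 1e-9)) {
    abort("prediction outside the fitted domain is not supported.")
  }
  B <- splines::bs(pmin(pmax(t_days, object$fit_domain[1]),
                        object$fit_domain[2]),
                   knots = object$interior_knots, degree = object$degree,
                   intercept = TRUE, Boundary.knots = object$boundary_knots)
  as.vector(as.matrix(B) %*% object$coefficients)
}

#' @export
tidy.drift_trend <- function(x, ...) {
  tibble(term = sprintf("b%02d", seq_along(x$coefficients)),
         estimate = x$coefficients)
}

#' @export
glance.drift_trend <- function(x, ...) {
  tibble(tau = x$tau, degree = x$degree, n_knots = x$n_knots,
         n = x$n, checkloss = x$checkloss, sic = x$sic)
}

#' Representative daily drift-rate predictions
#'
#' Evaluates a fitted trend at local noon of every day whose midpoint
#' falls inside the fitted domain; no extrapolation.
#'
#' @param trend A [fit_trend()] result.
#' @return Tibble with `day` (integer day index of the record), `t_days`
#'   (evaluation time, day + 0.5) and `drift_rate_pred` (m s^-1).
#' @export
predict_daily <- function(trend) {
  stopifnot(inherits(trend, "drift_trend"))
  lo <- trend$fit_domain[1]; hi <- trend$fit_domain[2]
  days <- seq(floor(lo), ceiling(hi))
  mids <- days + 0.5
  keep <- mids >= lo & mids <= hi
  tibble(day = as.integer(days[keep]), t_days = mids[keep],
         drift_rate_pred = predict(trend, mids[keep]))
}

#' Split a drift-rate series at extended haul-outs
#'
#' A months-long record can be interrupted by a haul-out ashore; the
#' buoyancy trend before and after is fitted separately. Observations
#' separated by more than `gap_days` are split into segments; if
#' `haulout_gaps` is supplied (logical, one value per between-observation
#' gap, `TRUE` where an independent source flags a haul-out), only
#' flagged gaps split and the gap rule applies within the flag.
#'
#' @param series Drift-rate series tibble (`time_utc` or `t_days` axis),
#'   time-ordered or not (it is sorted).
#' @param gap_days Gap threshold in days. Default 2.
#' @param haulout_gaps Optional logical vector of length `nrow(series) - 1`.
#' @return The series sorted in time with an integer `segment` column.
#' @export
split_on_haulout <- function(series, gap_days = 2, haulout_gaps = NULL) {
  xt <- trend_time_axis(series)
  o <- order(xt$t)
  series <- series[o, , drop = FALSE]
  t <- xt$t[o]
  gaps <- diff(t) > gap_days
  if (!is.null(haulout_gaps)) {
    if (length(haulout_gaps) != length(gaps)) {
      abort("`haulout_gaps` must have one value per between-observation gap.")
    }
    gaps <- gaps & haulout_gaps
  }
  series$segment <- cumsum(c(1L, as.integer(gaps)))
  series
}
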