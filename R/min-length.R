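#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS` of fitted against observed values. Can be
#' negative for fits worse than the observed mean.
#'
#' @param observed,fitted Numeric vectors of equal length (>= 2).
#' @return A single number in `(-Inf, 1]`.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) {
    abort("`observed` and `fitted` must have equal length.")
  }
  if (length(observed) < 2) abort("need at least 2 observations.")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) abort("total sum of squares is zero; R^2 undefined.")
  1 - sum((observed - fitted)^2) / tss
}

#' Goodness-of-fit curve over minimum-length thresholds
#'
#' The statistics-based derivation of the minimum drift-fragment length:
#' for each individual and each length threshold `x`, the candidate
#' fragments longer than `x` minutes form a subsample; a cross-validated
#' cubic smoothing spline of vertical speed against time is fitted to
#' that subsample and its `R^2` recorded. Short fragments carry noisy
#' speed estimates (the same absolute time/depth error is a larger
#' relative error), so `R^2` improves as they are excluded; the
#' threshold where the improvement is steepest is the recommended
#' minimum length.
#'
#' @param fragments Tibble with columns `individual_id`, `duration_s`,
#'   `vspeed_ms`, and a time axis: either `time_days` (numeric) or
#'   `start_utc` (POSIXct).
#' @param thresholds Length thresholds in minutes. Default `1:15`.
#' @param min_n Minimum subsample size per cell; smaller cells are
#'   marked missing. Default 10.
#' @return An object of class `r2_curve`: list with `cells` (tibble
#'   individual_id, threshold_min, r2, n) and `median` (tibble
#'   threshold_min, r2_median, n_individuals).
#' @seealso [find_inflection()]
#' @export
build_r2_curve <- function(fragments, thresholds = 1:15, min_n = 10) {
  assert_columns(fragments, c("individual_id", "duration_s", "vspeed_ms"),
                 "`fragments`")
  if (any(diff(thresholds) <= 0)) abort("`thresholds` must be strictly increasing.")
  if ("time_days" %in% names(fragments)) {
    tt <- fragments$time_days
  } else if ("start_utc" %in% names(fragments)) {
    tt <- as.numeric(fragments$start_utc) / 86400
    tt <- tt - min(tt)
  } else {
    abort("`fragments` needs a `time_days` or `start_utc` column.")
  }
  df <- tibble(individual_id = fragments$individual_id, t = tt,
               dur_min = fragments$duration_s / 60,
               v = fragments$vspeed_ms)
  cells <- purrr::map_dfr(split(df, df$individual_id), function(d) {
    purrr::map_dfr(thresholds, function(x) {
      sub <- d[d$dur_min > x, , drop = FALSE]
      n <- nrow(sub)
      r2 <- NA_real_
      if (n >= max(min_n, 5) && length(unique(sub$t)) >= 4 &&
          var(sub$v) > 0) {
        fit <- stats::smooth.spline(sub$t, sub$v, cv = FALSE)  # GCV penalty
        pred <- predict(fit, x = sub$t)$y
        r2 <- r_squared(sub$v, pred)
      }
      tibble(individual_id = d$individual_id[1], threshold_min = x,
             r2 = r2, n = n)
    })
  })
  med <- cells %>%
    group_by(.data$threshold_min) %>%
    summarise(r2_median = median(.data$r2, na.rm = TRUE),
              n_individuals = sum(!is.na(.data$r2)), .groups = "drop")
  if (all(is.na(med$r2_median))) {
    abort("all cells missing at every threshold; cannot build R^2 curve.")
  }
  empty <- med$threshold_min[med$n_individuals == 0]
  if (length(empty) > 0) {
    warn(sprintf("no usable subsample at threshold(s): %s min",
                 paste(empty, collapse = ", ")))
  }
  structure(list(cells = cells, median = med, thresholds = thresholds),
            class = "r2_curve")
}

#' @export
print.r2_curve <- function(x, ...) {
  cat("<r2_curve> median R^2 by minimum fragment length:\n")
  print(as.data.frame(x$median), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.r2_curve <- function(x, ...) x$cells

#' Recommend a minimum fragment length from an R^2 curve
#'
#' Operationalises "the most substantial improvement of fit": on the
#' median-across-individuals `R^2` sequence, the first differences
#' `delta(x) = R^2(x) - R^2(x-1)` are computed and the smallest
#' threshold attaining the largest single-step improvement is returned.
#' The full curve is always returned for visual inspection, since any
#' algorithmic detector of a "knee" is an interpretation.
#'
#' @param curve An [build_r2_curve()] result.
#' @param tol Minimal spread of the step sizes considered meaningful; if
#'   every `|delta|` is below it, or all steps are equal to within it
#'   (e.g. a strictly linear `R^2` increase), no step is distinguished
#'   and no inflection is reported. Default 1e-3.
#' @return List with `recommended_min` (minutes, or `NA` with a warning
#'   if the curve is flat or monotone without a distinguished step),
#'   `deltas` (tibble threshold_min, delta) and `median` (the median
#'   curve).
#' @export
find_inflection <- function(curve, tol = 1e-3) {
  stopifnot(inherits(curve, "r2_curve"))
  med <- curve$median[!is.na(curve$median$r2_median), , drop = FALSE]
  if (nrow(med) < 4) abort("need >= 4 thresholds with non-missing median R^2.")
  r2 <- med$r2_median
  x <- med$threshold_min
  delta <- diff(r2)
  dx <- x[-1]
  rec <- NA_real_
  distinguished <- any(abs(delta) >= tol) &&
    (max(delta) - min(delta)) >= tol && max(delta) >= tol
  if (distinguished) rec <- dx[which(delta >= max(delta) - 1e-9)[1]]
  if (is.na(rec)) {
    warn("no inflection found: R^2 improvements are flat or monotone.")
  }
  list(recommended_min = rec,
       deltas = tibble(threshold_min = dx, delta = delta),
       median = curve$median)
}

#' Fragment counts by length after the other six criteria
#'
#' Applies every selection criterion except the minimum-length one and
#' bins the surviving fragments by duration (1-min bins). The modal bin
#' is the companion diagnostic to [find_inflection()]: if drift
#' fragments truly dominate above some length, the histogram of
#' survivors peaks there.
#'
#' @param fragments Fragment tibble from [fragment_dives()].
#' @param config A [filter_config()].
#' @param max_min Upper edge of the histogram in minutes. Default 30.
#' @return List with `histogram` (tibble bin_min, n; empty if nothing
#'   survives) and `modal_bin_min` (lower edge of the modal bin, or NA).
#' @export
count_by_length <- function(fragments, config = filter_config(),
                            max_min = 30) {
  res <- apply_filters(fragments, config,
                       order = c("speed", "depth", "pct", "next_ascent",
                                 "time", "prev_descent"))
  surv <- res$drift
  if (nrow(surv) == 0) {
    return(list(histogram = tibble(bin_min = numeric(), n = integer()),
                modal_bin_min = NA_real_))
  }
  bin <- pmin(floor(surv$duration_s / 60), max_min)
  tab <- tibble(bin_min = as.numeric(names(table(bin))),
                n = as.integer(table(bin)))
  list(histogram = tab,
       modal_bin_min = tab$bin_min[which.max(tab$n)])
}
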