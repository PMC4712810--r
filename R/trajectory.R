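#' Logistic buoyancy trajectory
#'
#' Describes how an animal's characteristic drift rate (vertical speed
#' during passive drifting, m s^-1, negative = sinking) changes over a
#' foraging trip. Southern elephant seals leave the colony lean and
#' strongly negatively buoyant (drift rates around -0.3 to -0.4 m s^-1)
#' and approach neutral buoyancy as lipid stores accumulate over roughly
#' the first 75-150 days at sea; a logistic curve captures that saturating
#' recovery with four interpretable parameters.
#'
#' @param v0 Drift rate at departure (day 0), m s^-1. Default -0.35.
#' @param v1 Asymptotic drift rate late in the trip, m s^-1. Default -0.02
#'   (near-neutral buoyancy).
#' @param t_mid Day of the logistic inflection (fastest change). Default 75.
#' @param scale Transition width in days (logistic scale parameter).
#'   Must be positive. Default 15.
#'
#' @return An object of class `buoyancy_trajectory`.
#' @seealso [trajectory_value()]
#' @examples
#' traj <- buoyancy_trajectory()
#' trajectory_value(traj, c(0, 75, 200))
#' @export
buoyancy_trajectory <- function(v0 = -0.35, v1 = -0.02, t_mid = 75,
                                scale = 15) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("`scale` must be a single positive number.")
  }
  for (nm in c("v0", "v1", "t_mid")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  structure(list(v0 = v0, v1 = v1, t_mid = t_mid, scale = scale),
            class = "buoyancy_trajectory")
}

#' Evaluate a buoyancy trajectory
#'
#' Logistic form `v(t) = v0 + (v1 - v0) / (1 + exp(-(t - t_mid)/scale))`,
#' so `v(t_mid) = (v0 + v1)/2` and the asymptotes are `v0` (t -> -Inf)
#' and `v1` (t -> +Inf).
#'
#' @param trajectory A [buoyancy_trajectory()].
#' @param t Time since departure in days (vectorised, must be >= 0).
#' @return Drift rate(s) in m s^-1.
#' @export
trajectory_value <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "buoyancy_trajectory"))
  if (any(t < 0, na.rm = TRUE)) abort("`t` must be non-negative (days).")
  with(trajectory, v0 + (v1 - v0) / (1 + exp(-(t - t_mid) / scale)))
}

#' @export
print.buoyancy_trajectory <- function(x, ...) {
  cat(sprintf(
    "<buoyancy_trajectory> logistic: v0 = %.3f, v1 = %.3f m/s, t_mid = %g d, scale = %g d\n",
    x$v0, x$v1, x$t_mid, x$scale))
  invisible(x)
}
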