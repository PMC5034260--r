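# Hormone-modulated epithelial turnover curves.
#
# Normalized proliferation (f_PI) and apoptosis (f_AI) indices over one
# menstrual cycle modulate the baseline rates k_pro and k_apt. A positive
# hormone level theta scales both curves multiplicatively. The follicular
# phase can be dilated/contracted for variable cycle lengths while the luteal
# segment keeps its shape.

# Anchor points of the default normalized curves (day, value). Shape-
# preserving piecewise-cubic interpolation guarantees that local extrema sit
# exactly at anchors, so the normalization max(f) = 1 and the follicular PI
# ratio 13.45/30.46 hold exactly.
#
# f_PI: global maximum 1 in the luteal phase (day 24, "near the end of the
# cycle"); follicular local maximum at day 7 with value 13.45/30.46 so that
# simulated PI peaks reproduce the 30.46 (luteal) / 13.45 (follicular) range.
# f_AI: local maxima near cycle start (day 2) and in the mid-to-late luteal
# phase (day 24, global maximum 1), low mid-cycle; periodic (f(0) = f(28)).
.FPI_RATIO <- 13.45 / 30.46
.DEFAULT_PI_ANCHORS <- cbind(
  day = c(0, 3, 7, 11, 14, 17, 24, 28),
  val = c(0.15, 0.20, .FPI_RATIO, 0.28, 0.22, 0.35, 1.00, 0.15)
)
.DEFAULT_AI_ANCHORS <- cbind(
  day = c(0, 2, 5, 9, 14, 17, 21, 24, 28),
  val = c(0.70, 0.80, 0.35, 0.22, 0.20, 0.30, 0.70, 1.00, 0.70)
)

#' Construct a hormone profile
#'
#' @param t_grid times within one cycle, in days (increasing, starting at 0).
#' @param f_pi,f_ai normalized proliferation/apoptosis indices on `t_grid`
#'   (dimensionless, nonnegative).
#' @param follicular_len follicular phase length in days.
#' @param luteal_len luteal phase length in days (default 14).
#' @param theta positive hormone level scaling factor.
#' @return A `hormone_profile` object.
#' @export
hormone_profile <- function(t_grid, f_pi, f_ai, follicular_len = 14,
                            luteal_len = 14, theta = 1) {
  stopifnot(length(t_grid) == length(f_pi), length(t_grid) == length(f_ai),
            all(diff(t_grid) > 0), all(f_pi >= 0), all(f_ai >= 0))
  if (theta <= 0) stop("theta must be positive")
  structure(list(
    t_grid = as.numeric(t_grid), f_pi = as.numeric(f_pi),
    f_ai = as.numeric(f_ai), follicular_len = follicular_len,
    luteal_len = luteal_len, theta = theta
  ), class = "hormone_profile")
}

#' @export
print.hormone_profile <- function(x, ...) {
  cat("Hormone profile: cycle ", cycle_length(x), " d (follicular ",
      x$follicular_len, " + luteal ", x$luteal_len, "), theta = ", x$theta,
      "\n", sep = "")
  cat("  max f_PI = ", max(x$f_pi), " at day ", x$t_grid[which.max(x$f_pi)],
      "; max f_AI = ", max(x$f_ai), " at day ", x$t_grid[which.max(x$f_ai)],
      "\n", sep = "")
  invisible(x)
}

#' Cycle length of a hormone profile, in days
#' @param profile a [hormone_profile].
#' @export
cycle_length <- function(profile) profile$follicular_len + profile$luteal_len

#' Default normalized proliferation/apoptosis curves
#'
#' The reference 28-day cycle (follicular days 0--14, luteal 14--28).
#' The curves are smooth interpolants through anchor points encoding the
#' reported qualitative features: the proliferation index peaks near the end
#' of the cycle (normalized to 1) with a follicular local maximum of
#' 13.45/30.46 of the global maximum; the apoptosis index has local maxima
#' near the cycle start and in the mid-to-late luteal phase.
#'
#' @param theta positive hormone level (default 1).
#' @param step grid spacing in days (default 0.25).
#' @return A [hormone_profile].
#' @export
default_profile <- function(theta = 1, step = 0.25) {
  t_grid <- seq(0, 28, by = step)
  # shape-preserving piecewise-cubic Hermite interpolation: no overshoot, so
  # local extrema sit exactly at the anchors and normalization is exact
  f_pi <- signal::pchip(.DEFAULT_PI_ANCHORS[, 1], .DEFAULT_PI_ANCHORS[, 2],
                        t_grid)
  f_ai <- signal::pchip(.DEFAULT_AI_ANCHORS[, 1], .DEFAULT_AI_ANCHORS[, 2],
                        t_grid)
  hormone_profile(t_grid, pmax(f_pi, 0), pmax(f_ai, 0),
                  follicular_len = 14, luteal_len = 14, theta = theta)
}

# interpolate a profile curve at time t (days), periodic over the cycle
profile_value <- function(profile, t_day, which = c("f_pi", "f_ai")) {
  which <- match.arg(which)
  cl <- cycle_length(profile)
  tm <- t_day %% cl
  stats::approx(profile$t_grid, profile[[which]], xout = tm, rule = 2)$y
}

#' Hormone-modulated proliferation and apoptosis rates
#'
#' `rate_pro = k_pro * theta * f_PI(t)` and `rate_apt = k_apt * theta *
#' f_AI(t)`, with linear interpolation between grid points and periodic
#' extension across cycles.
#'
#' @param profile a [hormone_profile].
#' @param t_h hours since simulation start (>= 0).
#' @param k_pro baseline proliferation rate, per hour.
#' @param k_apt baseline apoptosis rate, per hour.
#' @param theta hormone level; defaults to the profile's theta.
#' @return list with `rate_pro` and `rate_apt` (per hour).
#' @export
hormone_rates <- function(profile, t_h, k_pro = 0.03, k_apt = 0.0021,
                          theta = profile$theta) {
  if (theta <= 0) stop("theta must be positive")
  stopifnot(all(t_h >= 0))
  t_day <- t_h / 24
  list(
    rate_pro = k_pro * theta * profile_value(profile, t_day, "f_pi"),
    rate_apt = k_apt * theta * profile_value(profile, t_day, "f_ai")
  )
}

#' Dilate or contract the follicular phase
#'
#' Linearly rescales the follicular segment of the time axis from
#' `[0, follicular_len]` to `[0, new_follicular_len]` and translates the
#' luteal segment, keeping its shape. Curve values are preserved pointwise
#' under the time map.
#'
#' @param profile a [hormone_profile].
#' @param new_follicular_len new follicular phase length in days (> 0).
#' @return A rescaled [hormone_profile].
#' @export
rescale_follicular <- function(profile, new_follicular_len) {
  if (new_follicular_len <= 0) stop("new_follicular_len must be positive")
  fl <- profile$follicular_len
  tg <- profile$t_grid
  new_t <- ifelse(tg <= fl, tg * new_follicular_len / fl, tg - fl + new_follicular_len)
  # the map can collide at the phase boundary when contracting; keep strictly
  # increasing grid by dropping duplicated times
  keep <- !duplicated(new_t)
  hormone_profile(new_t[keep], profile$f_pi[keep], profile$f_ai[keep],
                  follicular_len = new_follicular_len,
                  luteal_len = profile$luteal_len, theta = profile$theta)
}

#' Write hormone curves as CSV (`day,f_pi,f_ai`)
#' @param profile a [hormone_profile].
#' @param path output path.
#' @export
write_hormone_csv <- function(profile, path) {
  utils::write.csv(
    data.frame(day = profile$t_grid, f_pi = profile$f_pi, f_ai = profile$f_ai),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read hormone curves from CSV (`day,f_pi,f_ai`)
#' @param path CSV path.
#' @param follicular_len,luteal_len,theta phase lengths (days) and hormone level.
#' @return A [hormone_profile].
#' @export
read_hormone_csv <- function(path, follicular_len = 14, luteal_len = 14, theta = 1) {
  df <- utils::read.csv(path)
  need <- c("day", "f_pi", "f_ai")
  if (!all(need %in% names(df))) {
    stop("hormone CSV must have columns: ", paste(need, collapse = ", "))
  }
  hormone_profile(df$day, df$f_pi, df$f_ai, follicular_len, luteal_len, theta)
}
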