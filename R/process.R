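#' Detect the stance window from the vertical GRF
#'
#' Finds the first and last sample of sustained foot-floor contact: the bounds
#' of the first and last runs of at least `min_run` consecutive samples whose
#' vertical ground reaction force exceeds `threshold_fraction` of body weight.
#'
#' @param grf_vertical Vertical GRF series, N (non-negative).
#' @param body_mass Body mass in kg.
#' @param threshold_fraction Contact threshold as a fraction of body weight
#'   (default 0.03).
#' @param min_run Minimum run length of suprathreshold samples (default 3).
#' @return Integer vector `c(first, last)` of stance bounds (1-based).
#' @export
detect_stance <- function(grf_vertical, body_mass, threshold_fraction = 0.03,
                          min_run = 3L) {
  if (any(grf_vertical < 0)) stop("'grf_vertical' must be non-negative")
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("'threshold_fraction' must be in (0, 1)")
  }
  thr <- threshold_fraction * body_mass * 9.81
  above <- grf_vertical > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (!any(ok)) {
    stop("no sustained suprathreshold GRF region: cannot detect stance")
  }
  c(starts[which(ok)[1]], ends[utils::tail(which(ok), 1)])
}

#' Preprocess a stance trial
#'
#' Applies the standard preprocessing chain to a raw trial: optional zero-lag
#' Butterworth low-pass filtering of the angle and moment series
#' ([lowpass_zero_lag()]), cropping to the stance window, linear resampling of
#' all series onto `n_points` equally spaced time points over stance
#' (stance-time normalisation, 0-100%), unit conversion (degrees to radians),
#' mass normalisation of the moment (N m kg^-1), angular velocity by central
#' differences (second-order one-sided stencils at the ends), and joint power.
#'
#' Sign conventions: the angle is dorsiflexion-positive and the moment column
#' is plantarflexor-positive, which is the orientation in which the
#' controlled-dorsiflexion and powered-plantarflexion limbs of the loop have
#' positive slope (positive quasi-stiffness). Joint power pairs the internal
#' moment with the angular velocity, `power = -moment_norm * omega`, so that
#' power is negative during controlled dorsiflexion (absorption) and positive
#' during powered plantarflexion (generation).
#'
#' @param trial A `gait_trial`.
#' @param stance Optional integer pair overriding stance detection; by default
#'   the window is found with [detect_stance()].
#' @param n_points Number of resampled points over stance (default 101, i.e.
#'   0-100% in 1% steps). Use `NA` to keep the native sampling grid
#'   (crop only, no resampling).
#' @param lowpass Logical: apply the zero-lag filter (default TRUE).
#' @param cutoff,order Filter settings for [lowpass_zero_lag()].
#' @param threshold_fraction Stance-detection threshold, see [detect_stance()].
#' @return A `processed_trial`: metadata plus equal-length series `time`,
#'   `percent_stance`, `angle_rad`, `moment_norm`, `omega`, `power_norm`.
#' @export
process_trial <- function(trial, stance = NULL, n_points = 101,
                          lowpass = TRUE, cutoff = 10, order = 6,
                          threshold_fraction = 0.03) {
  validate_gait_trial(trial)
  fs <- trial$sampling_rate
  angle <- trial$angle_deg
  moment <- trial$moment_nm
  if (lowpass) {
    angle <- lowpass_zero_lag(angle, fs, cutoff, order)
    moment <- lowpass_zero_lag(moment, fs, cutoff, order)
  }
  if (is.null(stance)) {
    stance <- detect_stance(trial$grf_n, trial$body_mass, threshold_fraction)
  }
  i0 <- stance[1]; i1 <- stance[2]
  if (i0 < 1L || i1 > length(trial$time) || i0 >= i1) {
    stop("invalid stance bounds [", i0, ", ", i1, "] for a trial of ",
         length(trial$time), " samples")
  }
  if (i1 - i0 + 1L < 5L) stop("stance window shorter than 5 samples")
  t_in <- trial$time[i0:i1]
  angle <- angle[i0:i1]
  moment <- moment[i0:i1]

  if (is.null(n_points) || is.na(n_points)) {
    t_out <- t_in
  } else {
    if (n_points < 5) stop("'n_points' must be at least 5")
    t_out <- seq(t_in[1], t_in[length(t_in)], length.out = n_points)
  }
  angle_out <- stats::approx(t_in, angle, xout = t_out)$y
  moment_out <- stats::approx(t_in, moment, xout = t_out)$y

  angle_rad <- angle_out * pi / 180
  moment_norm <- moment_out / trial$body_mass
  omega <- deriv_central(angle_rad, t_out)
  power_norm <- -moment_norm * omega

  structure(list(
    subject_id = trial$subject_id,
    speed_category = trial$speed_category,
    body_mass = trial$body_mass,
    sampling_rate = fs,
    stance_bounds = c(i0, i1),
    n_points = length(t_out),
    lowpass = lowpass, cutoff = cutoff, order = order,
    time = t_out,
    percent_stance = 100 * (t_out - t_out[1]) / (t_out[length(t_out)] - t_out[1]),
    angle_rad = angle_rad,
    moment_norm = moment_norm,
    omega = omega,
    power_norm = power_norm
  ), class = "processed_trial")
}

# first derivative on a uniform grid: central differences inside,
# second-order one-sided stencils at the two boundary samples
deriv_central <- function(y, t) {
  n <- length(y)
  h <- (t[n] - t[1]) / (n - 1)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  d
}

#' @export
print.processed_trial <- function(x, ...) {
  cat(sprintf("<processed_trial> %s [%s], %d points over stance, mass %g kg\n",
              x$subject_id, x$speed_category, x$n_points, x$body_mass))
  cat(sprintf("  angle %.3f..%.3f rad, moment %.2f..%.2f N m kg^-1, power %.2f..%.2f W kg^-1\n",
              min(x$angle_rad), max(x$angle_rad),
              min(x$moment_norm), max(x$moment_norm),
              min(x$power_norm), max(x$power_norm)))
  invisible(x)
}
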