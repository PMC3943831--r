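#' Quasi-stiffness of a moment-angle segment
#'
#' Ordinary least-squares regression of the mass-normalised moment on the
#' joint angle over a segment; the slope is the quasi-stiffness K
#' (N m kg^-1 rad^-1), reported with the intercept, the coefficient of
#' determination and the number of points. The regression includes an
#' intercept because moment-angle loops do not pass through the origin.
#'
#' @param angle_rad Joint angle series, radians.
#' @param moment_norm Mass-normalised moment series, N m kg^-1
#'   (plantarflexor-positive).
#' @param segment Integer indices of the segment (default: whole series).
#' @param phase Optional phase label stored in the result.
#' @return A `phase_fit`: list with `phase`, `k`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_quasi_stiffness <- function(angle_rad, moment_norm,
                                segment = seq_along(angle_rad),
                                phase = NA_character_) {
  x <- angle_rad[segment]
  y <- moment_norm[segment]
  n <- length(x)
  if (n < 3) stop("segment must contain at least 3 samples, got ", n)
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  if (sxx <= .Machine$double.eps * n * max(1, xm^2)) {
    stop("degenerate segment: angle is constant, quasi-stiffness undefined")
  }
  sxy <- sum((x - xm) * (y - ym))
  k <- sxy / sxx
  b <- ym - k * xm
  ss_res <- sum((y - (k * x + b))^2)
  ss_tot <- sum((y - ym)^2)
  r2 <- if (ss_tot <= 0) {
    if (ss_res <= 1e-300) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  structure(list(phase = phase, k = k, intercept = b, r_squared = r2,
                 n_points = n), class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("<phase_fit %s> K = %.4f N m kg^-1 rad^-1, intercept %.4f, R^2 = %.4f (n = %d)\n",
              x$phase, x$k, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Trapezoidal work of a moment-angle segment
#'
#' Signed trapezoidal integral of the supplied moment over the angle path,
#' `sum(0.5 * (M[i] + M[i+1]) * (theta[i+1] - theta[i]))`. The sign carries
#' the direction of traversal: reversing the path negates the value. To obtain
#' energy-signed work (absorption negative, generation positive) pass the
#' power-paired moment, i.e. the negated plantarflexor-positive moment, as
#' [analyze_trial()] does.
#'
#' @param angle_rad Joint angle series, radians.
#' @param moment Moment series paired with the angle.
#' @param segment Integer indices of the segment (default: whole series).
#' @return Signed work, N m rad kg^-1 for mass-normalised input.
#' @export
phase_work <- function(angle_rad, moment, segment = seq_along(angle_rad)) {
  x <- angle_rad[segment]
  y <- moment[segment]
  if (length(x) < 2) stop("segment must contain at least 2 samples")
  trapz(y, x)
}

#' Net loop work from phase magnitudes
#'
#' The net work of the stance moment-angle loop, computed from the absolute
#' areas of the two energetically dominant sub-phases:
#' `W_total = |W_PP| - |W_CD|`. Controlled plantarflexion is excluded by this
#' accounting rule (its area is an order of magnitude smaller); it is reported
#' separately by [analyze_trial()].
#'
#' @param abs_w_pp Absolute powered-plantarflexion work (>= 0).
#' @param abs_w_cd Absolute controlled-dorsiflexion work (>= 0).
#' @return Net work, N m rad kg^-1.
#' @export
total_work <- function(abs_w_pp, abs_w_cd) {
  if (any(abs_w_pp < 0) || any(abs_w_cd < 0)) {
    stop("'abs_w_pp' and 'abs_w_cd' must be non-negative magnitudes")
  }
  abs_w_pp - abs_w_cd
}

#' Shoelace-area oracle for net loop work
#'
#' Signed polygon (shoelace) area of the moment-angle path, counter-clockwise
#' positive, closing the polygon from the last point back to the first. For a
#' closed loop in plantarflexor-positive coordinates this equals the signed
#' sum of the energy-signed per-phase trapezoidal works, providing an
#' independent cross-check of the work integration: a counter-clockwise loop
#' (net generation) has positive area, a clockwise loop (net absorption)
#' negative. The gap between the loop's endpoints is attached as attributes
#' `gap_angle` and `gap_moment` so near-closure can be verified.
#'
#' @param angle_rad Joint angle series, radians.
#' @param moment_norm Mass-normalised plantarflexor-positive moment,
#'   N m kg^-1.
#' @return Signed area (net work, N m rad kg^-1) with closure-gap attributes.
#' @export
loop_area_oracle <- function(angle_rad, moment_norm) {
  x <- angle_rad; y <- moment_norm
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a loop area")
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- 0.5 * sum(x * yn - xn * y)
  structure(area,
            gap_angle = abs(x[n] - x[1]),
            gap_moment = abs(y[n] - y[1]))
}

#' Stance power metrics
#'
#' @param power_norm Mass-normalised joint power series, W kg^-1.
#' @return A list with `peak_power` (maximum sample) and `mean_stance_power`
#'   (arithmetic mean over stance samples).
#' @export
power_metrics <- function(power_norm) {
  if (length(power_norm) == 0) stop("'power_norm' must be non-empty")
  list(peak_power = max(power_norm),
       mean_stance_power = mean(power_norm))
}

#' Full per-trial loop analysis
#'
#' Runs the mechanics chain on a processed trial: sub-phase segmentation
#' (unless a segmentation is supplied), per-phase quasi-stiffness regressions,
#' energy-signed per-phase trapezoidal works (computed on the power-paired
#' moment, so CD absorption is negative and PP generation positive), the net
#' loop work `|W_PP| - |W_CD|`, the shoelace-area diagnostic with its
#' discrepancy from the signed sum of phase works (they differ by the loop's
#' closure gap), and stance power metrics.
#'
#' @param ptrial A `processed_trial`.
#' @param seg Optional precomputed `stance_segmentation`.
#' @param ... Passed to [segment_phases()] when `seg` is NULL.
#' @return A `trial_metrics` list: `fits` (per-phase `phase_fit`s), `work`
#'   (signed and absolute per-phase works, `w_total`), `power`, `loop`
#'   (shoelace area, closure gap, discrepancy vs summed works), `segmentation`
#'   and trial metadata.
#' @export
analyze_trial <- function(ptrial, seg = NULL, ...) {
  if (is.null(seg)) seg <- segment_phases(ptrial, ...)
  segs <- phase_segments(seg)
  angle <- ptrial$angle_rad
  moment <- ptrial$moment_norm

  fits <- list(
    cp = fit_quasi_stiffness(angle, moment, segs$cp, phase = "CP"),
    cd = fit_quasi_stiffness(angle, moment, segs$cd, phase = "CD"),
    pp = fit_quasi_stiffness(angle, moment, segs$pp, phase = "PP")
  )
  # energy-signed works: integrate the power-paired (internal) moment
  w_cp <- phase_work(angle, -moment, segs$cp)
  w_cd <- phase_work(angle, -moment, segs$cd)
  w_pp <- phase_work(angle, -moment, segs$pp)
  work <- list(w_cp = w_cp, w_cd = w_cd, w_pp = w_pp,
               abs_w_cp = abs(w_cp), abs_w_cd = abs(w_cd), abs_w_pp = abs(w_pp),
               w_total = total_work(abs(w_pp), abs(w_cd)))
  area <- loop_area_oracle(angle, moment)
  loop <- list(shoelace_area = as.numeric(area),
               gap_angle = attr(area, "gap_angle"),
               gap_moment = attr(area, "gap_moment"),
               area_minus_summed_work = as.numeric(area) - (w_cp + w_cd + w_pp))
  structure(list(
    subject_id = ptrial$subject_id,
    speed_category = ptrial$speed_category,
    body_mass = ptrial$body_mass,
    fits = fits,
    work = work,
    power = power_metrics(ptrial$power_norm),
    loop = loop,
    segmentation = seg
  ), class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("<trial_metrics> %s [%s]\n", x$subject_id, x$speed_category))
  cat(sprintf("  K (CP/CD/PP): %.3f / %.3f / %.3f; R^2: %.3f / %.3f / %.3f\n",
              x$fits$cp$k, x$fits$cd$k, x$fits$pp$k,
              x$fits$cp$r_squared, x$fits$cd$r_squared, x$fits$pp$r_squared))
  cat(sprintf("  |W| (CP/CD/PP): %.3f / %.3f / %.3f; W_total = %.3f N m rad kg^-1\n",
              x$work$abs_w_cp, x$work$abs_w_cd, x$work$abs_w_pp, x$work$w_total))
  cat(sprintf("  peak power %.3f, mean stance power %.3f W kg^-1\n",
              x$power$peak_power, x$power$mean_stance_power))
  invisible(x)
}

#' One-row data frame of per-trial metrics
#'
#' Flattens a `trial_metrics` into the row format consumed by
#' [aggregate_cohort()] and the cohort statistics.
#'
#' @param m A `trial_metrics`.
#' @return A one-row data.frame.
#' @export
metrics_row <- function(m) {
  data.frame(
    subject_id = m$subject_id,
    speed_category = m$speed_category,
    k_cp = m$fits$cp$k, k_cd = m$fits$cd$k, k_pp = m$fits$pp$k,
    r2_cp = m$fits$cp$r_squared, r2_cd = m$fits$cd$r_squared,
    r2_pp = m$fits$pp$r_squared,
    abs_w_cp = m$work$abs_w_cp, abs_w_cd = m$work$abs_w_cd,
    abs_w_pp = m$work$abs_w_pp, w_total = m$work$w_total,
    peak_power = m$power$peak_power,
    mean_stance_power = m$power$mean_stance_power,
    loop_area = m$loop$shoelace_area,
    loop_gap_moment = m$loop$gap_moment,
    stringsAsFactors = FALSE
  )
}
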