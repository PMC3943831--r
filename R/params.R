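#' @keywords internal
"_PACKAGE"

SPEED_LEVELS <- c("very_slow", "slow", "normal", "fast")

#' Generator parameters for a synthetic stance trial
#'
#' Bundles and validates the free parameters of the phase-switched
#' spring-damper-actuator ankle model used by [generate_trial()]. Stiffnesses
#' are quasi-stiffnesses in N m kg^-1 rad^-1; damping is in
#' N m s kg^-1 rad^-1; push-off work is the net energy (N m rad kg^-1, i.e.
#' J kg^-1) injected by the actuator during powered plantarflexion. Angles are
#' in degrees, dorsiflexion positive, zero where the foot is perpendicular to
#' the tibia.
#'
#' @param speed_category One of `"very_slow"`, `"slow"`, `"normal"`, `"fast"`.
#' @param stance_duration Stance duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param body_mass Body mass in kg (> 0).
#' @param k_cp,k_cd,k_pp Quasi-stiffness of the controlled plantarflexion,
#'   controlled dorsiflexion and powered plantarflexion phases
#'   (N m kg^-1 rad^-1). `k_cd` and `k_pp` must be positive.
#' @param damping_c Viscous damping coefficient (N m s kg^-1 rad^-1, >= 0).
#' @param pushoff_work Energy injected by the push-off actuator during powered
#'   plantarflexion (N m rad kg^-1, >= 0).
#' @param theta_cp_min Angle at the controlled-plantarflexion trough, degrees
#'   (< 0).
#' @param theta_cd_max Peak dorsiflexion angle in mid-stance, degrees (> 0).
#' @param theta_toeoff Toe-off angle, degrees; the deepest plantarflexion of
#'   the loop, so it must lie below `theta_cp_min`.
#' @param noise_sd_angle Additive Gaussian measurement noise on the angle,
#'   degrees (>= 0).
#' @param noise_sd_moment Additive Gaussian measurement noise on the
#'   mass-normalised moment, N m kg^-1 (>= 0).
#' @param cp_fraction,cd_fraction Fractions of stance time at which the model
#'   switches CP -> CD and CD -> PP (0 < cp_fraction < cd_fraction < 1).
#' @param rng_seed Integer seed for the trial's noise realisation.
#' @return An object of class `generator_params` (a validated list).
#' @seealso [speed_presets()] for the four default walking-speed conditions.
#' @export
generator_params <- function(speed_category = "normal",
                             stance_duration = 0.70,
                             sampling_rate = 100,
                             body_mass = 70,
                             k_cp = -0.2, k_cd = 5.5, k_pp = 4.6,
                             damping_c = 0.03,
                             pushoff_work = 0.19,
                             theta_cp_min = -5, theta_cd_max = 10,
                             theta_toeoff = -16,
                             noise_sd_angle = 0.25,
                             noise_sd_moment = 0.03,
                             cp_fraction = 0.07,
                             cd_fraction = 0.72,
                             rng_seed = 1L) {
  p <- list(speed_category = speed_category,
            stance_duration = stance_duration,
            sampling_rate = sampling_rate,
            body_mass = body_mass,
            k_cp = k_cp, k_cd = k_cd, k_pp = k_pp,
            damping_c = damping_c,
            pushoff_work = pushoff_work,
            theta_cp_min = theta_cp_min,
            theta_cd_max = theta_cd_max,
            theta_toeoff = theta_toeoff,
            noise_sd_angle = noise_sd_angle,
            noise_sd_moment = noise_sd_moment,
            cp_fraction = cp_fraction,
            cd_fraction = cd_fraction,
            rng_seed = as.integer(rng_seed))
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  chk <- function(cond, name, msg) {
    if (!isTRUE(cond)) stop("invalid generator parameter '", name, "': ", msg,
                            call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(is.character(p$speed_category) && length(p$speed_category) == 1 &&
        p$speed_category %in% SPEED_LEVELS, "speed_category",
      paste("must be one of", paste(SPEED_LEVELS, collapse = ", ")))
  chk(num1(p$stance_duration) && p$stance_duration > 0,
      "stance_duration", "must be a positive number of seconds")
  chk(num1(p$sampling_rate) && p$sampling_rate > 0,
      "sampling_rate", "must be a positive sampling rate in Hz")
  chk(num1(p$body_mass) && p$body_mass > 0, "body_mass", "must be positive kg")
  chk(num1(p$k_cp), "k_cp", "must be a finite number")
  chk(num1(p$k_cd) && p$k_cd > 0, "k_cd", "must be positive")
  chk(num1(p$k_pp) && p$k_pp > 0, "k_pp", "must be positive")
  chk(num1(p$damping_c) && p$damping_c >= 0, "damping_c", "must be >= 0")
  chk(num1(p$pushoff_work) && p$pushoff_work >= 0, "pushoff_work", "must be >= 0")
  chk(num1(p$theta_cp_min) && p$theta_cp_min < 0,
      "theta_cp_min", "must be negative (plantarflexion trough)")
  chk(num1(p$theta_cd_max) && p$theta_cd_max > 0,
      "theta_cd_max", "must be positive (dorsiflexion peak)")
  chk(num1(p$theta_toeoff) && p$theta_toeoff < p$theta_cp_min,
      "theta_toeoff",
      "must lie below theta_cp_min (toe-off is the deepest plantarflexion)")
  chk(num1(p$noise_sd_angle) && p$noise_sd_angle >= 0,
      "noise_sd_angle", "must be >= 0")
  chk(num1(p$noise_sd_moment) && p$noise_sd_moment >= 0,
      "noise_sd_moment", "must be >= 0")
  chk(num1(p$cp_fraction) && p$cp_fraction > 0 && p$cp_fraction < 0.35,
      "cp_fraction", "must be in (0, 0.35)")
  chk(num1(p$cd_fraction) && p$cd_fraction > p$cp_fraction && p$cd_fraction < 1,
      "cd_fraction", "must be in (cp_fraction, 1)")
  n <- round(p$stance_duration * p$sampling_rate) + 1
  chk(n >= 20, "stance_duration",
      "stance must contain at least 20 samples at the given sampling rate")
  invisible(p)
}

#' Default walking-speed presets
#'
#' Generator parameters for the four walking-speed conditions of the study
#' design (very slow, slow, normal, fast). Stance shortens and controlled
#' dorsiflexion stiffens as speed increases; the damping coefficient decreases
#' and the push-off actuator energy grows with speed, so net loop work moves
#' from slightly negative at the slowest speed (clockwise, dissipative loop)
#' to clearly positive at the fastest (counter-clockwise, generative loop).
#' The values are preset modelling choices that mimic the qualitative trends
#' of adult gait, not claims about any particular data set.
#'
#' @param body_mass Body mass in kg applied to all presets.
#' @param noise_sd_angle,noise_sd_moment Measurement-noise levels applied to
#'   all presets (see [generator_params()]).
#' @return Named list of `generator_params`, one per speed category.
#' @export
speed_presets <- function(body_mass = 70, noise_sd_angle = 0.25,
                          noise_sd_moment = 0.03) {
  mk <- function(...) generator_params(body_mass = body_mass,
                                       noise_sd_angle = noise_sd_angle,
                                       noise_sd_moment = noise_sd_moment, ...)
  list(
    very_slow = mk(speed_category = "very_slow", stance_duration = 0.85,
                   k_cp = -0.60, k_cd = 4.6, k_pp = 4.8,
                   damping_c = 0.08, pushoff_work = 0.035,
                   theta_cp_min = -4.0, theta_cd_max = 10, theta_toeoff = -14),
    slow = mk(speed_category = "slow", stance_duration = 0.78,
              k_cp = -0.45, k_cd = 4.5, k_pp = 4.5,
              damping_c = 0.05, pushoff_work = 0.115,
              theta_cp_min = -4.5, theta_cd_max = 10, theta_toeoff = -15),
    normal = mk(speed_category = "normal", stance_duration = 0.70,
                k_cp = -0.20, k_cd = 5.5, k_pp = 4.6,
                damping_c = 0.03, pushoff_work = 0.195,
                theta_cp_min = -5.0, theta_cd_max = 10, theta_toeoff = -16),
    fast = mk(speed_category = "fast", stance_duration = 0.60,
              k_cp = -0.40, k_cd = 5.8, k_pp = 4.5,
              damping_c = 0.02, pushoff_work = 0.395,
              theta_cp_min = -5.0, theta_cd_max = 11, theta_toeoff = -18)
  )
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params> ", x$speed_category,
      sprintf(": stance %.2f s @ %g Hz, mass %g kg\n",
              x$stance_duration, x$sampling_rate, x$body_mass))
  cat(sprintf("  K (CP/CD/PP): %.2f / %.2f / %.2f N m kg^-1 rad^-1\n",
              x$k_cp, x$k_cd, x$k_pp))
  cat(sprintf("  damping %.3f, push-off %.3f, noise (angle %.2f deg, moment %.3f N m kg^-1)\n",
              x$damping_c, x$pushoff_work, x$noise_sd_angle, x$noise_sd_moment))
  invisible(x)
}
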