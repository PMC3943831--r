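#' Generate one synthetic stance trial
#'
#' Simulates a single stance-phase recording from a phase-switched
#' spring-damper-actuator ankle model. The angle follows half-cosine segments
#' from neutral to the controlled-plantarflexion (CP) trough, up to the peak
#' dorsiflexion that ends controlled dorsiflexion (CD), and down to toe-off
#' (powered plantarflexion, PP); each segment starts and ends with zero
#' angular velocity, so the trajectory is C1 at the switches. The
#' mass-normalised moment in each phase is
#' `M = K_phase * (theta - anchor) + c * omega`, plus a half-sine actuator
#' bump confined to PP. Anchors are solved so that (a) the moment is
#' continuous across phase switches and (b) the elastic energy stored over CD
#' equals the elastic energy returned over PP; with that construction the net
#' loop work `|W_PP| - |W_CD|` of the noise-free trial equals the actuator
#' energy minus the damping losses over CD and PP exactly (trapezoidal
#' integrals of a moment linear in the angle telescope without discretisation
#' error), which is what the returned ground truth records.
#'
#' The vertical ground reaction force is a double-hump curve (peaks about 1.12
#' body weight), strictly positive inside stance and exactly zero at the first
#' and last samples. Gaussian measurement noise with the requested standard
#' deviations is added to the written angle and moment series only; the ground
#' truth is computed from the noise-free model output.
#'
#' @param params A [generator_params()] object.
#' @param subject_id Subject label stored in the trial metadata.
#' @return A list with components `trial` (a `gait_trial`: time s, angle deg,
#'   moment N m un-normalised plantarflexor-positive, vertical GRF N, plus
#'   metadata) and `truth` (a `gait_ground_truth` with the generating
#'   stiffnesses, phase-switch sample indices, the discrete energy ledger and
#'   `expected_w_total_sign`).
#' @export
generate_trial <- function(params, subject_id = "S01") {
  validate_generator_params(params)
  p <- params
  fs <- p$sampling_rate
  n <- as.integer(round(p$stance_duration * fs)) + 1L
  # snap phase switches to the sampling grid so ground-truth indices are exact
  i1 <- as.integer(round(p$cp_fraction * (n - 1))) + 1L   # CP -> CD switch sample
  i2 <- as.integer(round(p$cd_fraction * (n - 1))) + 1L   # CD -> PP switch sample
  if (i1 < 3L || i2 - i1 < 3L || n - i2 < 3L) {
    stop("invalid generator parameter 'cp_fraction'/'cd_fraction': ",
         "each sub-phase needs at least 3 samples at this sampling rate")
  }
  tvec <- (seq_len(n) - 1L) / fs
  t1 <- tvec[i1]; t2 <- tvec[i2]; t_end <- tvec[n]

  th1 <- p$theta_cp_min * pi / 180
  th2 <- p$theta_cd_max * pi / 180
  th3 <- p$theta_toeoff * pi / 180

  # half-cosine angle segments (radians) with zero end-velocities
  seg <- function(t, ta, tb, tha, thb) {
    s <- (t - ta) / (tb - ta)
    list(theta = tha + (thb - tha) / 2 * (1 - cos(pi * s)),
         omega = (thb - tha) / 2 * pi / (tb - ta) * sin(pi * s))
  }
  theta <- numeric(n); omega <- numeric(n)
  cp_idx <- 1:i1; cd_idx <- i1:i2; pp_idx <- i2:n
  s1 <- seg(tvec[cp_idx], 0, t1, 0, th1)
  s2 <- seg(tvec[cd_idx], t1, t2, th1, th2)
  s3 <- seg(tvec[pp_idx], t2, t_end, th2, th3)
  theta[cp_idx] <- s1$theta; omega[cp_idx] <- s1$omega
  theta[cd_idx] <- s2$theta; omega[cd_idx] <- s2$omega
  theta[pp_idx] <- s3$theta; omega[pp_idx] <- s3$omega

  a <- solve_anchors(p$k_cp, p$k_cd, p$k_pp, th1, th2, th3)

  # actuator: half-sine plantarflexor bump over PP, scaled so that the energy
  # it injects, -integral(M_act dtheta), equals pushoff_work analytically
  amp <- 4 * p$pushoff_work / (pi * (th2 - th3))
  s_pp <- (tvec[pp_idx] - t2) / (t_end - t2)
  m_act <- numeric(n)
  m_act[pp_idx] <- amp * sin(pi * s_pp)

  m_spring <- numeric(n)
  m_spring[1:(i1 - 1L)] <- p$k_cp * (theta[1:(i1 - 1L)] - a$cp)
  m_spring[i1:(i2 - 1L)] <- p$k_cd * (theta[i1:(i2 - 1L)] - a$cd)
  m_spring[i2:n] <- p$k_pp * (theta[i2:n] - a$pp)
  # at the switch samples omega = 0 and the anchors enforce continuity, so the
  # phase attribution of the boundary sample is immaterial
  m_norm <- m_spring + p$damping_c * omega + m_act

  # discrete energy ledger on the noise-free samples (trapezoid in theta),
  # matching the mechanics module's integration rule
  w_cp_true <- trapz(-m_norm[cp_idx], theta[cp_idx])
  w_cd_true <- trapz(-m_norm[cd_idx], theta[cd_idx])
  w_pp_true <- trapz(-m_norm[pp_idx], theta[pp_idx])
  injected <- -trapz(m_act[pp_idx], theta[pp_idx])
  dissipated <- p$damping_c *
    (trapz(omega[cd_idx], theta[cd_idx]) + trapz(omega[pp_idx], theta[pp_idx]))
  w_total_true <- abs(w_pp_true) - abs(w_cd_true)

  # double-hump vertical GRF, zero exactly at heel strike and toe-off
  tau <- tvec / t_end
  bw <- p$body_mass * 9.81
  grf <- bw * (1.30 * sin(pi * tau) + 0.28 * sin(3 * pi * tau))
  grf[1] <- 0; grf[n] <- 0
  grf[grf < 0] <- 0

  noise <- with_trial_rng(p$rng_seed, function() {
    list(angle = stats::rnorm(n, 0, p$noise_sd_angle),
         moment = stats::rnorm(n, 0, p$noise_sd_moment))
  })

  trial <- structure(list(
    subject_id = subject_id,
    speed_category = p$speed_category,
    body_mass = p$body_mass,
    sampling_rate = fs,
    time = tvec,
    angle_deg = theta * 180 / pi + noise$angle,
    moment_nm = p$body_mass * (m_norm + noise$moment),
    grf_n = grf
  ), class = "gait_trial")
  validate_gait_trial(trial)

  truth <- structure(list(
    subject_id = subject_id,
    speed_category = p$speed_category,
    k_cp = p$k_cp, k_cd = p$k_cd, k_pp = p$k_pp,
    damping_c = p$damping_c,
    pushoff_work = p$pushoff_work,
    seed = p$rng_seed,
    n_samples = n,
    cp_end_index = i1,
    cd_end_index = i2,
    w_cp_true = w_cp_true,
    w_cd_true = w_cd_true,
    w_pp_true = w_pp_true,
    w_total_true = w_total_true,
    injected_work = injected,
    dissipated_work = dissipated,
    expected_w_total_sign = sign_tol(injected - dissipated)
  ), class = "gait_ground_truth")

  list(trial = trial, truth = truth)
}

# Spring anchors: continuity at both switches plus equality of the elastic
# energy stored over CD and returned over PP (so the passive loop is closed
# and net work is actuator minus damping by construction). The equality is a
# linear equation in the CD anchor; trapezoidal integration of a moment linear
# in theta is exact, so the continuum solution is also the discrete one.
solve_anchors <- function(k_cp, k_cd, k_pp, th1, th2, th3) {
  rhs <- -k_cd * (th2^2 - th1^2) / 2 + k_pp * (th2^2 - th3^2) / 2 -
    k_pp * th2 * (th2 - th3) + k_cd * th2 * (th2 - th3)
  a_cd <- rhs / (k_cd * (th1 - th3))
  a_pp <- th2 - (k_cd / k_pp) * (th2 - a_cd)
  a_cp <- if (abs(k_cp) < 1e-12) 0 else th1 - (k_cd / k_cp) * (th1 - a_cd)
  m1 <- k_cd * (th1 - a_cd)
  list(cp = a_cp, cd = a_cd, pp = a_pp, m_cp_const = m1)
}

sign_tol <- function(x, tol = 1e-12) {
  if (abs(x) <= tol) 0L else as.integer(sign(x))
}

# run `fn` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_trial_rng <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

trapz <- function(y, x) {
  k <- length(y)
  sum(0.5 * (y[-1] + y[-k]) * diff(x))
}

validate_gait_trial <- function(trial) {
  n <- length(trial$time)
  series <- list(angle_deg = trial$angle_deg, moment_nm = trial$moment_nm,
                 grf_n = trial$grf_n)
  for (nm in names(series)) {
    if (length(series[[nm]]) != n) {
      stop("gait_trial series '", nm, "' has length ", length(series[[nm]]),
           ", expected ", n)
    }
  }
  if (n < 20) stop("gait_trial must have at least 20 samples, got ", n)
  if (any(diff(trial$time) <= 0)) stop("gait_trial time must be strictly increasing")
  if (any(trial$grf_n < 0)) stop("gait_trial grf_n must be non-negative")
  invisible(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s [%s], %d samples @ %g Hz, mass %g kg\n",
              x$subject_id, x$speed_category, length(x$time),
              x$sampling_rate, x$body_mass))
  cat(sprintf("  angle %.1f..%.1f deg, moment %.1f..%.1f N m, peak GRF %.0f N\n",
              min(x$angle_deg), max(x$angle_deg),
              min(x$moment_nm), max(x$moment_nm), max(x$grf_n)))
  invisible(x)
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> %s [%s] seed %d\n",
              x$subject_id, x$speed_category, x$seed))
  cat(sprintf("  K: %.3f / %.3f / %.3f; injected %.4f, dissipated %.4f, W_total %.4f (sign %+d)\n",
              x$k_cp, x$k_cd, x$k_pp, x$injected_work, x$dissipated_work,
              x$w_total_true, x$expected_w_total_sign))
  invisible(x)
}

#' Generate a cohort of synthetic stance trials
#'
#' Builds a repeated-measures cohort: each subject receives a multiplicative
#' random effect on the stiffnesses (one factor shared by CP/CD/PP, so the
#' within-subject correlation across speeds is real), on stance duration, on
#' the push-off energy and on the damping coefficient; every subject then
#' walks all speed conditions. Trial noise seeds are derived deterministically
#' from the master seed, so a cohort is bit-reproducible given `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param presets Named list of [generator_params()], one per speed condition
#'   (default [speed_presets()]).
#' @param trials_per_cell Trials per subject x speed cell.
#' @param seed Master integer seed.
#' @param subject_k_sd,subject_duration_sd,subject_pushoff_sd,subject_damping_sd
#'   Standard deviations of the multiplicative (mean 1) Gaussian subject
#'   effects on stiffness, stance duration, push-off work and damping.
#' @param body_mass_mean,body_mass_sd Mean and SD of subject body mass (kg).
#' @return A list with `trials` (list of `gait_trial`), `truths` (matching
#'   `gait_ground_truth`s) and `index` (data.frame: subject_id,
#'   speed_category, trial, file stem).
#' @export
generate_cohort <- function(n_subjects, presets = speed_presets(),
                            trials_per_cell = 1, seed = 1,
                            subject_k_sd = 0.12,
                            subject_duration_sd = 0.05,
                            subject_pushoff_sd = 0.15,
                            subject_damping_sd = 0.10,
                            body_mass_mean = 67.6, body_mass_sd = 10.2) {
  if (n_subjects < 2) stop("'n_subjects' must be at least 2")
  if (length(presets) == 0) stop("'presets' must not be empty")
  if (is.null(names(presets)) || any(!nzchar(names(presets)))) {
    stop("'presets' must be a named list keyed by speed category")
  }
  if (trials_per_cell < 1) stop("'trials_per_cell' must be at least 1")

  eff <- with_trial_rng(as.integer(seed), function() {
    list(k = pmax(0.2, stats::rnorm(n_subjects, 1, subject_k_sd)),
         dur = pmax(0.5, stats::rnorm(n_subjects, 1, subject_duration_sd)),
         push = pmax(0, stats::rnorm(n_subjects, 1, subject_pushoff_sd)),
         dmp = pmax(0, stats::rnorm(n_subjects, 1, subject_damping_sd)),
         mass = pmax(40, stats::rnorm(n_subjects, body_mass_mean, body_mass_sd)),
         trial_seeds = sample.int(.Machine$integer.max,
                                  n_subjects * length(presets) * trials_per_cell))
  })

  trials <- list(); truths <- list()
  idx <- data.frame(subject_id = character(), speed_category = character(),
                    trial = integer(), stem = character(),
                    stringsAsFactors = FALSE)
  counter <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (sp in names(presets)) {
      base <- presets[[sp]]
      for (tr in seq_len(trials_per_cell)) {
        counter <- counter + 1L
        p <- base
        p$k_cp <- base$k_cp * eff$k[s]
        p$k_cd <- base$k_cd * eff$k[s]
        p$k_pp <- base$k_pp * eff$k[s]
        p$stance_duration <- base$stance_duration * eff$dur[s]
        p$pushoff_work <- base$pushoff_work * eff$push[s]
        p$damping_c <- base$damping_c * eff$dmp[s]
        p$body_mass <- eff$mass[s]
        p$rng_seed <- eff$trial_seeds[counter]
        validate_generator_params(p)
        g <- generate_trial(p, subject_id = sid)
        stem <- sprintf("%s_%s_t%02d", sid, sp, tr)
        trials[[stem]] <- g$trial
        truths[[stem]] <- g$truth
        idx <- rbind(idx, data.frame(subject_id = sid, speed_category = sp,
                                     trial = tr, stem = stem,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  list(trials = trials, truths = truths, index = idx)
}
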