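# Shared fixtures, all built in code.

# A noise-free generator parameter set; override fields via ...
quiet_params <- function(...) {
  args <- list(...)
  defaults <- list(noise_sd_angle = 0, noise_sd_moment = 0)
  do.call(generator_params, utils::modifyList(defaults, args))
}

# Full-trial processing with exact settings (no filter, native grid, known
# stance bounds): the configuration used for machine-precision checks.
process_exact <- function(trial) {
  process_trial(trial, stance = c(1, length(trial$time)), n_points = NA,
                lowpass = FALSE)
}

# Exactly closed moment-angle loop: one full cycle of a spring (+ optional
# damper) driven sinusoidally; last point equals the first. Returns the path
# plus three contiguous segment index ranges that cover it (shared endpoints).
make_closed_loop <- function(n = 200, k = 5, c_damp = 0, amplitude = 0.2) {
  t <- seq(0, 2 * pi, length.out = n)
  theta <- amplitude * sin(t)
  moment <- k * theta + c_damp * amplitude * cos(t)
  theta[n] <- theta[1]
  moment[n] <- moment[1]
  a <- floor(n / 4); b <- floor(2 * n / 3)
  list(theta = theta, moment = moment,
       segments = list(1:a, a:b, b:n))
}

# Analyze one generated trial with the default pipeline, returning NULL on
# segmentation failure.
analyze_default <- function(trial, ...) {
  tryCatch(analyze_trial(process_trial(trial, ...)), error = function(e) NULL)
}

# Generate + analyze a cohort in memory with the default pipeline.
analyze_cohort_mem <- function(cohort, ...) {
  rows <- lapply(names(cohort$trials), function(stem) {
    m <- analyze_default(cohort$trials[[stem]], ...)
    if (is.null(m)) return(NULL)
    metrics_row(m)
  })
  do.call(rbind, rows)
}

# Brute-force repeated-measures sums of squares by explicit loops
# (independent oracle for rm_anova).
rm_ss_bruteforce <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + y[i, j]
  grand <- grand / (n * k)
  ss_subj <- 0
  for (i in 1:n) {
    rm_i <- 0
    for (j in 1:k) rm_i <- rm_i + y[i, j]
    rm_i <- rm_i / k
    ss_subj <- ss_subj + k * (rm_i - grand)^2
  }
  ss_cond <- 0
  for (j in 1:k) {
    cm_j <- 0
    for (i in 1:n) cm_j <- cm_j + y[i, j]
    cm_j <- cm_j / n
    ss_cond <- ss_cond + n * (cm_j - grand)^2
  }
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (y[i, j] - grand)^2
  list(ss_subjects = ss_subj, ss_conditions = ss_cond,
       ss_error = ss_tot - ss_subj - ss_cond)
}
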