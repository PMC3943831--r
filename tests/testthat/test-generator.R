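test_that("invalid generator parameters are rejected by name", {
  expect_error(generator_params(theta_toeoff = -2), "theta_toeoff")
  expect_error(generator_params(theta_cp_min = 3), "theta_cp_min")
  expect_error(generator_params(stance_duration = -1), "stance_duration")
  expect_error(generator_params(damping_c = -0.1), "damping_c")
  expect_error(generator_params(noise_sd_angle = -1), "noise_sd_angle")
  expect_error(generator_params(speed_category = "sprint"), "speed_category")
})

test_that("generated trials honour the trajectory contract", {
  p <- quiet_params()
  g <- generate_trial(p)
  tr <- g$trial
  n <- length(tr$time)
  expect_gte(n, 20)
  expect_equal(diff(tr$time), rep(1 / p$sampling_rate, n - 1), tolerance = 1e-12)
  # angle path hits the three extrema, ends at toe-off
  expect_equal(tr$angle_deg[1], 0, tolerance = 1e-12)
  expect_equal(tr$angle_deg[g$truth$cp_end_index], p$theta_cp_min, tolerance = 1e-12)
  expect_equal(tr$angle_deg[g$truth$cd_end_index], p$theta_cd_max, tolerance = 1e-12)
  expect_equal(tr$angle_deg[n], p$theta_toeoff, tolerance = 1e-12)
  # GRF: zero exactly at heel strike / toe-off, positive strictly inside
  expect_identical(tr$grf_n[1], 0)
  expect_identical(tr$grf_n[n], 0)
  expect_true(all(tr$grf_n[2:(n - 1)] > 0))
})

test_that("noise-free moment path is continuous across phase switches", {
  # a continuous path has sample-to-sample steps that shrink in proportion to
  # the sampling interval; a jump at a phase switch would not
  for (p in speed_presets()) {
    p$noise_sd_angle <- 0; p$noise_sd_moment <- 0
    g100 <- generate_trial(p)
    p$sampling_rate <- 1000
    g1k <- generate_trial(p)
    step100 <- max(abs(diff(g100$trial$moment_nm))) / p$body_mass
    m1k <- g1k$trial$moment_nm / p$body_mass
    step1k <- max(abs(diff(m1k)))
    expect_lt(step1k, 0.3 * step100)
    # and specifically at the switch samples
    for (idx in c(g1k$truth$cp_end_index, g1k$truth$cd_end_index)) {
      expect_lt(abs(m1k[idx + 1] - m1k[idx]), 0.3 * step100)
      expect_lt(abs(m1k[idx] - m1k[idx - 1]), 0.3 * step100)
    }
  }
})

test_that("conservative spring trial: CD slope recovered to machine precision, zero net work", {
  p <- quiet_params(damping_c = 0, pushoff_work = 0, k_cd = 5.0)
  g <- generate_trial(p)
  m <- analyze_trial(process_exact(g$trial))
  expect_equal(m$fits$cd$k, 5.0, tolerance = 1e-12)
  expect_equal(m$fits$cd$r_squared, 1.0, tolerance = 1e-12)
  expect_lt(abs(m$work$w_total), 1e-12)
  expect_identical(g$truth$expected_w_total_sign, 0L)
})

test_that("pure damping dissipates (clockwise loop), strong actuator generates", {
  p_damp <- quiet_params(damping_c = 0.05, pushoff_work = 0)
  g <- generate_trial(p_damp)
  expect_identical(g$truth$expected_w_total_sign, -1L)
  m <- analyze_trial(process_exact(g$trial))
  expect_lt(m$work$w_total, 0)

  p_act <- speed_presets()$fast
  p_act$noise_sd_angle <- 0; p_act$noise_sd_moment <- 0
  g2 <- generate_trial(p_act)
  expect_identical(g2$truth$expected_w_total_sign, 1L)
  m2 <- analyze_trial(process_exact(g2$trial))
  expect_gt(m2$work$w_total, 0)
})

test_that("generator energy ledger matches the mechanics pipeline exactly", {
  for (p in speed_presets()) {
    p$noise_sd_angle <- 0; p$noise_sd_moment <- 0
    g <- generate_trial(p)
    m <- analyze_trial(process_exact(g$trial))
    expect_lt(abs(m$work$w_total - g$truth$w_total_true), 1e-9)
    expect_lt(abs(m$work$w_total -
                    (g$truth$injected_work - g$truth$dissipated_work)), 1e-9)
    expect_identical(as.integer(sign(g$truth$w_total_true)),
                     g$truth$expected_w_total_sign)
  }
})

test_that("cohort generation is deterministic and layout-complete", {
  c1 <- generate_cohort(4, trials_per_cell = 2, seed = 11)
  c2 <- generate_cohort(4, trials_per_cell = 2, seed = 11)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$index), 4 * 4 * 2)
  expect_setequal(unique(c1$index$speed_category), names(speed_presets()))

  c3 <- generate_cohort(4, trials_per_cell = 2, seed = 12)
  expect_false(identical(c1$trials, c3$trials))
  # different seeds change realisations, not the preset means
  expect_identical(sort(names(c1$trials)), sort(names(c3$trials)))

  expect_error(generate_cohort(1), "n_subjects")
  expect_error(generate_cohort(3, presets = list()), "presets")
})

test_that("subject random effects preserve the preset means across seeds", {
  k_cd_fast <- sapply(1:20, function(s) {
    co <- generate_cohort(6, seed = 100 + s)
    mean(sapply(co$truths[grep("fast", names(co$truths))], `[[`, "k_cd"))
  })
  expect_equal(mean(k_cd_fast), speed_presets()$fast$k_cd, tolerance = 0.05)
})
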