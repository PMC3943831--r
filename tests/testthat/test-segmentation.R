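test_that("stance detection finds sustained suprathreshold GRF runs", {
  grf <- rep(0, 100)
  grf[10:90] <- 700
  expect_identical(detect_stance(grf, body_mass = 70), c(10L, 90L))
  expect_error(detect_stance(rep(0, 50), 70), "no sustained")
  expect_error(detect_stance(c(-1, rep(700, 30)), 70), "non-negative")
  # short blips below the run-length requirement are ignored
  grf2 <- rep(0, 100); grf2[5] <- 900; grf2[20:80] <- 700
  expect_identical(detect_stance(grf2, 70), c(20L, 80L))
})

test_that("stance bounds on generated GRF are within one sample of the trial span", {
  g <- generate_trial(quiet_params())
  n <- length(g$trial$time)
  b <- detect_stance(g$trial$grf_n, g$trial$body_mass)
  expect_lte(abs(b[1] - 1L), 1L)
  expect_lte(abs(b[2] - n), 1L)
})

test_that("noise-free segmentation recovers the generator's switch indices exactly", {
  for (p in speed_presets()) {
    p$noise_sd_angle <- 0; p$noise_sd_moment <- 0
    g <- generate_trial(p)
    seg <- segment_phases(process_exact(g$trial))
    expect_identical(seg$cp_end, as.integer(g$truth$cp_end_index))
    expect_identical(seg$cd_end, as.integer(g$truth$cd_end_index))
    expect_identical(seg$toe_off, as.integer(g$truth$n_samples))
    expect_true(seg$heel_strike < seg$cp_end)
    expect_true(seg$cp_end < seg$cd_end)
    expect_true(seg$cd_end < seg$toe_off)
    # phase map is contiguous, covers stance, each phase >= 3 samples
    expect_identical(as.integer(table(seg$phase_of)[c("CP", "CD", "PP")]),
                     c(seg$cp_end, seg$cd_end - seg$cp_end,
                       seg$toe_off - seg$cd_end))
    expect_true(all(table(seg$phase_of) >= 3))
  }
})

test_that("degenerate angle traces raise named segmentation errors", {
  g <- generate_trial(quiet_params())
  pt <- process_exact(g$trial)
  # monotone increasing angle: no CP trough
  pt_mono <- pt
  pt_mono$angle_rad <- seq(-0.1, 0.2, length.out = length(pt$angle_rad))
  expect_error(segment_phases(pt_mono), "no CP trough")
  # power forced negative everywhere: no PP onset
  pt_neg <- pt
  pt_neg$power_norm <- -abs(pt$power_norm) - 0.01
  expect_error(segment_phases(pt_neg), "no PP onset")
})

test_that("a single-sample positive power blip does not trigger PP onset", {
  g <- generate_trial(quiet_params())
  pt <- process_exact(g$trial)
  ref <- segment_phases(pt)
  blip <- pt
  j <- ref$cd_end - 4L  # inside CD, within the search window
  blip$power_norm[j] <- 0.05
  seg <- segment_phases(blip, persistence = 3)
  expect_identical(seg$cd_end, ref$cd_end)
})

test_that("segmentation is invariant to uniform moment scaling", {
  g <- generate_trial(generator_params(rng_seed = 21))
  pt <- process_trial(g$trial)
  pt_scaled <- pt
  pt_scaled$moment_norm <- 10 * pt$moment_norm
  pt_scaled$power_norm <- 10 * pt$power_norm
  s1 <- segment_phases(pt)
  s2 <- segment_phases(pt_scaled)
  expect_identical(s1$cp_end, s2$cp_end)
  expect_identical(s1$cd_end, s2$cd_end)
})

test_that("the angle-maximum rule is available and close to the power rule", {
  g <- generate_trial(quiet_params())
  pt <- process_exact(g$trial)
  s_pow <- segment_phases(pt, cd_rule = "power")
  s_ang <- segment_phases(pt, cd_rule = "angle")
  expect_identical(s_ang$cd_end, s_ang$diagnostics$angle_max_index)
  expect_lte(abs(s_pow$cd_end - s_ang$cd_end), 2L)
})

test_that("segmentation under default noise is robust (Monte Carlo)", {
  # 200 noisy trials per run; boundaries compared to the noise-free trial
  # processed identically (isolates noise sensitivity from the systematic,
  # documented passband distortion of the 10 Hz filter)
  p0 <- speed_presets()$normal
  p0$noise_sd_angle <- 0; p0$noise_sd_moment <- 0
  ref <- segment_phases(process_trial(generate_trial(p0)$trial))
  ok <- 0L; within <- 0L
  n_mc <- 200
  for (i in seq_len(n_mc)) {
    p <- speed_presets()$normal
    p$rng_seed <- 5000L + i
    m <- tryCatch(segment_phases(process_trial(generate_trial(p)$trial)),
                  error = function(e) NULL)
    if (!is.null(m)) {
      ok <- ok + 1L
      if (abs(m$cp_end - ref$cp_end) <= 2 && abs(m$cd_end - ref$cd_end) <= 2) {
        within <- within + 1L
      }
    }
  }
  expect_gte(ok / n_mc, 0.95)
  expect_gte(within / n_mc, 0.95)
})
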