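test_that("quasi-stiffness fit is exact on an exact line and guards degeneracy", {
  x <- seq(-0.1, 0.2, length.out = 30)
  y <- 5.0 * x + 0.2
  f <- fit_quasi_stiffness(x, y)
  expect_equal(f$k, 5.0, tolerance = 1e-12)
  expect_equal(f$intercept, 0.2, tolerance = 1e-12)
  expect_identical(f$r_squared, 1)
  expect_identical(f$n_points, 30L)

  expect_error(fit_quasi_stiffness(x[1:2], y[1:2]), "at least 3")
  expect_error(fit_quasi_stiffness(rep(0.1, 10), rnorm(10)), "degenerate")
})

test_that("noisy CD stiffness is recovered without bias (Monte Carlo)", {
  k_hat <- sapply(1:100, function(i) {
    p <- quiet_params(k_cd = 5.0, noise_sd_moment = 0.05, rng_seed = i)
    g <- generate_trial(p)
    m <- analyze_trial(process_exact(g$trial))
    m$fits$cd$k
  })
  expect_lt(abs(mean(k_hat) - 5.0) / 5.0, 0.02)
})

test_that("trapezoidal phase work: rectangle, antisymmetry, conservative loop", {
  theta <- seq(0, 0.5, length.out = 26)
  m <- rep(1, 26)
  expect_equal(phase_work(theta, m), 0.5, tolerance = 1e-12)
  expect_equal(phase_work(rev(theta), rev(m)), -0.5, tolerance = 1e-12)
  expect_error(phase_work(theta[1], m[1]), "at least 2")

  loop <- make_closed_loop(k = 5, c_damp = 0)
  works <- sapply(loop$segments, function(s) phase_work(loop$theta, -loop$moment, s))
  expect_lt(abs(sum(works)), 1e-9)
})

test_that("net loop work follows the |W_PP| - |W_CD| rule", {
  expect_equal(total_work(0.28, 0.33), -0.05, tolerance = 1e-12)
  expect_equal(total_work(0.55, 0.20), 0.35, tolerance = 1e-12)
  expect_identical(total_work(0.3, 0.3), 0)
  expect_error(total_work(-0.1, 0.2), "non-negative")
  expect_error(total_work(0.1, -0.2), "non-negative")
})

test_that("shoelace oracle: unit square orientation and closure gap", {
  sq_x <- c(0, 1, 1, 0); sq_y <- c(0, 0, 1, 1)
  expect_equal(as.numeric(loop_area_oracle(sq_x, sq_y)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(loop_area_oracle(rev(sq_x), rev(sq_y))), -1,
               tolerance = 1e-12)
  open_path <- loop_area_oracle(c(0, 1, 1), c(0, 0, 1))
  expect_equal(attr(open_path, "gap_angle"), 1)
  expect_equal(attr(open_path, "gap_moment"), 1)
})

test_that("shoelace area equals summed per-phase trapezoidal works on closed loops", {
  for (cd in c(0, 0.3, 1)) {
    loop <- make_closed_loop(n = 257, k = 4.2, c_damp = cd)
    works <- sapply(loop$segments, function(s) phase_work(loop$theta, -loop$moment, s))
    area <- as.numeric(loop_area_oracle(loop$theta, loop$moment))
    expect_lt(abs(area - sum(works)), 1e-9)
    if (cd > 0) expect_lt(area, 0)  # damped loop is clockwise (dissipative)
  }
})

test_that("power metrics are the sample peak and mean", {
  pm <- power_metrics(c(-1, 0, 2))
  expect_identical(pm$peak_power, 2)
  expect_equal(pm$mean_stance_power, 1 / 3)
  pm2 <- power_metrics(c(-3, -1, -2))
  expect_identical(pm2$peak_power, -1)
  expect_lt(pm2$mean_stance_power, 0)
  expect_error(power_metrics(numeric(0)), "non-empty")
})

test_that("loop diagnostics report the discrepancy between oracle and work sum", {
  g <- generate_trial(quiet_params())
  m <- analyze_trial(process_exact(g$trial))
  # the stance path is open (heel-strike and toe-off moments differ), so the
  # shoelace area differs from the summed works by the closure segment only
  x <- process_exact(g$trial)
  closure <- -0.5 * (x$moment_norm[1] + x$moment_norm[length(x$moment_norm)]) *
    (x$angle_rad[1] - x$angle_rad[length(x$angle_rad)])
  expect_equal(m$loop$area_minus_summed_work, closure, tolerance = 1e-9)
})

test_that("CD absorbs and PP generates on noise-free trials", {
  for (p in speed_presets()) {
    p$noise_sd_angle <- 0; p$noise_sd_moment <- 0
    m <- analyze_trial(process_exact(generate_trial(p)$trial))
    expect_lt(m$work$w_cd, 0)
    expect_gt(m$work$w_pp, 0)
    expect_equal(m$work$w_total, m$work$abs_w_pp - m$work$abs_w_cd,
                 tolerance = 1e-12)
  }
})
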