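test_that("cohort aggregation matches hand computation", {
  metrics <- data.frame(
    subject_id = rep(c("A", "B"), each = 4),
    speed_category = rep(c("very_slow", "slow", "normal", "fast"), 2),
    k_cd = c(4, 5, 6, 7, 6, 7, 8, 9)
  )
  ct <- aggregate_cohort(metrics, values = "k_cd")
  expect_equal(ct$table$mean, c(5, 6, 7, 8))
  expect_equal(ct$table$sd, rep(sd(c(4, 6)), 4))
  expect_equal(ct$table$n, rep(2L, 4), ignore_attr = TRUE)

  # repeated trials are averaged within subject first
  m2 <- rbind(metrics,
              data.frame(subject_id = "A", speed_category = "slow", k_cd = 9))
  ct2 <- aggregate_cohort(m2, values = "k_cd")
  expect_equal(ct2$table$mean[ct2$table$speed == "slow"], mean(c(mean(c(5, 9)), 7)))

  # subjects missing a speed are dropped with a warning
  m3 <- rbind(metrics,
              data.frame(subject_id = "C", speed_category = "fast", k_cd = 1))
  expect_warning(ct3 <- aggregate_cohort(m3, values = "k_cd"), "complete-case")
  expect_equal(ct3$n_subjects, 2)
  expect_equal(ct3$n_dropped, 1)
  expect_equal(ct3$table$mean, ct$table$mean)
})

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  set.seed(31)
  for (rep in 1:5) {
    y <- matrix(rnorm(80, mean = rep(rnorm(20), 4), sd = 1.3), 20, 4)
    a <- rm_anova(y)
    o <- rm_ss_bruteforce(y)
    expect_lt(abs(a$ss_subjects - o$ss_subjects), 1e-10)
    expect_lt(abs(a$ss_conditions - o$ss_conditions), 1e-10)
    expect_lt(abs(a$ss_error - o$ss_error), 1e-10)
    expect_identical(a$df_effect, 3)
    expect_identical(a$df_error, 57)
  }
})

test_that("rm_anova agrees with stats::aov on the same decomposition", {
  set.seed(5)
  y <- matrix(rnorm(48, sd = 2), 12, 4)
  a <- rm_anova(y)
  df <- data.frame(y = c(y), s = factor(rep(1:12, 4)),
                   cond = factor(rep(1:4, each = 12)))
  fit <- summary(stats::aov(y ~ cond + Error(s / cond), df))
  tab <- fit[["Error: s:cond"]][[1]]
  expect_equal(a$F, tab$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p, tab$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("rm_anova null identity and subject-shift invariance", {
  y <- matrix(rep(c(1, 2, 5, 9), each = 6), 6, 4, byrow = FALSE)
  # every subject identical across conditions
  y_flat <- matrix(rep(1:6, 4), 6, 4)
  a_flat <- rm_anova(y_flat)
  expect_identical(a_flat$F, 0)
  expect_identical(a_flat$p, 1)

  set.seed(8)
  y2 <- matrix(rnorm(40), 10, 4)
  a1 <- rm_anova(y2)
  a2 <- rm_anova(y2 + rnorm(10) %o% rep(1, 4) * 100)
  expect_equal(a1$F, a2$F, tolerance = 1e-8)

  expect_error(rm_anova(matrix(c(1, NA, 3, 4), 2, 2)), "complete")
  expect_error(rm_anova(matrix(1:4, 1, 4)), "2 subjects")
})

test_that("Bonferroni-adjusted pairwise p values are valid and ordered", {
  set.seed(13)
  y <- matrix(rnorm(60, mean = rep(c(0, 0.2, 0.7, 1), each = 15)), 15, 4)
  a <- rm_anova(y)
  expect_equal(nrow(a$pairwise), 6)
  expect_true(all(a$pairwise$p_bonferroni >= a$pairwise$p_raw))
  expect_true(all(a$pairwise$p_bonferroni <= 1))
  expect_equal(pmin(1, a$pairwise$p_raw * 6), a$pairwise$p_bonferroni)
})

test_that("rm_anova type-I error is calibrated at alpha = 0.05", {
  set.seed(99)
  n_sim <- 400  # quick suite-level check; the acceptance run uses 2000
  rej <- mean(replicate(n_sim, {
    y <- matrix(rnorm(80), 20, 4) + rnorm(20)
    rm_anova(y)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("KS normality check behaves at both extremes", {
  # sample placed at the fitted normal's quantiles: near-perfect fit
  x <- qnorm((1:40) / 41, mean = 3, sd = 2)
  r <- ks_normality(x)
  expect_lt(r$D, 0.05)
  expect_gt(r$p, 0.9)
  expect_identical(r$method, "ks_parameters_estimated")

  # strongly non-normal data are rejected in nearly every draw
  hits <- sapply(1:50, function(i) {
    set.seed(i)
    ks_normality(rexp(200))$p < 0.05
  })
  expect_gte(mean(hits), 0.95)

  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "zero variance")

  r2 <- ks_normality(x, method = "lilliefors")
  expect_identical(r2$method, "lilliefors")
  expect_true(r2$p >= 0 && r2$p <= 1)
})

test_that("Greenhouse-Geisser epsilon is bounded and reduces significance", {
  set.seed(17)
  y <- matrix(rnorm(48), 12, 4)
  a0 <- rm_anova(y)
  a1 <- rm_anova(y, gg_correction = TRUE)
  expect_gte(a1$epsilon, 1 / 3)
  expect_lte(a1$epsilon, 1)
  expect_gte(a1$p, a0$p)
})
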