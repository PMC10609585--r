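test_that("Shapiro-Wilk wrapper behaves on normal, bimodal, constant data", {
  set.seed(1)
  # normal data: median p across repeats comfortably above alpha
  ps <- replicate(41, shapiro_wilk(stats::rnorm(100))$p)
  expect_gt(stats::median(ps), 0.2)
  # two point masses at n = 12: decisively non-normal
  expect_lt(shapiro_wilk(rep(c(0, 1), 6))$p, 0.05)
  # constant vector: degenerate, inapplicable
  deg <- shapiro_wilk(rep(3, 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(shapiro_wilk(c(1, 2)), "n")
})

test_that("Levene matches one-way ANOVA on absolute deviations", {
  set.seed(2)
  g <- rep(letters[1:4], each = 3)
  y <- stats::rnorm(12, sd = rep(c(1, 1, 1, sqrt(10)), each = 3))
  lv <- levene_test(y, g)
  z <- abs(y - stats::ave(y, g))
  fit <- stats::anova(stats::lm(z ~ factor(g)))
  expect_equal(lv$F, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p, fit$`Pr(>F)`[1], tolerance = 1e-10)
  # against the established implementation too
  cv <- car::leveneTest(y, factor(g), center = mean)
  expect_equal(lv$F, cv$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p, cv$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene is scale-invariant and null on equal spreads", {
  y <- c(1, 2, 3, 11, 12, 13)   # identical within-group spread
  g <- rep(c("a", "b"), each = 3)
  lv <- levene_test(y, g)
  expect_equal(lv$F, 0)
  expect_equal(lv$p, 1)
  set.seed(3)
  y2 <- stats::rnorm(12); g2 <- rep(1:3, each = 4)
  expect_equal(levene_test(y2, g2)$F, levene_test(100 * y2, g2)$F,
               tolerance = 1e-12)
  expect_error(levene_test(1:3, c("a", "a", "b")), "2 groups")
})

test_that("two-way ANOVA matches the linear-model projection oracle", {
  set.seed(4)
  for (i in 1:30) {
    d <- random_factorial(r = 3, effect_a = stats::rnorm(1),
                          effect_b = stats::rnorm(1),
                          effect_ab = stats::rnorm(1))
    rep_ <- suppressWarnings(two_way_anova(d))
    or <- lm_anova_oracle(d)
    expect_equal(rep_$effects$ss, or$ss, tolerance = 1e-10)
    expect_equal(rep_$effects$F, or$f, tolerance = 1e-10)
    expect_equal(rep_$effects$p, or$p, tolerance = 1e-10)
    expect_equal(rep_$error$ss, or$ss_err, tolerance = 1e-10)
    # SS additivity on the balanced decomposition
    expect_equal(sum(rep_$effects$ss) + rep_$error$ss, rep_$ss_total,
                 tolerance = 1e-9)
  }
})

test_that("degenerate factorial datasets are handled", {
  # all values equal: no variance anywhere
  d <- factorial_dataset(rep(5, 12), rep(c("lo", "hi"), 6),
                         rep(c("lo", "hi"), each = 6))
  rep_ <- two_way_anova(d)
  expect_equal(rep_$effects$F, rep(0, 3))
  expect_equal(rep_$effects$p, rep(1, 3))
  expect_true(rep_$assumptions$shapiro$degenerate)

  # pure interaction with zero within-cell noise: p -> 0
  y <- rep(c(0, 0, 0, 1), each = 3)
  a <- rep(rep(c("lo", "hi"), each = 3), 2)
  b <- rep(c("lo", "hi"), each = 6)
  d2 <- factorial_dataset(y, a, b)
  rep2 <- two_way_anova(d2)
  expect_equal(rep2$error$ss, 0)
  expect_equal(rep2$effects$p[rep2$effects$effect == "A:B"], 0)
  expect_true(is.na(rep2$effects$omega_g[1]))  # undefined at MS_error = 0

  expect_error(factorial_dataset(1:11, rep(c("lo", "hi"), c(5, 6)),
                                 rep(c("lo", "hi"), c(6, 5))),
               "balanced|levels")
})

test_that("generalized omega-squared behaves at the limits", {
  set.seed(5)
  # null effect: omega_g slightly negative, displayed clamped at 0
  d <- random_factorial(r = 3)
  rep_ <- suppressWarnings(two_way_anova(d))
  expect_true(all(rep_$effects$omega_g_display >= 0))
  idx <- which(rep_$effects$ss < rep_$error$ms)
  expect_true(all(rep_$effects$omega_g[idx] < 0))
  expect_true(all(rep_$effects$omega_g_display[idx] == 0))

  # huge effect, tiny error: omega_g -> 1 from below
  d2 <- random_factorial(r = 3, effect_a = 100, sd = 0.01)
  rep2 <- suppressWarnings(two_way_anova(d2))
  og <- rep2$effects$omega_g[1]
  expect_gt(og, 0.999)
  expect_lt(og, 1)

  # omega_g never exceeds eta-squared on the same decomposition
  for (i in 1:20) {
    d3 <- random_factorial(r = 3, effect_a = stats::rnorm(1, 0, 2))
    r3 <- suppressWarnings(two_way_anova(d3))
    expect_true(all(r3$effects$omega_g <= r3$effects$eta_sq + 1e-12))
  }
})

test_that("omega_g mean tracks its large-sample value in simulation", {
  # effect delta at noise sd 1 in a 2x2xr design: population generalized
  # omega^2 = (delta^2/4) / (delta^2/4 + 1)
  set.seed(6)
  delta <- 4; r <- 6
  target <- (delta^2 / 4) / (delta^2 / 4 + 1)
  og <- replicate(400, {
    d <- random_factorial(r = r, effect_a = delta)
    suppressWarnings(two_way_anova(d))$effects$omega_g[1]
  })
  expect_equal(mean(og), target, tolerance = 0.03)
})

test_that("effects table pairs every significant p with a shown omega", {
  set.seed(8)
  reports <- lapply(1:5, function(i) {
    d <- random_factorial(r = 3, effect_a = 3 * (i %% 2))
    suppressWarnings(two_way_anova(d))
  })
  names(reports) <- paste0("resp", 1:5)
  tab <- build_effects_table(reports, c("CO2", "T"))
  expect_equal(nrow(tab), 5)
  for (lab in c("CO2", "T", "CO2xT")) {
    p <- tab[[paste0("p_", lab)]]
    om <- tab[[paste0("omega_", lab)]]
    expect_true(all(!is.na(om[p < 0.05])))   # shown where significant
    expect_true(all(is.na(om[p >= 0.05])))   # suppressed otherwise
  }
  expect_equal(nrow(build_effects_table(list())), 0)
})

test_that("permutation p-values agree with F-test p-values", {
  set.seed(9)
  for (i in 1:5) {
    d <- random_factorial(r = 3, effect_a = stats::rnorm(1))
    rep_ <- suppressWarnings(two_way_anova(d))
    f_obs <- rep_$effects$F[1]
    perm <- replicate(2000, {
      d2 <- d; d2$y <- sample(d2$y)
      suppressWarnings(two_way_anova(d2))$effects$F[1]
    })
    p_perm <- mean(perm >= f_obs)
    expect_lt(abs(p_perm - rep_$effects$p[1]), 0.03)
  }
})
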