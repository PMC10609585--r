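test_that("specific growth rate is ln(1 + production/biomass)", {
  expect_equal(specific_growth_rate(0, 10), 0)
  expect_equal(specific_growth_rate((exp(1) - 1) * 21.9, 21.9), 1)
  # ambient assemblage means: ln(1 + 64.282/21.90)
  expect_equal(specific_growth_rate(64.282, 21.90), 1.370, tolerance = 1e-3)
  # monotone in production at fixed biomass
  p <- sort(stats::runif(20, 0, 100))
  expect_true(all(diff(specific_growth_rate(p, 21.9)) > 0))
  expect_error(specific_growth_rate(10, 0), "biomass")
})

test_that("net growth rate is log-ratio over time, antisymmetric", {
  expect_equal(net_growth_rate(1e9, 1e9, 2), 0)
  expect_equal(net_growth_rate(1e9, 2e9, 1), log(2))
  expect_equal(net_growth_rate(2.43e9, 3.49e9, 2), 0.181, tolerance = 1e-2)
  n0 <- stats::runif(10, 1e8, 1e10); nt <- stats::runif(10, 1e8, 1e10)
  expect_equal(net_growth_rate(n0, nt, 2), -net_growth_rate(nt, n0, 2))
  expect_error(net_growth_rate(0, 1e9, 2))
  expect_error(net_growth_rate(1e9, 1e9, 0))
})

test_that("mortality rate is SGR - NGR", {
  expect_equal(mortality_rate(1.321, -0.120), 1.441)
  expect_equal(mortality_rate(1.006, -0.115), 1.121)
  x <- stats::runif(5)
  expect_equal(mortality_rate(x, x), rep(0, 5))
  expect_error(mortality_rate(Inf, 1))
})

test_that("MR:SGR ratio indexes top-down control", {
  expect_equal(mr_sgr_ratio(1.44, 1.32), 1.09, tolerance = 1e-2)
  expect_equal(mr_sgr_ratio(0, 2), 0)
  expect_equal(mr_sgr_ratio(0.307, 0.484), 0.634, tolerance = 1e-3)
  expect_warning(val <- mr_sgr_ratio(0.5, 0), "undefined")
  expect_true(is.na(val))
})

test_that("rate identity MR + NGR = SGR holds on random replicate tables", {
  set.seed(7)
  for (i in 1:25) {
    df <- data.frame(
      treatment = rep(c("control", "X"), each = 3),
      replicate = rep(1:3, 2),
      n0 = stats::runif(6, 1e8, 5e9),
      nt = stats::runif(6, 1e8, 5e9),
      production = stats::runif(6, 0, 100),
      biomass = stats::runif(6, 5, 150))
    tr <- treatment_rates(df, t = 2)
    expect_equal(tr$replicates$mr + tr$replicates$ngr, tr$replicates$sgr,
                 tolerance = 1e-12)
    # identity survives averaging to treatment means
    expect_equal(tr$summary$mr_mean + tr$summary$ngr_mean,
                 tr$summary$sgr_mean, tolerance = 1e-12)
  }
})

test_that("treatment summaries are means of per-replicate rates with se", {
  df <- data.frame(treatment = "control", replicate = 1:3,
                   n0 = c(1e9, 1.1e9, 0.9e9), nt = c(2e9, 1.9e9, 2.1e9),
                   production = c(50, 60, 55), biomass = c(20, 25, 22))
  tr <- treatment_rates(df, t = 2)
  expect_equal(tr$summary$sgr_mean, mean(tr$replicates$sgr))
  expect_equal(tr$summary$sgr_se,
               stats::sd(tr$replicates$sgr) / sqrt(3))
  expect_error(treatment_rates(df[, -3], t = 2), "missing columns")
})
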