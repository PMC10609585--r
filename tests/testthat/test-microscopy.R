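test_that("abundance follows mean count x area ratio / volume", {
  obs <- count_observation(rep(1, 60), filter_area_ratio = 1,
                           volume_filtered = 1)
  expect_equal(suppressWarnings(abundance_from_counts(obs)), 1)

  obs <- count_observation(rep(8, 60), filter_area_ratio = 1e5,
                           volume_filtered = 0.001)
  expect_equal(suppressWarnings(abundance_from_counts(obs)), 8e8)
})

test_that("sparse slides warn but still yield an estimate", {
  empty <- count_observation(rep(0, 50), 1e5, 0.001)
  expect_warning(val <- abundance_from_counts(empty), "400")
  expect_equal(val, 0)

  few_fields <- count_observation(rep(20, 30), 1e5, 0.001)
  expect_warning(abundance_from_counts(few_fields), "fields")
})

test_that("count observation rejects bad geometry", {
  expect_error(count_observation(rep(1, 50), 1e5, 0), "volume")
  expect_error(count_observation(rep(1, 50), -1, 0.001), "ratio")
  expect_error(count_observation(numeric(0), 1e5, 0.001))
})

test_that("allometric cell carbon matches the power law", {
  expect_equal(cell_carbon(1), 0.12)
  expect_equal(cell_carbon(0.1), 0.12 * 0.1^0.72, tolerance = 1e-12)
  expect_equal(cell_carbon(0.1), 0.02287, tolerance = 1e-3)
  # log-space evaluation agreement
  cvs <- c(0.01, 0.05, 0.1, 0.5, 1, 2)
  expect_equal(cell_carbon(cvs), exp(log(0.12) + 0.72 * log(cvs)),
               tolerance = 1e-12)
  # monotone in volume
  expect_true(all(diff(cell_carbon(sort(stats::runif(20, 0.01, 2)))) > 0))
  expect_error(cell_carbon(0), "positive")
  expect_error(cell_carbon_model(coefficient = -1))
})

test_that("biomass is abundance x mean cell carbon x 1e-9 and bilinear", {
  expect_equal(biomass(0, 123), 0)
  expect_equal(biomass(1e9, 20), 20)
  # consistency with reported assemblage state (per-cell carbon in fg)
  expect_equal(biomass(8.53e8, 25.67), 21.90, tolerance = 2e-4)
  a <- stats::runif(10, 1e8, 1e10); cc <- stats::runif(10, 5, 50)
  expect_equal(biomass(2 * a, cc), 2 * biomass(a, cc))
  expect_equal(biomass(a, 2 * cc), 2 * biomass(a, cc))
  expect_error(biomass(-1, 20))
})
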