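test_that("exponential dynamics are exact", {
  p <- true_treatment_params("x", sgr_true = 0.8, mr_true = 0.8,
                             n0_true = 1e9)
  expect_equal(simulate_dynamics(p, 3.7), 1e9)          # balanced growth

  p2 <- true_treatment_params("x", sgr_true = log(2), mr_true = 0,
                              n0_true = 1e9)
  expect_equal(simulate_dynamics(p2, 1), 2e9)           # doubling

  # ambient-like rates over a 2-day incubation: N0 * exp(-0.24)
  p3 <- true_treatment_params("x", sgr_true = 1.321, mr_true = 1.441,
                              n0_true = 1e9)
  expect_equal(simulate_dynamics(p3, 2), 1e9 * exp(-0.24))
  expect_equal(simulate_dynamics(p3, 2), 7.866e8, tolerance = 1e-4)

  expect_error(simulate_dynamics(p3, -1), "t")
  expect_error(true_treatment_params("x", -0.1, 0.2, 1e9))
  expect_error(true_treatment_params("x", 0.1, 0.2, 0))
})

test_that("same seed regenerates a bit-identical experiment", {
  tr <- experiment_truths("co2_uvr")
  noise <- observation_noise_model()
  e1 <- simulate_experiment(tr$design, tr$truths, noise, seed = 11)
  e2 <- simulate_experiment(tr$design, tr$truths, noise, seed = 11)
  expect_identical(e1$samples, e2$samples)
  e3 <- simulate_experiment(tr$design, tr$truths, noise, seed = 12)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("noiseless generation round-trips truths through the pipeline", {
  for (preset in c("co2_uvr", "co2_t")) {
    tr <- experiment_truths(preset)
    ex <- simulate_experiment(tr$design, zero_cv_truths(tr$truths),
                              noiseless_model(), seed = 1)
    b <- run_pipeline(ex)
    truth <- do.call(rbind, lapply(tr$truths, function(p)
      data.frame(treatment = p$treatment_label, sgr = p$sgr_true,
                 mr = p$mr_true)))
    got <- b$rates$summary[match(truth$treatment,
                                 b$rates$summary$treatment), ]
    expect_equal(got$sgr_mean, truth$sgr, tolerance = 1e-6)
    expect_equal(got$mr_mean, truth$mr, tolerance = 1e-6)
    expect_equal(got$ngr_mean, truth$sgr - truth$mr, tolerance = 1e-6)
  }
})

test_that("expected total cells counted matches the counting geometry", {
  # large-sample average over many seeds, single treatment
  design <- microcosm_design("CO2", "UVR", replicates = 2)
  p <- true_treatment_params("control", 0.5, 0.3, 1e9)
  truths <- list(p,
                 true_treatment_params("CO2", 0.5, 0.3, 1e9),
                 true_treatment_params("UVR", 0.5, 0.3, 1e9),
                 true_treatment_params("CO2+UVR", 0.5, 0.3, 1e9))
  noise <- observation_noise_model()
  tot <- vapply(1:120, function(s) {
    ex <- simulate_experiment(design, truths, noise, seed = s)
    t0 <- ex$samples[ex$samples$timepoint == 0 &
                       ex$samples$treatment == "control" &
                       ex$samples$replicate == 1, ]
    sum(t0$cells_in_field)
  }, numeric(1))
  expected <- 1e9 * noise$volume_filtered / noise$filter_area_ratio *
    noise$fields_per_slide
  expect_equal(mean(tot), expected, tolerance = 0.02)
})

test_that("configurations that cannot reach the counting minimum warn", {
  tr <- experiment_truths("co2_uvr")
  thin <- observation_noise_model(volume_filtered = 1e-6)
  warns <- capture_warnings(
    simulate_experiment(tr$design, tr$truths, thin, seed = 1))
  expect_true(any(grepl("protocol minimum", warns)))
})

test_that("truths must cover every treatment exactly once", {
  tr <- experiment_truths("co2_uvr")
  expect_error(
    simulate_experiment(tr$design, tr$truths[1:3],
                        observation_noise_model(), seed = 1),
    "one parameter set per treatment")
})
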