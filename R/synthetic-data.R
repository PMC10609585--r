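#' Synthetic microcosm experiments with known ground truth
#'
#' Generates complete two-factor microcosm experiments — microscopy field
#' counts, cell biovolumes, scintillation DPM, and carbonate-chemistry
#' columns — from known per-treatment growth and mortality rates, so every
#' downstream estimator can be tested against truth. Abundance follows
#' exponential dynamics `N(t) = N0 * exp((SGR - MR) * t)`; observation noise
#' is Poisson per microscopy field, lognormal for biovolumes, and
#' multiplicative Gaussian for DPM. The DPM signal is the exact inverse of
#' the leucine estimator arithmetic, so with all noise switched off the
#' pipeline recovers the truths to numerical precision.
#'
#' @name synthetic_data
NULL

#' Define a balanced two-factor microcosm design
#'
#' Four treatments crossing two levels of each factor, each replicated.
#' Carbonate-chemistry columns (pH, TA, temperature, salinity) are carried
#' per treatment so the generated sheet is speciation-ready.
#'
#' @param factor_a,factor_b factor names (e.g. `"CO2"`, `"UVR"`, `"T"`).
#' @param replicates replicates per treatment (>= 2).
#' @param incubation_days incubation length, days (> 0), default 2.
#' @param label experiment label written into the sample sheet.
#' @param ph,ta_umol_kg,temp_c,salinity length-4 vectors (one value per
#'   treatment, order control / A / B / A+B) or scalars recycled.
#' @return A `microcosm_design` object.
#' @export
microcosm_design <- function(factor_a = "CO2", factor_b = "UVR",
                             replicates = 3, incubation_days = 2,
                             label = "exp",
                             ph = c(8.1, 7.9, 8.1, 7.9),
                             ta_umol_kg = 2300, temp_c = 13,
                             salinity = 35.5) {
  stopifnot(replicates >= 2, incubation_days > 0)
  treatments <- data.frame(
    treatment = c("control", factor_a, factor_b,
                  paste0(factor_a, "+", factor_b)),
    level_a = c("ambient", "high", "ambient", "high"),
    level_b = c("ambient", "ambient", "high", "high"),
    ph = rep_len(ph, 4), ta_umol_kg = rep_len(ta_umol_kg, 4),
    temp_c = rep_len(temp_c, 4), salinity = rep_len(salinity, 4),
    stringsAsFactors = FALSE
  )
  structure(
    list(label = label, factor_a = factor_a, factor_b = factor_b,
         replicates = as.integer(replicates),
         incubation_days = incubation_days, treatments = treatments),
    class = "microcosm_design"
  )
}

#' Ground-truth parameters for one treatment
#'
#' @param treatment_label treatment name matching the design.
#' @param sgr_true specific instantaneous growth rate, d^-1 (>= 0).
#' @param mr_true mortality rate, d^-1 (>= 0).
#' @param n0_true initial abundance, cells L^-1 (> 0).
#' @param mean_cell_volume mean cell biovolume, um^3 (> 0).
#' @param cv_cell_volume coefficient of variation of biovolumes (>= 0).
#' @return A `true_treatment_params` object.
#' @export
true_treatment_params <- function(treatment_label, sgr_true, mr_true,
                                  n0_true, mean_cell_volume = 0.1,
                                  cv_cell_volume = 0.35) {
  vals <- c(sgr_true = sgr_true, mr_true = mr_true, n0_true = n0_true,
            mean_cell_volume = mean_cell_volume,
            cv_cell_volume = cv_cell_volume)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all truth parameters must be finite and non-negative")
  if (n0_true <= 0 || mean_cell_volume <= 0)
    stop("`n0_true` and `mean_cell_volume` must be > 0")
  structure(
    list(treatment_label = treatment_label, sgr_true = sgr_true,
         mr_true = mr_true, n0_true = n0_true,
         mean_cell_volume = mean_cell_volume,
         cv_cell_volume = cv_cell_volume),
    class = "true_treatment_params"
  )
}

#' Observation-noise and protocol model
#'
#' Defaults describe a realistic epifluorescence + leucine protocol: 60
#' random fields per slide, 0.5 mL filtered, a filtration-to-field area
#' ratio of 2.5e4, 5 mL assay aliquots incubated 2 h with isotope of
#' specific activity 304 uCi umol^-1, 40 DPM killed blanks, and 8%
#' multiplicative scintillation noise. `counting_noise = FALSE` replaces
#' the Poisson/lognormal microscopy draws by their exact expectations
#' (used, with zero DPM noise and zero blanks, for noiseless round-trips).
#'
#' @param fields_per_slide microscopy fields per slide (>= 50).
#' @param min_cells_total protocol minimum total cells per slide.
#' @param filter_area_ratio filtration area / field area (> 0).
#' @param volume_filtered volume filtered per slide, litres (> 0).
#' @param leu_specific_activity isotope specific activity, uCi umol^-1.
#' @param leu_incubation_hours assay incubation, hours.
#' @param leu_sample_volume assay aliquot, litres.
#' @param leu_to_carbon leucine-to-carbon factor, kg C mol^-1.
#' @param dpm_blank_mean mean killed-blank DPM (>= 0).
#' @param dpm_noise_cv multiplicative CV of DPM readings (>= 0).
#' @param counting_noise draw Poisson counts and lognormal biovolumes
#'   (`TRUE`) or use exact expectations (`FALSE`).
#' @return An `observation_noise_model` object.
#' @export
observation_noise_model <- function(fields_per_slide = 60,
                                    min_cells_total = 400,
                                    filter_area_ratio = 2.5e4,
                                    volume_filtered = 5e-4,
                                    leu_specific_activity = 304,
                                    leu_incubation_hours = 2,
                                    leu_sample_volume = 0.005,
                                    leu_to_carbon = 1.5,
                                    dpm_blank_mean = 40,
                                    dpm_noise_cv = 0.08,
                                    counting_noise = TRUE) {
  if (fields_per_slide < 50)
    stop("`fields_per_slide` must be >= 50 (counting protocol minimum)")
  stopifnot(filter_area_ratio > 0, volume_filtered > 0,
            leu_specific_activity > 0, leu_incubation_hours > 0,
            leu_sample_volume > 0, leu_to_carbon > 0,
            dpm_blank_mean >= 0, dpm_noise_cv >= 0,
            is.logical(counting_noise))
  structure(
    list(fields_per_slide = as.integer(fields_per_slide),
         min_cells_total = min_cells_total,
         filter_area_ratio = filter_area_ratio,
         volume_filtered = volume_filtered,
         leu_specific_activity = leu_specific_activity,
         leu_incubation_hours = leu_incubation_hours,
         leu_sample_volume = leu_sample_volume,
         leu_to_carbon = leu_to_carbon,
         dpm_blank_mean = dpm_blank_mean,
         dpm_noise_cv = dpm_noise_cv,
         counting_noise = counting_noise),
    class = "observation_noise_model"
  )
}

#' Exponential growth-mortality dynamics
#'
#' `N(t) = N0 * exp((SGR - MR) * t)`, exact, no noise.
#'
#' @param params a [true_treatment_params()].
#' @param t time, days (>= 0, vectorised).
#' @return True abundance, cells L^-1.
#' @export
simulate_dynamics <- function(params, t) {
  stopifnot(inherits(params, "true_treatment_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be >= 0 days")
  params$n0_true * exp((params$sgr_true - params$mr_true) * t)
}

#' Preset ground truths for the two winter-lagoon experiment layouts
#'
#' Treatment means for the CO2 x UVR and CO2 x temperature experiments:
#' SGR as tabulated, MR taken as SGR - NGR so the exponential dynamics are
#' internally consistent. Initial abundances and mean biovolumes match the
#' reported source-water states (biovolumes back-computed from mean cell
#' carbon through the allometry).
#'
#' @param which `"co2_uvr"` or `"co2_t"`.
#' @return List with elements `design` and `truths`.
#' @export
experiment_truths <- function(which = c("co2_uvr", "co2_t")) {
  which <- match.arg(which)
  if (which == "co2_uvr") {
    design <- microcosm_design("CO2", "UVR", label = "co2_uvr",
                               temp_c = 13)
    sgr <- c(1.321, 1.237, 0.757, 0.458)
    ngr <- c(-0.120, -0.160, 0.018, 0.198)
    n0 <- 1.11e9
    mcv <- 0.117
  } else {
    design <- microcosm_design("CO2", "T", label = "co2_t",
                               temp_c = c(10, 10, 13, 13))
    sgr <- c(0.484, 0.409, 1.006, 0.891)
    ngr <- c(0.177, 0.187, -0.115, -0.068)
    n0 <- 2.43e9
    mcv <- 0.245
  }
  truths <- Map(function(lbl, s, g) {
    true_treatment_params(lbl, sgr_true = s, mr_true = s - g,
                          n0_true = n0, mean_cell_volume = mcv)
  }, design$treatments$treatment, sgr, ngr)
  list(design = design, truths = unname(truths))
}

# Lognormal draws with a given arithmetic mean and CV.
rlnorm_meancv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a complete microcosm experiment
#'
#' Draws one sample sheet (one row per microscopy field) for every
#' replicate of every treatment at the start and end of the incubation.
#' All randomness comes from a single stream seeded once with `seed`;
#' draws occur in a fixed documented order (treatments in design order,
#' replicates within treatment, start before end within a unit; within a
#' unit-timepoint: field counts, then biovolumes, then sample DPM, then
#' blank DPM), so regeneration with the same arguments is bit-identical.
#'
#' The DPM signal inverts the production estimator: true production is
#' `P = B_end * (exp(SGR) - 1)` with `B_end` the true end biomass, mapped
#' backwards through the leucine arithmetic to a net DPM, added to the
#' blank, and jittered multiplicatively.
#'
#' @param design a [microcosm_design()].
#' @param truths list of [true_treatment_params()], one per treatment.
#' @param noise an [observation_noise_model()].
#' @param seed integer master seed.
#' @param cc_model [cell_carbon_model()] used to map biovolume to carbon
#'   (pg; converted to fg internally) when inverting the leucine signal.
#' @return A `synthetic_experiment` with the design, truths, noise, seed
#'   and `$samples` (the sample-sheet data frame).
#' @export
simulate_experiment <- function(design, truths, noise, seed,
                                cc_model = cell_carbon_model()) {
  stopifnot(inherits(design, "microcosm_design"),
            inherits(noise, "observation_noise_model"))
  if (length(seed) != 1 || !is.finite(seed))
    stop("a single integer `seed` is required")
  labels <- vapply(truths, function(p) p$treatment_label, character(1))
  if (!identical(sort(labels), sort(design$treatments$treatment)))
    stop("`truths` must supply exactly one parameter set per treatment")
  truths <- truths[match(design$treatments$treatment, labels)]

  set.seed(as.integer(seed))
  t_end <- design$incubation_days
  nf <- noise$fields_per_slide
  rows <- vector("list", 4L * design$replicates * 2L)
  i <- 0L
  for (ti in seq_len(nrow(design$treatments))) {
    tr <- design$treatments[ti, ]
    p <- truths[[ti]]
    for (rep_i in seq_len(design$replicates)) {
      for (tp in c(0, t_end)) {
        n_true <- simulate_dynamics(p, tp)
        lambda <- n_true * noise$volume_filtered / noise$filter_area_ratio
        if (lambda * nf < noise$min_cells_total)
          warning(sprintf(
            "treatment %s t=%g: expected %.0f cells in %d fields (< %g protocol minimum)",
            tr$treatment, tp, lambda * nf, nf, noise$min_cells_total),
            call. = FALSE)
        counts <- if (noise$counting_noise) stats::rpois(nf, lambda)
                  else rep(lambda, nf)
        vols <- if (noise$counting_noise)
          rlnorm_meancv(nf, p$mean_cell_volume, p$cv_cell_volume)
        else rep(p$mean_cell_volume, nf)
        if (tp > 0) {
          cc_fg <- 1000 * cell_carbon(p$mean_cell_volume, cc_model)
          b_end <- biomass(n_true, cc_fg)                    # ugC/L
          prod_true <- b_end * expm1(p$sgr_true)             # ugC/L/d
          leu_nmol_h <- prod_true / noise$leu_to_carbon / 24
          net_dpm <- leu_nmol_h * 1e-3 * DPM_PER_UCI *
            noise$leu_specific_activity * noise$leu_incubation_hours *
            noise$leu_sample_volume
          dpm_s <- pmax(0, noise$dpm_blank_mean + net_dpm *
                          (1 + stats::rnorm(3, 0, noise$dpm_noise_cv)))
          dpm_b <- pmax(0, noise$dpm_blank_mean *
                          (1 + stats::rnorm(3, 0, noise$dpm_noise_cv)))
        } else {
          dpm_s <- dpm_b <- rep(NA_real_, 3)
        }
        i <- i + 1L
        rows[[i]] <- data.frame(
          experiment = design$label, treatment = tr$treatment,
          replicate = rep_i, timepoint = tp,
          field_index = seq_len(nf), cells_in_field = counts,
          mean_cell_volume_um3 = vols,
          dpm_sample_1 = dpm_s[1], dpm_sample_2 = dpm_s[2],
          dpm_sample_3 = dpm_s[3],
          dpm_blank_1 = dpm_b[1], dpm_blank_2 = dpm_b[2],
          dpm_blank_3 = dpm_b[3],
          ph = tr$ph, ta_umol_kg = tr$ta_umol_kg,
          temp_c = tr$temp_c, salinity = tr$salinity,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(design = design, truths = truths, noise = noise,
         seed = as.integer(seed), samples = do.call(rbind, rows)),
    class = "synthetic_experiment"
  )
}
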