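#' End-to-end microcosm pipeline
#'
#' Orchestrates sample-sheet reduction (microscopy + leucine), rate
#' estimation, factorial effect testing, and carbonate bookkeeping, writing
#' a deterministic report bundle: derived-state, per-replicate and summary
#' rate tables, an effects table, a carbonate summary, and a run log.
#'
#' @name pipeline
NULL

#' Required sample-sheet columns
#'
#' One row per microscopy field; DPM and chemistry columns are constant
#' within an experimental unit and timepoint (DPM may be NA where no
#' production assay was run, e.g. at the start of the incubation).
#' @export
SAMPLE_SHEET_COLUMNS <- c(
  "experiment", "treatment", "replicate", "timepoint", "field_index",
  "cells_in_field", "mean_cell_volume_um3",
  "dpm_sample_1", "dpm_sample_2", "dpm_sample_3",
  "dpm_blank_1", "dpm_blank_2", "dpm_blank_3",
  "ph", "ta_umol_kg", "temp_c", "salinity")

#' Pipeline run configuration
#'
#' Every default is a protocol constant documented in the module it feeds:
#' the allometric carbon model, counting geometry, leucine assay constants,
#' incubation length, and the significance / large-effect thresholds.
#'
#' @param incubation_days incubation length, days.
#' @param cc_coefficient,cc_exponent allometric volume-to-carbon model
#'   (pg C at unit um^3, see [cell_carbon()]).
#' @param filter_area_ratio,volume_filtered counting geometry, see
#'   [count_observation()].
#' @param leu_specific_activity,leu_incubation_hours,leu_sample_volume,leu_to_carbon
#'   leucine assay constants, see [leucine_assay()].
#' @param volume_averaging `"volume_then_carbon"` (average biovolumes, then
#'   convert; default) or `"carbon_then_average"` (convert per cell, then
#'   average).
#' @param sgr_biomass pair production with `"end"` (default) or `"start"`
#'   biomass in the SGR.
#' @param alpha significance level.
#' @param omega_threshold large-effect threshold on generalized
#'   omega-squared.
#' @param seed integer seed recorded in the run log.
#' @return A `run_config` object.
#' @export
run_config <- function(incubation_days = 2,
                       cc_coefficient = 0.12, cc_exponent = 0.72,
                       filter_area_ratio = 2.5e4, volume_filtered = 5e-4,
                       leu_specific_activity = 304,
                       leu_incubation_hours = 2,
                       leu_sample_volume = 0.005, leu_to_carbon = 1.5,
                       volume_averaging = c("volume_then_carbon",
                                            "carbon_then_average"),
                       sgr_biomass = c("end", "start"),
                       alpha = 0.05, omega_threshold = 0.70, seed = 1L) {
  structure(
    list(incubation_days = incubation_days,
         cc_model = cell_carbon_model(cc_coefficient, cc_exponent),
         filter_area_ratio = filter_area_ratio,
         volume_filtered = volume_filtered,
         leu_specific_activity = leu_specific_activity,
         leu_incubation_hours = leu_incubation_hours,
         leu_sample_volume = leu_sample_volume,
         leu_to_carbon = leu_to_carbon,
         volume_averaging = match.arg(volume_averaging),
         sgr_biomass = match.arg(sgr_biomass),
         alpha = alpha, omega_threshold = omega_threshold,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Configuration matching a synthetic experiment's generator settings
#'
#' @param experiment a `synthetic_experiment`.
#' @param ... overrides passed on to [run_config()].
#' @return A `run_config` whose geometry and assay constants equal those
#'   the generator used.
#' @export
config_from_experiment <- function(experiment, ...) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  nm <- experiment$noise
  run_config(incubation_days = experiment$design$incubation_days,
             filter_area_ratio = nm$filter_area_ratio,
             volume_filtered = nm$volume_filtered,
             leu_specific_activity = nm$leu_specific_activity,
             leu_incubation_hours = nm$leu_incubation_hours,
             leu_sample_volume = nm$leu_sample_volume,
             leu_to_carbon = nm$leu_to_carbon,
             seed = experiment$seed, ...)
}

#' Read a sample sheet (CSV, tab-separated accepted)
#'
#' @param path file path.
#' @return Data frame with the standard sample-sheet columns.
#' @export
read_sample_sheet <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(SAMPLE_SHEET_COLUMNS, names(df))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a sample sheet CSV
#'
#' @param samples sample-sheet data frame (or a `synthetic_experiment`).
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  if (inherits(samples, "synthetic_experiment"))
    samples <- samples$samples
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

unit_key <- function(df)
  interaction(df$experiment, df$treatment, df$replicate, df$timepoint,
              drop = TRUE, lex.order = TRUE)

#' Reduce a sample sheet to per-unit derived state
#'
#' For each experimental unit and timepoint: abundance from field counts,
#' mean cell volume and carbon (pg from the allometry, converted to fg),
#' biomass, and — where DPM columns are present — leucine incorporation,
#' carbon production and cell-specific activity.
#'
#' @param samples sample-sheet data frame or `synthetic_experiment`.
#' @param config a [run_config()].
#' @return Derived-state data frame, one row per unit-timepoint.
#' @export
reduce_samples <- function(samples, config = run_config()) {
  if (inherits(samples, "synthetic_experiment")) {
    config <- config_from_experiment(samples)
    samples <- samples$samples
  }
  stopifnot(inherits(config, "run_config"))
  units <- split(samples, unit_key(samples))
  rows <- lapply(units, function(u) {
    obs <- count_observation(u$cells_in_field, config$filter_area_ratio,
                             config$volume_filtered)
    ab <- suppressWarnings(abundance_from_counts(obs))
    mcv <- mean(u$mean_cell_volume_um3)
    cc_fg <- if (config$volume_averaging == "volume_then_carbon")
      1000 * cell_carbon(mcv, config$cc_model)
    else
      1000 * mean(cell_carbon(u$mean_cell_volume_um3, config$cc_model))
    bm <- biomass(ab, cc_fg)
    dpm_s <- as.numeric(u[1, c("dpm_sample_1", "dpm_sample_2",
                               "dpm_sample_3")])
    has_dpm <- all(is.finite(dpm_s))
    if (has_dpm) {
      assay <- leucine_assay(
        dpm_s,
        as.numeric(u[1, c("dpm_blank_1", "dpm_blank_2", "dpm_blank_3")]),
        specific_activity = config$leu_specific_activity,
        incubation = config$leu_incubation_hours,
        sample_volume = config$leu_sample_volume,
        leu_to_carbon = config$leu_to_carbon)
      leu <- leucine_incorporation_rate(assay)
      prod <- carbon_production(leu, assay)
      act <- cell_specific_activity(leu * 24, ab)
    } else {
      leu <- prod <- act <- NA_real_
    }
    data.frame(experiment = u$experiment[1], treatment = u$treatment[1],
               replicate = u$replicate[1], timepoint = u$timepoint[1],
               abundance = ab, mean_cell_volume = mcv,
               mean_cell_carbon_fg = cc_fg, biomass = bm,
               leu_rate_nmol_l_h = leu, production = prod,
               cell_activity = act,
               ph = u$ph[1], ta_umol_kg = u$ta_umol_kg[1],
               temp_c = u$temp_c[1], salinity = u$salinity[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$treatment, out$replicate, out$timepoint), ]
}

#' Per-replicate rates from derived state
#'
#' Pairs each replicate's start and end states and applies the rate
#' estimators. Production is paired with end-of-incubation biomass by
#' default (`config$sgr_biomass`).
#'
#' @param derived derived-state data frame from [reduce_samples()].
#' @param config a [run_config()].
#' @return As [treatment_rates()]: list with `replicates` and `summary`.
#' @export
estimate_rates <- function(derived, config = run_config()) {
  t0 <- derived[derived$timepoint == 0, ]
  tend <- derived[derived$timepoint == max(derived$timepoint), ]
  key <- function(d) paste(d$experiment, d$treatment, d$replicate)
  tend <- tend[match(key(t0), key(tend)), ]
  if (any(is.na(tend$abundance)))
    stop("every replicate needs both a start and an end state")
  bm <- if (config$sgr_biomass == "end") tend$biomass else t0$biomass
  df <- data.frame(treatment = t0$treatment, replicate = t0$replicate,
                   n0 = t0$abundance, nt = tend$abundance,
                   production = tend$production, biomass = bm,
                   stringsAsFactors = FALSE)
  treatment_rates(df, t = config$incubation_days)
}

#' Publication-shaped treatment summary table
#'
#' Treatment rows with mean and standard error of net production, cellular
#' activity, SGR, NGR, MR and the MR:SGR ratio (end-of-incubation values).
#'
#' @param derived derived-state data frame.
#' @param rates result of [estimate_rates()].
#' @return Summary data frame, one row per treatment.
#' @export
rates_report_table <- function(derived, rates) {
  tend <- derived[derived$timepoint == max(derived$timepoint), ]
  se <- function(x) stats::sd(x) / sqrt(length(x))
  extra <- do.call(rbind, lapply(split(tend, tend$treatment), function(g)
    data.frame(treatment = g$treatment[1],
               production_mean = mean(g$production),
               production_se = se(g$production),
               cell_activity_mean = mean(g$cell_activity),
               cell_activity_se = se(g$cell_activity),
               stringsAsFactors = FALSE)))
  out <- merge(extra, rates$summary, by = "treatment", sort = FALSE)
  out[match(rates$summary$treatment, out$treatment), ]
}

#' Factorial effect tests across all responses
#'
#' Runs the balanced two-way ANOVA for abundance, biomass, net production,
#' cellular activity, SGR, NGR and MR (end-of-incubation replicate values)
#' and assembles the effects table.
#'
#' @param derived derived-state data frame.
#' @param rates result of [estimate_rates()].
#' @param design a [microcosm_design()] mapping treatments to factor
#'   levels.
#' @param config a [run_config()].
#' @return List with `reports` (per-response `anova_report`s) and `table`
#'   (the effects table from [build_effects_table()]).
#' @export
experiment_anova <- function(derived, rates, design,
                             config = run_config()) {
  stopifnot(inherits(design, "microcosm_design"))
  tend <- derived[derived$timepoint == max(derived$timepoint), ]
  reps <- rates$replicates
  key <- paste(tend$treatment, tend$replicate)
  reps <- reps[match(key, paste(reps$treatment, reps$replicate)), ]
  lv <- design$treatments[match(tend$treatment,
                                design$treatments$treatment), ]
  responses <- list(
    abundance = tend$abundance, biomass = tend$biomass,
    net_production = tend$production, cellular_activity = tend$cell_activity,
    sgr = reps$sgr, ngr = reps$ngr, mr = reps$mr)
  reports <- lapply(names(responses), function(nm) {
    ds <- factorial_dataset(responses[[nm]],
                            factor(lv$level_a, c("ambient", "high")),
                            factor(lv$level_b, c("ambient", "high")),
                            response_name = nm)
    suppressWarnings(two_way_anova(ds, alpha = config$alpha,
                                   omega_threshold = config$omega_threshold))
  })
  names(reports) <- names(responses)
  list(reports = reports,
       table = build_effects_table(reports,
                                   c(design$factor_a, design$factor_b)))
}

#' Carbonate summary over a sample sheet
#'
#' Speciates each distinct (treatment, timepoint) chemistry row.
#'
#' @param samples sample-sheet data frame.
#' @return Data frame of carbonate states.
#' @export
carbonate_summary <- function(samples) {
  u <- unique(samples[, c("experiment", "treatment", "timepoint",
                          "ph", "ta_umol_kg", "temp_c", "salinity")])
  states <- lapply(seq_len(nrow(u)), function(i) {
    s <- speciate_from_ta_ph(u$ta_umol_kg[i], u$ph[i], u$temp_c[i],
                             u$salinity[i])
    data.frame(u[i, ], pco2 = s$pco2, dic = s$dic, hco3 = s$hco3,
               co3 = s$co3, co2_star = s$co2_star)
  })
  out <- do.call(rbind, states)
  rownames(out) <- NULL
  out
}

# Tiny polynomial rolling hash of the configuration for the run log.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[order(names(config))]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline and write a report bundle
#'
#' Stages: reduce -> rates -> anova -> carbonate. Writes
#' `derived_state.csv`, `rates_replicates.csv`, `rates_summary.csv`,
#' `effects_table.csv`, `carbonate_summary.csv` and `run_log.txt` into
#' `out_dir` (identical inputs and config give byte-identical outputs).
#' Input files are never modified; on failure, partial outputs are
#' removed.
#'
#' @param experiment a `synthetic_experiment`, or a sample-sheet data
#'   frame (then `design` is required).
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and just returns the bundle.
#' @param config a [run_config()]; defaults to the generator's settings
#'   when `experiment` is synthetic.
#' @param design a [microcosm_design()]; taken from the experiment when
#'   synthetic.
#' @return Invisibly, a list with `derived`, `rates`, `summary_table`,
#'   `anova`, `carbonate`, `config`.
#' @export
run_pipeline <- function(experiment, out_dir = NULL, config = NULL,
                         design = NULL) {
  if (inherits(experiment, "synthetic_experiment")) {
    if (is.null(config)) config <- config_from_experiment(experiment)
    if (is.null(design)) design <- experiment$design
    samples <- experiment$samples
  } else {
    samples <- experiment
    if (is.null(config)) config <- run_config()
    if (is.null(design)) stop("`design` is required for raw sample sheets")
  }
  derived <- reduce_samples(samples, config)
  rates <- estimate_rates(derived, config)
  summary_table <- rates_report_table(derived, rates)
  anova <- experiment_anova(derived, rates, design, config)
  carb <- carbonate_summary(samples)
  bundle <- list(derived = derived, rates = rates,
                 summary_table = summary_table, anova = anova,
                 carbonate = carb, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    written <- character(0)
    tryCatch({
      wr <- function(df, name) {
        path <- file.path(out_dir, name)
        utils::write.csv(df, path, row.names = FALSE)
        written <<- c(written, path)
      }
      wr(derived, "derived_state.csv")
      wr(rates$replicates, "rates_replicates.csv")
      wr(summary_table, "rates_summary.csv")
      wr(anova$table, "effects_table.csv")
      wr(carb, "carbonate_summary.csv")
      log_path <- file.path(out_dir, "run_log.txt")
      writeLines(c(
        sprintf("config_hash: %s", config_hash(config)),
        sprintf("seed: %d", config$seed),
        sprintf("stage reduce: %d rows in, %d units out",
                nrow(samples), nrow(derived)),
        sprintf("stage rates: %d replicates, %d treatments",
                nrow(rates$replicates), nrow(rates$summary)),
        sprintf("stage anova: %d responses", length(anova$reports)),
        sprintf("stage carbonate: %d states", nrow(carb))),
        log_path)
      written <- c(written, log_path)
    }, error = function(e) {
      unlink(written)
      stop(e)
    })
  }
  invisible(bundle)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments ignored. Values are converted to numeric where possible.
#'
#' @param path file path.
#' @return Named list of values.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}
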