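#' Leucine incorporation: scintillation DPM to carbon production
#'
#' Radiolabelled leucine uptake into the TCA-insoluble fraction is the
#' standard proxy for heterotrophic prokaryote protein synthesis. Blank
#' (killed-control) DPM is subtracted from mean sample DPM; the net signal
#' is converted through the isotope's specific activity to a leucine
#' incorporation rate, then to carbon production with a leucine-to-carbon
#' factor, and normalised to abundance for a cell-specific activity index.
#'
#' @name leucine
NULL

#' Disintegrations per minute per microcurie (radioactivity unit constant).
#' @export
DPM_PER_UCI <- 2.22e6

#' Construct a leucine assay description
#'
#' @param dpm_samples numeric vector of sample DPM readings (usually 3).
#' @param dpm_blanks numeric vector of killed-blank DPM readings (usually 3).
#' @param specific_activity isotope specific activity, uCi per umol
#'   (default 304, i.e. 304 mCi mmol^-1).
#' @param incubation incubation time, hours (default 2).
#' @param sample_volume assay aliquot volume, litres.
#' @param leu_to_carbon leucine-to-carbon conversion, kg C per mol leucine
#'   (default the theoretical 1.5; equivalently 1.5 ug C per nmol leucine).
#' @return A `leucine_assay` object.
#' @export
leucine_assay <- function(dpm_samples, dpm_blanks, specific_activity = 304,
                          incubation = 2, sample_volume = 0.005,
                          leu_to_carbon = 1.5) {
  stopifnot(is.numeric(dpm_samples), length(dpm_samples) >= 1,
            is.numeric(dpm_blanks), length(dpm_blanks) >= 1,
            all(is.finite(dpm_samples)), all(is.finite(dpm_blanks)))
  for (nm in c("specific_activity", "incubation", "sample_volume",
               "leu_to_carbon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm))
  }
  structure(
    list(dpm_samples = as.numeric(dpm_samples),
         dpm_blanks = as.numeric(dpm_blanks),
         specific_activity = specific_activity,
         incubation = incubation,
         sample_volume = sample_volume,
         leu_to_carbon = leu_to_carbon),
    class = "leucine_assay"
  )
}

#' Leucine incorporation rate from an assay
#'
#' Net DPM (mean sample minus mean blank, floored at zero with a warning if
#' blanks exceed samples) is divided by 2.22e6 DPM/uCi, the specific
#' activity, the incubation time and the aliquot volume.
#'
#' @param assay a [leucine_assay()].
#' @return Incorporation rate, nmol leucine L^-1 h^-1.
#' @export
leucine_incorporation_rate <- function(assay) {
  stopifnot(inherits(assay, "leucine_assay"))
  net <- mean(assay$dpm_samples) - mean(assay$dpm_blanks)
  if (net < 0) {
    warning(sprintf("net DPM negative (%.1f); floored at 0", net),
            call. = FALSE)
    net <- 0
  }
  umol_per_l_h <- net / DPM_PER_UCI / assay$specific_activity /
    assay$incubation / assay$sample_volume
  umol_per_l_h * 1e3   # umol -> nmol
}

#' Carbon production from a leucine incorporation rate
#'
#' Linear extrapolation of the hourly rate to a day, times the
#' leucine-to-carbon factor (1 nmol leucine = 1.5 ug C at the default).
#'
#' @param leu_rate incorporation rate, nmol leucine L^-1 h^-1 (>= 0).
#' @param assay a [leucine_assay()] supplying the conversion factor.
#' @return Production, ug C L^-1 d^-1.
#' @export
carbon_production <- function(leu_rate, assay) {
  stopifnot(inherits(assay, "leucine_assay"))
  if (any(!is.finite(leu_rate)) || any(leu_rate < 0))
    stop("`leu_rate` must be finite and >= 0")
  leu_rate * 24 * assay$leu_to_carbon
}

#' Cell-specific leucine activity
#'
#' Daily leucine incorporation normalised to abundance, reported in units of
#' 1e-9 nmol leucine cell^-1 d^-1 (the scale on which assemblage values are
#' conventionally tabulated).
#'
#' @param leu_rate_daily incorporation rate, nmol leucine L^-1 d^-1 (>= 0).
#' @param abundance cells L^-1 (> 0).
#' @return Cell-specific activity, 1e-9 nmol leucine cell^-1 d^-1.
#' @export
cell_specific_activity <- function(leu_rate_daily, abundance) {
  if (any(!is.finite(leu_rate_daily)) || any(leu_rate_daily < 0))
    stop("`leu_rate_daily` must be finite and >= 0")
  if (any(!is.finite(abundance)) || any(abundance <= 0))
    stop("`abundance` must be > 0")
  leu_rate_daily / abundance * 1e9
}
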