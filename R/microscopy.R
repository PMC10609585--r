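#' Microscopy reduction: counts and biovolumes to abundance and biomass
#'
#' Epifluorescence counting of DAPI/acridine-orange stained cells yields, for
#' each slide, a vector of cells per random visual field. Abundance follows
#' from the mean field count, the ratio of effective filtration area to field
#' area, and the volume of water filtered. Cell biovolume is converted to
#' carbon with a power-law allometry, and biomass is abundance times mean
#' cell carbon.
#'
#' @name microscopy
NULL

# Counting protocol minima: at least this many fields and this many total
# cells per slide before the abundance estimate is considered routine.
.MIN_FIELDS <- 50L
.MIN_CELLS <- 400L

#' Construct a microscopy count observation
#'
#' @param cells_per_field integer-like vector, cells enumerated in each
#'   random visual field of one slide.
#' @param filter_area_ratio effective filtration area divided by the area of
#'   one visual field (dimensionless, > 0).
#' @param volume_filtered volume of sample filtered onto the membrane, litres.
#' @return A `count_observation` object.
#' @export
count_observation <- function(cells_per_field, filter_area_ratio,
                              volume_filtered) {
  stopifnot(is.numeric(cells_per_field), length(cells_per_field) >= 1,
            all(is.finite(cells_per_field)), all(cells_per_field >= 0))
  if (!is.numeric(filter_area_ratio) || filter_area_ratio <= 0)
    stop("`filter_area_ratio` must be a positive number")
  if (!is.numeric(volume_filtered) || volume_filtered <= 0)
    stop("`volume_filtered` must be a positive volume in litres")
  structure(
    list(cells_per_field = as.numeric(cells_per_field),
         filter_area_ratio = filter_area_ratio,
         volume_filtered = volume_filtered),
    class = "count_observation"
  )
}

#' Abundance from field counts
#'
#' Mean cells per field, scaled by the filtration-to-field area ratio and
#' divided by the volume filtered. Slides with fewer than 50 fields or fewer
#' than 400 total cells are flagged with a warning (protocol targets, not
#' validity rules): sparse slides still yield an estimate.
#'
#' @param obs a [count_observation()].
#' @return Abundance in cells per litre.
#' @export
abundance_from_counts <- function(obs) {
  stopifnot(inherits(obs, "count_observation"))
  n_fields <- length(obs$cells_per_field)
  total <- sum(obs$cells_per_field)
  if (n_fields < .MIN_FIELDS)
    warning(sprintf("only %d fields counted (< %d protocol minimum)",
                    n_fields, .MIN_FIELDS), call. = FALSE)
  if (total < .MIN_CELLS)
    warning(sprintf("only %s cells counted in total (< %d protocol minimum)",
                    format(total), .MIN_CELLS), call. = FALSE)
  mean(obs$cells_per_field) * obs$filter_area_ratio / obs$volume_filtered
}

#' Allometric cell volume to carbon model
#'
#' The default coefficient/exponent pair (0.12, 0.72) is the standard
#' volume-to-carbon allometry for aquatic bacteria; with cell volume in
#' um^3 it yields carbon in pg per cell (so a 0.1 um^3 cell carries
#' ~0.023 pg = 23 fg of carbon). Pipeline code converts to fg before the
#' biomass step.
#'
#' @param coefficient multiplicative constant (> 0), default 0.12.
#' @param exponent power on cell volume (> 0), default 0.72.
#' @return A `cell_carbon_model` object.
#' @export
cell_carbon_model <- function(coefficient = 0.12, exponent = 0.72) {
  if (!is.numeric(coefficient) || coefficient <= 0)
    stop("`coefficient` must be > 0")
  if (!is.numeric(exponent) || exponent <= 0)
    stop("`exponent` must be > 0")
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "cell_carbon_model")
}

#' Carbon content of a cell from its biovolume
#'
#' @param cv cell volume, um^3 (vectorised, all > 0).
#' @param model a [cell_carbon_model()].
#' @return Cell carbon in the coefficient's units (pg cell^-1 for the
#'   default model).
#' @export
cell_carbon <- function(cv, model = cell_carbon_model()) {
  stopifnot(inherits(model, "cell_carbon_model"))
  if (!is.numeric(cv) || any(!is.finite(cv)) || any(cv <= 0))
    stop("cell volume must be positive and finite")
  model$coefficient * cv^model$exponent
}

#' Assemblage biomass from abundance and mean cell carbon
#'
#' @param abundance cells per litre (>= 0).
#' @param mean_cc mean cell carbon, fg C per cell (>= 0).
#' @return Biomass in ug C per litre (`abundance * mean_cc * 1e-9`).
#' @export
biomass <- function(abundance, mean_cc) {
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("`abundance` must be finite and >= 0")
  if (any(!is.finite(mean_cc)) || any(mean_cc < 0))
    stop("`mean_cc` must be finite and >= 0")
  abundance * mean_cc * 1e-9
}
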