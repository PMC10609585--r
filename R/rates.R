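#' Growth, net growth and mortality rates
#'
#' Assuming exponential dynamics over a bottle incubation, the specific
#' instantaneous growth rate (SGR) of the assemblage follows from carbon
#' production relative to standing biomass, the net growth rate (NGR) from
#' the change in abundance, and the mortality rate (MR) — a lumped loss term
#' covering predation and viral lysis — indirectly as their difference.
#' The MR:SGR ratio indexes overall top-down control: 1 means mortality
#' exactly balances gross growth.
#'
#' @name rates
NULL

#' Specific instantaneous growth rate
#'
#' `SGR = ln(1 + production / biomass)`, d^-1.
#'
#' @param production carbon production, ug C L^-1 d^-1 (>= 0).
#' @param biomass standing biomass, ug C L^-1 (> 0).
#' @return SGR in d^-1.
#' @export
specific_growth_rate <- function(production, biomass) {
  if (any(!is.finite(biomass)) || any(biomass <= 0))
    stop("`biomass` must be > 0")
  if (any(!is.finite(production)) || any(production < 0))
    stop("`production` must be finite and >= 0")
  log1p(production / biomass)
}

#' Net growth rate from start and end abundances
#'
#' `NGR = (ln N_t - ln N_0) / t`, d^-1.
#'
#' @param n0 abundance at the start, cells L^-1 (> 0).
#' @param nt abundance at the end, cells L^-1 (> 0).
#' @param t incubation time, days (> 0).
#' @return NGR in d^-1.
#' @export
net_growth_rate <- function(n0, nt, t) {
  if (any(!is.finite(n0)) || any(n0 <= 0) ||
      any(!is.finite(nt)) || any(nt <= 0))
    stop("abundances must be > 0")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be > 0 days")
  (log(nt) - log(n0)) / t
}

#' Mortality rate (indirect)
#'
#' `MR = SGR - NGR`, d^-1.
#'
#' @param sgr specific instantaneous growth rate, d^-1.
#' @param ngr net growth rate, d^-1.
#' @return MR in d^-1.
#' @export
mortality_rate <- function(sgr, ngr) {
  if (any(!is.finite(sgr)) || any(!is.finite(ngr)))
    stop("rates must be finite")
  sgr - ngr
}

#' Mortality-to-growth ratio
#'
#' Top-down control proxy `MR / SGR`; undefined (NA with a warning) when
#' SGR is zero.
#'
#' @param mr mortality rate, d^-1.
#' @param sgr specific instantaneous growth rate, d^-1.
#' @return Dimensionless ratio, NA where `sgr == 0`.
#' @export
mr_sgr_ratio <- function(mr, sgr) {
  if (any(!is.finite(mr)) || any(!is.finite(sgr)))
    stop("rates must be finite")
  out <- mr / sgr
  zero <- sgr == 0
  if (any(zero)) {
    warning("SGR of 0: MR:SGR ratio undefined, reported as NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Per-replicate rate quartets and treatment summaries
#'
#' Takes a per-replicate table of derived quantities at the start and end of
#' an incubation and returns per-replicate SGR/NGR/MR/MR:SGR plus treatment
#' means and standard errors. Treatment summaries are means of per-replicate
#' rates (not rates of mean quantities), so the identity MR = SGR - NGR is
#' preserved row-by-row and for the means.
#'
#' @param df data frame with columns `treatment`, `replicate`, `n0`, `nt`,
#'   `production`, `biomass` (end-of-incubation biomass by default; supply
#'   start biomass in that column to pair with initial standing stock).
#' @param t incubation time in days.
#' @return List with `replicates` (per-replicate rates) and `summary`
#'   (treatment mean and standard error per rate), both data frames.
#' @export
treatment_rates <- function(df, t = 2) {
  need <- c("treatment", "replicate", "n0", "nt", "production", "biomass")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  sgr <- specific_growth_rate(df$production, df$biomass)
  ngr <- net_growth_rate(df$n0, df$nt, t)
  mr <- mortality_rate(sgr, ngr)
  ratio <- suppressWarnings(mr_sgr_ratio(mr, sgr))
  reps <- data.frame(treatment = df$treatment, replicate = df$replicate,
                     sgr = sgr, ngr = ngr, mr = mr, mr_sgr = ratio,
                     stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(reps, reps$treatment), function(g) {
    se <- function(x) stats::sd(x) / sqrt(length(x))
    data.frame(treatment = g$treatment[1], n = nrow(g),
               sgr_mean = mean(g$sgr), sgr_se = se(g$sgr),
               ngr_mean = mean(g$ngr), ngr_se = se(g$ngr),
               mr_mean = mean(g$mr), mr_se = se(g$mr),
               mr_sgr_mean = mean(g$mr_sgr), mr_sgr_se = se(g$mr_sgr),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[match(unique(reps$treatment), summ$treatment), , drop = FALSE]
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}
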