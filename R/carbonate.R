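#' Seawater carbonate-system speciation
#'
#' Computes the CO2 system from total alkalinity (TA) and total-scale pH at
#' a given temperature and salinity: the proton condition is used to strip
#' borate, hydroxide and free-proton contributions from TA, leaving
#' carbonate alkalinity, from which bicarbonate, carbonate, dissolved CO2
#' and pCO2 follow via the first and second dissociation constants.
#'
#' Constants: K1/K2 from Lueker et al. (2000, total scale), K0 from Weiss
#' (1974), KB from Dickson (1990), KW from the DOE handbook formulation
#' (total scale), total boron from salinity after Uppstrom (1974). Nutrient
#' (phosphate/silicate) alkalinity terms are omitted: they are unmeasured in
#' typical microcosm sheets and contribute < 1 umol kg^-1 at coastal levels.
#'
#' @name carbonate
NULL

# Thermodynamic constants at temperature (degC) and practical salinity.
# All on the total pH scale, concentrations in mol kg-SW^-1.
carbonate_constants <- function(temp, salinity) {
  tk <- temp + 273.15
  s <- salinity
  lnk0 <- 93.4517 * (100 / tk) - 60.2409 + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)
  pk1 <- 3633.86 / tk - 61.2172 + 9.67770 * log(tk) -
    0.011555 * s + 0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.9290 - 3.16967 * log(tk) -
    0.01781 * s + 0.0001122 * s^2
  lnkb <- (-8966.90 - 2890.53 * sqrt(s) - 77.942 * s +
             1.728 * s^1.5 - 0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sqrt(s) + 1.62142 * s +
    (-24.4344 - 25.085 * sqrt(s) - 0.2474 * s) * log(tk) +
    0.053105 * sqrt(s) * tk
  lnkw <- 148.96502 - 13847.26 / tk - 23.6521 * log(tk) +
    (118.67 / tk - 5.977 + 1.0495 * log(tk)) * sqrt(s) - 0.01615 * s
  list(k0 = exp(lnk0), k1 = 10^(-pk1), k2 = 10^(-pk2),
       kb = exp(lnkb), kw = exp(lnkw),
       bt = 0.0004157 * s / 35)
}

check_carbonate_inputs <- function(ta, temp, salinity, ph = NULL) {
  if (!is.finite(ta) || ta <= 0)
    stop("`ta` must be > 0 umol kg^-1")
  if (!is.finite(salinity) || salinity <= 0 || salinity > 45)
    stop("`salinity` must be in (0, 45]")
  if (!is.finite(temp) || temp < -2 || temp > 40)
    stop("`temp` must be in [-2, 40] degC")
  if (!is.null(ph) && (!is.finite(ph) || ph < 6 || ph > 9))
    stop("`ph` must be in [6, 9] (total scale)")
  invisible(TRUE)
}

#' Speciate the carbonate system from TA and pH
#'
#' @param ta total alkalinity, umol kg^-1 (> 0).
#' @param ph total-scale pH, in `[6, 9]`.
#' @param temp temperature, degC, in `[-2, 40]`.
#' @param salinity practical salinity, in `(0, 45]`.
#' @return A `carbonate_state` list: inputs plus `pco2` (uatm), `dic`,
#'   `hco3`, `co3`, `co2_star`, `boh4`, `oh` (umol kg^-1).
#' @export
speciate_from_ta_ph <- function(ta, ph, temp, salinity) {
  check_carbonate_inputs(ta, temp, salinity, ph)
  k <- carbonate_constants(temp, salinity)
  h <- 10^(-ph)
  balk <- k$bt * k$kb / (k$kb + h)
  oh <- k$kw / h
  calk <- ta * 1e-6 - balk - oh + h
  if (calk <= 0)
    stop("non-positive carbonate alkalinity: TA/pH combination infeasible")
  hco3 <- calk / (1 + 2 * k$k2 / h)
  co3 <- hco3 * k$k2 / h
  co2 <- hco3 * h / k$k1
  structure(
    list(ta = ta, ph = ph, temp = temp, salinity = salinity,
         pco2 = co2 / k$k0 * 1e6,
         dic = (co2 + hco3 + co3) * 1e6,
         hco3 = hco3 * 1e6, co3 = co3 * 1e6, co2_star = co2 * 1e6,
         boh4 = balk * 1e6, oh = oh * 1e6),
    class = "carbonate_state"
  )
}

#' Alkalinity-balance residual of a carbonate state
#'
#' `[HCO3-] + 2[CO3--] + [B(OH)4-] + [OH-] - [H+] - TA`, umol kg^-1;
#' should close to well under 0.1 umol kg^-1.
#'
#' @param state a `carbonate_state`.
#' @return Residual in umol kg^-1.
#' @export
alkalinity_residual <- function(state) {
  stopifnot(inherits(state, "carbonate_state"))
  h <- 10^(-state$ph) * 1e6
  state$hco3 + 2 * state$co3 + state$boh4 + state$oh - h - state$ta
}

#' Solve pH from TA and pCO2
#'
#' Bracketed root-solve of the alkalinity balance in pH over `[6, 9]`:
#' at fixed pCO2 dissolved CO2 is known, bicarbonate and carbonate follow
#' from the candidate proton concentration, and the pH is adjusted until
#' computed alkalinity matches the target.
#'
#' @inheritParams speciate_from_ta_ph
#' @param pco2 CO2 partial pressure, uatm (> 0).
#' @return Total-scale pH.
#' @export
solve_ph_from_ta_pco2 <- function(ta, pco2, temp, salinity) {
  check_carbonate_inputs(ta, temp, salinity)
  if (!is.finite(pco2) || pco2 <= 0)
    stop("`pco2` must be > 0 uatm")
  k <- carbonate_constants(temp, salinity)
  co2 <- k$k0 * pco2 * 1e-6
  resid <- function(ph) {
    h <- 10^(-ph)
    hco3 <- k$k1 * co2 / h
    co3 <- k$k1 * k$k2 * co2 / h^2
    balk <- k$bt * k$kb / (k$kb + h)
    (hco3 + 2 * co3 + balk + k$kw / h - h) - ta * 1e-6
  }
  lo <- resid(6); hi <- resid(9)
  if (sign(lo) == sign(hi))
    stop("no pH root in [6, 9] for the requested TA/pCO2")
  root <- stats::uniroot(resid, c(6, 9), tol = .Machine$double.eps^0.6)
  if (abs(resid(root$root)) > 1e-10)
    stop("pH solve did not converge to the required residual")
  root$root
}
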