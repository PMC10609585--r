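---
title: "Estimating growth and mortality of heterotrophic prokaryotes in multi-stressor microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating growth and mortality of heterotrophic prokaryotes in multi-stressor microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokrates)
```

## The measurement chain

Bottle (microcosm) experiments on natural assemblages of planktonic
heterotrophic prokaryotes typically manipulate two environmental factors at
two levels each (for instance CO~2~ × UVR, or CO~2~ × temperature), in
triplicate, over a short incubation (2 days by default here). Three raw
observation types feed the analysis:

* **Epifluorescence counts.** Cells per random visual field on a membrane
  filter, with per-cell biovolumes. Abundance (cells L^-1^) is

  $$N = \bar{c} \cdot \frac{A_{filter}/A_{field}}{V_{filtered}}$$

  where $\bar{c}$ is the mean field count. The standard counting protocol
  targets at least 50 fields and 400 cells per slide; `prokrates` warns,
  rather than fails, when a slide falls short, because sparse slides are a
  property of the water, not an invalid measurement.

* **Biovolume → carbon.** Cell carbon follows the power-law allometry
  $CC = 0.12 \times CV^{0.72}$ with $CV$ in µm^3^. A note on units: this
  relationship yields **pg C cell^-1^** — a 0.1 µm^3^ coastal bacterium
  carries ≈ 0.023 pg = 23 fg of carbon, which is the only reading
  consistent with typical assemblage states (e.g. 8.5 × 10^8^ cells L^-1^
  and 21.9 µg C L^-1^ imply 25.7 fg C cell^-1^). `cell_carbon()` is the
  pure power law in the coefficient's own units; the pipeline multiplies by
  1000 to get fg before `biomass()`, which applies the fg → µg conversion
  ($B = N \cdot CC_{fg} \cdot 10^{-9}$, µg C L^-1^). The literature often
  prints "fg" next to this coefficient; we follow the self-consistent
  interpretation.

* **^14^C-leucine incorporation.** Triplicate sample and killed-blank DPM
  readings from liquid scintillation. Net DPM (mean sample − mean blank,
  floored at zero with a warning — blanks occasionally exceed samples by
  counting noise) converts to a leucine incorporation rate through
  2.22 × 10^6^ DPM µCi^-1^, the isotope specific activity (default
  304 µCi µmol^-1^), the incubation time (default 2 h) and the aliquot
  volume. Carbon production uses the theoretical 1.5 kg C mol^-1^ leucine
  factor (1 nmol leucine ≡ 1.5 µg C), extrapolated ×24 from the 2-h
  incubation to a day — the standard linear convention; isotope dilution is
  ignored (the 60 nM addition is treated as saturating). Cell-specific
  activity is the daily leucine rate per cell, reported ×10^-9^ nmol
  leucine cell^-1^ d^-1^.

## Rates

Assuming exponential dynamics over the incubation:

$$SGR = \ln\!\left(1 + \frac{P}{B}\right), \qquad
  NGR = \frac{\ln N_t - \ln N_0}{t}, \qquad
  MR = SGR - NGR,$$

all in d^-1^. SGR is the gross per-capita growth rate implied by carbon
production $P$ relative to biomass $B$; NGR is the realized change in
abundance; MR lumps all losses (protistan grazing plus viral lysis — the
method cannot separate them). The MR:SGR ratio indexes top-down control
(1 = mortality exactly balances growth).

Two choices here were genuinely open:

* **Which biomass pairs with production in SGR.** Production is assayed at
  the end of the incubation, so the default pairs it with end-of-incubation
  biomass (`sgr_biomass = "end"`); start-biomass pairing is a config
  option.
* **Averaging order for cell carbon.** The default converts the mean
  biovolume (`volume_averaging = "volume_then_carbon"`), matching the
  "mean cell carbon content" convention; converting per cell and then
  averaging is available, and with a concave exponent (0.72 < 1) always
  gives slightly smaller cell carbon.

Treatment summaries are **means of per-replicate rates**, not rates of mean
quantities, so the identity $MR + NGR = SGR$ holds exactly for every
replicate *and* for every summary row (published tables built the other way
can violate it in the third decimal). Standard errors are sd/√n over
replicates.

## Factorial inference

Each response (abundance, biomass, net production, cellular activity, SGR,
NGR, MR) is tested with a balanced two-way ANOVA. Sums of squares use the
cell-mean decomposition — for a balanced design Type I/II/III coincide — and
`stats::anova(lm(...))` serves as an independent projection oracle in the
test suite. Unbalanced input is rejected rather than silently re-weighted.

Effect sizes are **generalized partial omega-squared** for the
both-factors-manipulated case (true of CO~2~/UVR/temperature
manipulations):

$$\omega_G^2 = \frac{SS_{eff} - df_{eff}\,MS_{err}}{SS_{total} + MS_{err}}$$

Negative estimates (expected under null effects at small n) are reported as
computed and displayed clamped to zero; plain partial ω^2^ and η^2^ are
returned alongside, and ω² ≤ η² always. Values above 0.70 are flagged as
large effects; α = 0.05, both configurable. Residual normality
(Shapiro–Wilk, on residuals rather than per cell — n = 3 per cell is too
small for per-cell testing) and variance homogeneity (Levene, classic
mean-centred form with a median-centred option) annotate the report and
warn on failure but never abort the ANOVA. In the effects table, ω²_G is
suppressed for non-significant terms, mirroring the usual reporting
convention. No multiple-testing correction is applied across the seven
responses, and no post-hoc tests are run.

## Carbonate bookkeeping

High-CO~2~ treatments are designed and audited from total alkalinity and
pH. `speciate_from_ta_ph()` subtracts borate, hydroxide and free-proton
terms from TA to get carbonate alkalinity, then solves the speciation with
K1/K2 from Lueker et al. (2000), K0 from Weiss (1974), K~B~ from Dickson
(1990), total-scale K~W~, and Uppström total boron — the constants a
Seacarb/CO2SYS user would get by default for these conditions. pH is
assumed to be on the total scale. Phosphate/silicate alkalinity is omitted
(unmeasured in typical microcosm sheets, < 1 µmol kg^-1^ at coastal
levels). `solve_ph_from_ta_pco2()` inverts the balance by bracketed
root-finding on pH ∈ [6, 9] with a residual tolerance of 10^-10^;
`alkalinity_residual()` exposes the closure check (every returned state
closes to well under 0.1 µmol kg^-1^). The test suite compares the solver
to an independently coded reference implementation over a
TA ∈ [2000, 2500] × pH ∈ [7.7, 8.3] × T ∈ [8, 20] °C × S ∈ [30, 38] grid at
1% pCO~2~. Salinity is rarely printed with experiment metadata; the
documented working default is 35.5 (a mesotidal Atlantic lagoon in winter).

## The synthetic-experiment generator

`simulate_experiment()` draws complete sample sheets from known
ground-truth rates, so every estimator can be tested against truth with no
external data:

* True abundance follows $N(t) = N_0 e^{(SGR - MR)t}$ exactly.
* Field counts are Poisson around the true cells-per-field implied by the
  counting geometry (independent fields); biovolumes are lognormal
  (positive, right-skewed) with the requested arithmetic mean and CV.
* The DPM signal is the **exact inverse of the estimator**: true production
  is $P = B_{end}(e^{SGR} - 1)$, mapped backwards through the leucine
  arithmetic to a net DPM, added to the blank mean, with multiplicative
  Gaussian noise; blanks are drawn around their mean with the same CV. This
  inversion is what makes the noiseless round trip exact to machine
  precision — a structural test that the generator and estimator agree on
  every unit conversion.
* All randomness comes from a single stream seeded once, with a fixed
  documented draw order (treatments in design order, replicates within
  treatment, start before end; within a unit: counts, volumes, sample DPM,
  blank DPM). Regeneration with identical arguments is bit-identical. We
  preferred one documented stream over per-unit child streams: the
  reproducibility contract is the same, with less seed-derivation
  machinery.
* Configurations whose expected total count cannot reach the 400-cell
  protocol minimum warn loudly instead of silently violating the protocol.

Default truths (`experiment_truths()`) are the treatment-mean rates of the
two winter coastal-lagoon experiments the package is shaped around
(CO~2~ × UVR: ambient SGR ≈ 1.32 d^-1^, MR ≈ 1.44 d^-1^; CO~2~ ×
temperature: ambient SGR ≈ 0.48, MR ≈ 0.31, warmed SGR ≈ 1.01, MR ≈ 1.12),
with MR taken as SGR − NGR so the dynamics are internally consistent.
Protocol defaults never printed with such experiments were fixed once at
realistic lab values: 60 fields per slide, 0.5 mL filtered at a
filtration-to-field area ratio of 2.5 × 10^4^ (≈ 20–50 cells per field at
10^9^–3 × 10^9^ cells L^-1^), 5 mL leucine aliquots, 40 DPM blanks, 8%
scintillation CV, 35% biovolume CV.

**What the generator does not emulate.** Replicate scatter is observation
noise only; real replicates add biological variability (bottle effects,
micro-heterogeneity), so generated replicate SDs sit at or below field
values, and significance tests on synthetic data are correspondingly
liberal relative to a real experiment at the same effect size. Mortality is
a single lumped rate — no explicit grazers or viruses, no diel light
cycling, no UV dose–response. Passing recovery and calibration tests
therefore demonstrates that the estimators are unbiased and correctly
calibrated *for this observation model*, not that any particular field
effect is real.

## Numerical choices and problem sizes

Tolerances follow the structure of each quantity: algebraic identities
(MR + NGR = SGR, biomass bilinearity, SS additivity) are asserted at
10^-9^–10^-12^; root-finding at 10^-10^ residual; stochastic checks use
Monte-Carlo standard errors. The test suite verifies parameter recovery
over 200 simulated experiments, ANOVA type-I error over 2000 null
experiments (nominal 0.05; accepted within [0.03, 0.08]), and detection of
the default warming contrast over 200 experiments; these sizes give
binomial/MC standard errors comfortably below the decision margins. The
`scripts/acceptance.R` report recomputes the same quantities at 200/1000/200
replicates.

## Worked example

```{r example, eval = FALSE}
tr <- experiment_truths("co2_t")
ex <- simulate_experiment(tr$design, tr$truths,
                          observation_noise_model(), seed = 42)
bundle <- run_pipeline(ex, out_dir = "report")
bundle$rates$summary        # treatment SGR/NGR/MR, mean +/- se
bundle$anova$table          # p and omega_G^2 per factor and interaction
bundle$carbonate            # pCO2/DIC per treatment chemistry state
```

## Known limitations

* The leucine→carbon factor is the theoretical constant; no empirical
  calibration is attempted.
* The carbonate module handles the total pH scale only, and TA arrives as
  a number (no titration-curve processing).
* MR inherits the biases of both SGR (conservative in the presence of dead
  or inactive cells) and NGR; it can go negative in noisy data and is
  reported as computed.
* The ANOVA layer is specialised to balanced 2 × 2 designs, which is what
  the microcosm layout produces; it is not a general factorial engine.
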