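#' Headspace partitioning configuration
#'
#' Dimensionless Henry coefficient (gas/aqueous concentration ratio) and
#' vial geometry used to convert headspace measurements into aqueous
#' concentrations and per-vial inventories. The default geometry is a
#' 72 mL serum vial holding 20 mL of culture (52 mL headspace); the default
#' coefficient 0.227 is the literature value for benzene at 25 degrees C and
#' should be replaced by the user's own calibration when available.
#'
#' @param H_cc Dimensionless Henry coefficient, > 0.
#' @param V_gas Headspace volume, mL.
#' @param V_liq Liquid volume, mL.
#' @return An object of class `henry_config`.
#' @export
henry_config <- function(H_cc = 0.227, V_gas = 52, V_liq = 20) {
  if (!is.numeric(H_cc) || H_cc <= 0) stop("Henry coefficient must be > 0")
  if (V_gas < 0 || V_liq <= 0) stop("vial volumes must be positive")
  structure(list(H_cc = H_cc, V_gas = V_gas, V_liq = V_liq),
            class = "henry_config")
}

#' Aqueous concentration from a headspace measurement
#'
#' `c_aq = c_gas / H_cc`. Inverse of [headspace_from_aqueous()].
#'
#' @param c_gas Headspace concentration (any amount/volume unit; the result
#'   carries the same unit).
#' @param cfg A [henry_config()].
#' @return Aqueous concentration in the same unit as `c_gas`.
#' @export
aqueous_from_headspace <- function(c_gas, cfg = henry_config()) {
  stopifnot(all(c_gas >= 0))
  c_gas / cfg$H_cc
}

#' @rdname aqueous_from_headspace
#' @param c_aq Aqueous concentration.
#' @export
headspace_from_aqueous <- function(c_aq, cfg = henry_config()) {
  stopifnot(all(c_aq >= 0))
  c_aq * cfg$H_cc
}

#' Total per-vial benzene from its aqueous concentration
#'
#' Closes the two-phase inventory: `c_aq * V_liq + c_aq * H_cc * V_gas`,
#' i.e. liquid plus equilibrium headspace amounts.
#'
#' @param c_aq Aqueous concentration in uM (umol/L).
#' @param cfg A [henry_config()].
#' @return Total amount per vial in umol.
#' @export
total_benzene_moles <- function(c_aq, cfg = henry_config()) {
  stopifnot(all(c_aq >= 0))
  c_aq * (cfg$V_liq + cfg$H_cc * cfg$V_gas) / 1000  # uM * mL -> nmol; /1000 -> umol
}

#' Benzene to carbon stoichiometry
#'
#' One benzene molecule carries six carbon atoms.
#'
#' @param benzene Amount of benzene in umol.
#' @return Carbon amount in umol-C.
#' @export
benzene_to_carbon <- function(benzene) {
  stopifnot(all(benzene >= 0))
  6 * benzene
}

#' Percent of initial benzene degraded over a time series
#'
#' `100 * (c_0 - c_end) / c_0` from the first to the last observation.
#'
#' @param series Data frame with columns `day` and `benzene_aq` (any
#'   consistent concentration unit), days strictly increasing.
#' @return Percent degraded.
#' @export
degradation_percent <- function(series) {
  stopifnot(all(diff(series$day) > 0))
  c0 <- series$benzene_aq[1]
  if (c0 <= 0) stop("initial benzene concentration must be > 0")
  100 * (c0 - series$benzene_aq[NROW(series)]) / c0
}

#' Close the carbon balance for degraded substrate
#'
#' Partitions degraded substrate carbon into recovered CH4-C, CO2-C, a
#' biomass allowance, and the residual attributed to intermediates:
#' `residual = degraded - CH4 - CO2` (all umol-C), with
#' `CH4 + CO2 <= degraded` enforced. The biomass allowance defaults to 10%
#' of degraded carbon, the upper bound expected for anaerobic growth
#' yields; it is reported as a maximum, not subtracted from the residual.
#'
#' @param benzene_degraded_C Degraded substrate carbon, umol-C.
#' @param ch4_C,co2_C Recovered gas carbon, umol-C.
#' @param biomass_fraction_max Maximum biomass yield as a fraction of
#'   degraded carbon (default 0.10).
#' @return An object of class `carbon_balance` with fields
#'   `benzene_degraded_C`, `ch4_C`, `co2_C`, `biomass_C_max`, `residual_C`,
#'   `mineralization_pct`.
#' @export
carbon_balance <- function(benzene_degraded_C, ch4_C, co2_C,
                           biomass_fraction_max = 0.10) {
  if (any(c(benzene_degraded_C, ch4_C, co2_C) < 0))
    stop("carbon amounts must be >= 0")
  if (ch4_C + co2_C > benzene_degraded_C)
    stop("recovered gas carbon exceeds degraded carbon")
  structure(list(
    benzene_degraded_C = benzene_degraded_C,
    ch4_C = ch4_C,
    co2_C = co2_C,
    biomass_C_max = biomass_fraction_max * benzene_degraded_C,
    residual_C = benzene_degraded_C - ch4_C - co2_C,
    mineralization_pct = mineralization_percent(benzene_degraded_C, ch4_C, co2_C)
  ), class = "carbon_balance")
}

#' Mineralization percentage
#'
#' Fraction of degraded substrate carbon recovered as CH4 plus CO2,
#' `100 * (ch4_C + co2_C) / benzene_degraded_C`. Headline values are
#' conventionally reported to the nearest percent; this function returns
#' full precision (see [print.carbon_balance()] for the rounded report).
#'
#' @param benzene_degraded_C Degraded substrate carbon, umol-C (> 0).
#' @param ch4_C,co2_C Recovered gas carbon, umol-C.
#' @return Percent mineralized.
#' @export
mineralization_percent <- function(benzene_degraded_C, ch4_C, co2_C) {
  if (any(c(benzene_degraded_C, ch4_C, co2_C) < 0))
    stop("carbon amounts must be >= 0")
  if (benzene_degraded_C <= 0) stop("degraded carbon must be > 0")
  100 * (ch4_C + co2_C) / benzene_degraded_C
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat("Carbon balance (umol-C per vial)\n")
  cat(sprintf("  degraded:        %8.1f\n", x$benzene_degraded_C))
  cat(sprintf("  CH4-C:           %8.1f\n", x$ch4_C))
  cat(sprintf("  CO2-C:           %8.1f\n", x$co2_C))
  cat(sprintf("  residual:        %8.1f (intermediates + biomass)\n", x$residual_C))
  cat(sprintf("  biomass (max):   %8.1f\n", x$biomass_C_max))
  cat(sprintf("  mineralized:     %7.0f%% (%.4f%%)\n",
              round(x$mineralization_pct), x$mineralization_pct))
  invisible(x)
}

#' Read a gas time series from CSV
#'
#' Expects columns `day`, `treatment`, `benzene_aq_mM`, `ch4_umolC`,
#' `co2_umolC`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `day`, `treatment`, `benzene_aq`,
#'   `ch4_13C`, `co2_13C`.
#' @export
read_gas_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "treatment", "benzene_aq_mM", "ch4_umolC", "co2_umolC")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gas table lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(day = df$day, treatment = df$treatment,
             benzene_aq = df$benzene_aq_mM,
             ch4_13C = df$ch4_umolC, co2_13C = df$co2_umolC)
}

#' Carbon balance from a gas time series
#'
#' Computes degraded benzene carbon from the first and last aqueous
#' concentrations (two-phase inventory via the Henry configuration, times
#' six carbons per benzene), takes the final CH4-C and CO2-C amounts, and
#' closes the balance.
#'
#' @param series Gas time series (see [read_gas_series()]); `benzene_aq`
#'   in mM.
#' @param cfg A [henry_config()].
#' @param biomass_fraction_max Passed to [carbon_balance()].
#' @return A `carbon_balance`.
#' @export
balance_from_series <- function(series, cfg = henry_config(),
                                biomass_fraction_max = 0.10) {
  stopifnot(NROW(series) >= 2)
  n <- NROW(series)
  degraded_umol <- total_benzene_moles(series$benzene_aq[1] * 1000, cfg) -
    total_benzene_moles(series$benzene_aq[n] * 1000, cfg)
  carbon_balance(benzene_to_carbon(degraded_umol),
                 series$ch4_13C[n], series$co2_13C[n],
                 biomass_fraction_max)
}
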