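# Oxygen-deficit physiology: Hill saturation curve, CO2-corrected P50,
# inversion of SpO2 to a calculated arterial O2 tension (gPaO2).

#' Oxygen dissociation curve configuration
#'
#' Constants governing the saturation model used to convert SpO2 into a
#' calculated arterial oxygen tension (gPaO2). The saturation curve is the
#' Hill equation with exponent `hill_n`; its half-saturation point P50 is
#' shifted with PACO2 (Bohr effect) through a Henderson--Hasselbalch pH
#' estimate at a fixed assumed bicarbonate.
#'
#' @param hill_n Hill exponent (dimensionless). Default 2.88.
#' @param p50_standard P50 at the reference PACO2, mmHg. Default 26.86.
#' @param reference_paco2 PACO2 at which P50 equals `p50_standard`, mmHg.
#' @param bohr_slope Bohr coefficient, change in log10(P50) per unit pH.
#'   Default -0.48.
#' @param assumed_hco3 Assumed plasma bicarbonate, mmol/L. Default 24.
#' @param spo2_clamp Two-element numeric, admissible SpO2 range in percent.
#'   Readings above the upper bound are clamped (devices report 100%);
#'   readings below the lower bound are rejected as implausible.
#'
#' @return An object of class `oxygen_curve_config`.
#' @export
#' @examples
#' cfg <- oxygen_curve_config()
#' corrected_p50(40, cfg)  # == cfg$p50_standard
oxygen_curve_config <- function(hill_n = 2.88,
                                p50_standard = 26.86,
                                reference_paco2 = 40,
                                bohr_slope = -0.48,
                                assumed_hco3 = 24,
                                spo2_clamp = c(50, 99.5)) {
  stopifnot(hill_n > 0, p50_standard > 0, reference_paco2 > 0,
            assumed_hco3 > 0, length(spo2_clamp) == 2)
  if (!(spo2_clamp[1] < spo2_clamp[2] && spo2_clamp[2] < 100)) {
    stop("spo2_clamp must satisfy lower < upper < 100")
  }
  structure(
    list(hill_n = hill_n, p50_standard = p50_standard,
         reference_paco2 = reference_paco2, bohr_slope = bohr_slope,
         assumed_hco3 = assumed_hco3, spo2_clamp = spo2_clamp),
    class = "oxygen_curve_config"
  )
}

#' Hill saturation curve
#'
#' Fractional hemoglobin saturation `po2^n / (po2^n + p50^n)`.
#'
#' @param po2 Oxygen tension, mmHg (vectorised, must be >= 0).
#' @param p50 Half-saturation tension, mmHg.
#' @param n Hill exponent.
#' @return Saturation as a fraction in `[0, 1)`.
#' @export
hill_saturation <- function(po2, p50 = 26.86, n = 2.88) {
  if (any(!is.finite(po2)) || any(po2 < 0)) stop("po2 must be finite and >= 0")
  if (!is.finite(p50) || p50 <= 0) stop("p50 must be > 0")
  po2^n / (po2^n + p50^n)
}

#' Severinghaus empirical saturation curve
#'
#' The classic empirical fit `1 / (23400 / (po2^3 + 150 po2) + 1)` to the
#' adult oxyhemoglobin dissociation curve at standard conditions. Used as an
#' independent cross-check of the Hill approximation.
#'
#' @param po2 Oxygen tension, mmHg (vectorised, must be > 0).
#' @return Saturation as a fraction in `(0, 1)`.
#' @export
severinghaus_saturation <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 <= 0)) stop("po2 must be finite and > 0")
  1 / (23400 / (po2^3 + 150 * po2) + 1)
}

#' CO2-corrected P50
#'
#' Shifts the standard P50 for the Bohr effect of CO2. pH is estimated from
#' PACO2 by Henderson--Hasselbalch (pK 6.1, CO2 solubility 0.03 mmol/L/mmHg,
#' bicarbonate fixed at `config$assumed_hco3`), and the shift is applied to
#' the pH difference from the reference PACO2 so that
#' `corrected_p50(reference_paco2) == p50_standard` exactly. Algebraically
#' this is `p50_standard * (paco2 / reference_paco2)^(-bohr_slope)`.
#'
#' @param paco2 Alveolar CO2 tension, mmHg, in `[10, 120]`.
#' @param config An [oxygen_curve_config()].
#' @return P50 in mmHg; increases with `paco2`.
#' @export
corrected_p50 <- function(paco2, config = oxygen_curve_config()) {
  if (any(!is.finite(paco2)) || any(paco2 < 10) || any(paco2 > 120)) {
    stop("paco2 must be within [10, 120] mmHg")
  }
  ph <- 6.1 + log10(config$assumed_hco3 / (0.03 * paco2))
  ph_ref <- 6.1 + log10(config$assumed_hco3 / (0.03 * config$reference_paco2))
  config$p50_standard * 10^(config$bohr_slope * (ph - ph_ref))
}

#' Calculated arterial oxygen tension from SpO2
#'
#' Inverts the Hill saturation curve at the observed SpO2, using a P50
#' corrected for the measured PACO2 (taken as a proxy for PaCO2, with no
#' gradient term): `gPaO2 = P50 * (S / (1 - S))^(1 / n)` with `S = spo2/100`.
#'
#' SpO2 at or above the clamp ceiling (including 100%, where the inversion
#' is singular) is clamped with a warning; SpO2 below the clamp floor is an
#' error.
#'
#' @param spo2 Pulse-oximetry saturation, percent.
#' @param paco2 Alveolar CO2 tension, mmHg.
#' @param config An [oxygen_curve_config()].
#' @return gPaO2 in mmHg.
#' @export
#' @examples
#' gpao2_from_spo2(94, 40)
gpao2_from_spo2 <- function(spo2, paco2, config = oxygen_curve_config()) {
  if (any(!is.finite(spo2))) stop("spo2 must be finite")
  lo <- config$spo2_clamp[1]; hi <- config$spo2_clamp[2]
  if (any(spo2 < lo)) {
    stop(sprintf("spo2 below %g%% is physiologically implausible input", lo))
  }
  if (any(spo2 > hi)) {
    warning(sprintf("spo2 > %g%% clamped to %g%% (saturation inversion is singular at 100%%)",
                    hi, hi))
    spo2 <- pmin(spo2, hi)
  }
  s <- spo2 / 100
  p50 <- corrected_p50(paco2, config)
  p50 * (s / (1 - s))^(1 / config$hill_n)
}

#' Oxygen deficit
#'
#' `OD = PAO2 - gPaO2`, the noninvasive surrogate for the alveolar--arterial
#' oxygen gradient. Higher values indicate worse gas exchange. Negative
#' values (possible with noisy inputs) are passed through with a warning.
#'
#' @param pao2 Alveolar O2 tension, mmHg.
#' @param gpao2 Calculated arterial O2 tension, mmHg.
#' @return OD in mmHg.
#' @export
oxygen_deficit <- function(pao2, gpao2) {
  if (any(!is.finite(pao2)) || any(!is.finite(gpao2))) {
    stop("pao2 and gpao2 must be finite")
  }
  od <- pao2 - gpao2
  if (any(od < 0)) warning("negative oxygen deficit (gPaO2 exceeds PAO2); passed through")
  od
}

#' ODFlip orientation dummy
#'
#' `ODFlip = 100 - OD` re-orients the oxygen deficit so that, like SpO2,
#' higher values indicate better gas exchange and both can be plotted on a
#' common ROC axis. `od_from_odflip()` is its exact inverse.
#'
#' @param od Oxygen deficit, mmHg.
#' @return ODFlip in mmHg.
#' @export
odflip <- function(od) {
  if (any(!is.finite(od))) stop("od must be finite")
  100 - od
}

#' @rdname odflip
#' @param odflip_value ODFlip, mmHg.
#' @export
od_from_odflip <- function(odflip_value) {
  if (any(!is.finite(odflip_value))) stop("odflip must be finite")
  100 - odflip_value
}
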