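#' Temperature correction of pH and pCO2
#'
#' Converts analyzer values measured at 37 degrees C to the animal's rectal
#' body temperature using the standard analyzer convention: pH shifts by
#' -0.0147 units per degree C and pCO2 scales by 10^(0.019 * dT).
#'
#' @param pH_v Venous pH at 37 degrees C.
#' @param pCO2_v Venous CO2 partial pressure (mmHg) at 37 degrees C.
#' @param body_temp Rectal temperature (degrees C), in (30, 43).
#' @param constants An [acidbase_constants()] list.
#' @return A tibble with columns `pH_BT` and `pCO2_BT`.
#' @examples
#' temperature_correct(7.40, 45, 39.0)
#' @export
temperature_correct <- function(pH_v, pCO2_v, body_temp,
                                constants = acidbase_constants()) {
  check_range(pH_v, "pH_v", 6.5, 8.0, open = TRUE)
  check_range(pCO2_v, "pCO2_v", 0, Inf, open = TRUE)
  check_range(body_temp, "body_temp", 30, 43, open = TRUE)
  dT <- body_temp - 37
  tibble::tibble(
    pH_BT   = pH_v + constants$temp_ph_slope * dT,
    pCO2_BT = pCO2_v * 10^(constants$temp_pco2_log_slope * dT)
  )
}

#' Actual bicarbonate from the Henderson-Hasselbalch equation
#'
#' cHCO3 = S * pCO2 * 10^(pH - pK1') with S = 0.0307 mmol/L/mmHg and
#' pK1' = 6.12.
#'
#' @inheritParams temperature_correct
#' @param pH Plasma pH (at 37 degrees C).
#' @param pCO2 CO2 partial pressure (mmHg), >= 0.
#' @return Bicarbonate concentration (mmol/L).
#' @examples
#' actual_bicarbonate(7.40, 45) # ~26.3 mmol/L
#' @export
actual_bicarbonate <- function(pH, pCO2, constants = acidbase_constants()) {
  if (!is.numeric(pCO2) || any(pCO2 < 0, na.rm = TRUE)) {
    stop("pCO2 must be non-negative", call. = FALSE)
  }
  constants$S * pCO2 * 10^(pH - constants$pK1)
}

# internal: Van Slyke base excess with an arbitrary effective hemoglobin
van_slyke <- function(pH, hco3, hb_eff, k) {
  (1 - k$vs_hb_space * hb_eff) *
    (hco3 - k$vs_hco3_ref +
       (k$vs_buffer_hb_slope * hb_eff + k$vs_buffer_intercept) *
       (pH - k$vs_ph_ref))
}

#' Actual base excess (Van Slyke equation)
#'
#' BE = (1 - 0.0143 ctHb) * (cHCO3 - 24.4 + (1.63 ctHb + 9.5) * (pH - 7.40))
#' with ctHb in g/dL; zero at pH 7.40 / cHCO3 24.4 mmol/L.
#'
#' @inheritParams actual_bicarbonate
#' @param ctHb Total hemoglobin (g/dL).
#' @return Base excess (mmol/L).
#' @examples
#' base_excess_actual(7.30, 45, 10)   # acidemia: negative
#' @export
base_excess_actual <- function(pH, pCO2, ctHb,
                               constants = acidbase_constants()) {
  check_range(pH, "pH", 6.5, 8.0, open = TRUE)
  check_range(ctHb, "ctHb", 0, Inf)
  van_slyke(pH, actual_bicarbonate(pH, pCO2, constants), ctHb, constants)
}

#' Standard base excess of extracellular fluid
#'
#' Same Van Slyke form as [base_excess_actual()] but with hemoglobin
#' diluted to a third of its blood value, modelling the whole
#' extracellular compartment.
#'
#' @inheritParams base_excess_actual
#' @return Standard base excess (mmol/L).
#' @export
base_excess_ecf <- function(pH, pCO2, ctHb,
                            constants = acidbase_constants()) {
  check_range(pH, "pH", 6.5, 8.0, open = TRUE)
  check_range(ctHb, "ctHb", 0, Inf)
  van_slyke(pH, actual_bicarbonate(pH, pCO2, constants),
            ctHb / constants$ecf_hb_dilution, constants)
}

#' Standard bicarbonate
#'
#' Bicarbonate the sample would show after equilibration to pCO2 40 mmHg,
#' obtained by sliding the sample along the non-bicarbonate buffer line
#' implied by the Van Slyke constants: the pH at 40 mmHg is the root of
#' BE(pH, cHCO3(pH, 40), ctHb) = BE(sample), and the standard bicarbonate
#' is the Henderson-Hasselbalch bicarbonate at that pH.  A sample already
#' at 40 mmHg is returned unchanged.
#'
#' @inheritParams base_excess_actual
#' @return Standard bicarbonate (mmol/L).
#' @examples
#' standard_bicarbonate(7.35, 50, 10)
#' @export
standard_bicarbonate <- function(pH, pCO2, ctHb,
                                 constants = acidbase_constants()) {
  be <- base_excess_actual(pH, pCO2, ctHb, constants)
  n <- max(length(pH), length(pCO2), length(ctHb))
  pH <- rep_len(pH, n); ctHb <- rep_len(ctHb, n); be <- rep_len(be, n)
  vapply(seq_len(n), function(i) {
    f <- function(p) {
      van_slyke(p, actual_bicarbonate(p, 40, constants), ctHb[i],
                constants) - be[i]
    }
    p40 <- stats::uniroot(f, c(6.0, 8.5), tol = 1e-10)$root
    actual_bicarbonate(p40, 40, constants)
  }, numeric(1))
}

#' Anion gap
#'
#' AG = (cNa + cK) - (cCl + cHCO3); monovalent ions, so mmol/L = mEq/L.
#'
#' @param cNa,cK,cCl Plasma ion concentrations (mmol/L).
#' @param cHCO3 Actual bicarbonate (mmol/L).
#' @return Anion gap (mEq/L).
#' @examples
#' anion_gap(140, 4, 104, 26) # 14
#' @export
anion_gap <- function(cNa, cK, cCl, cHCO3) {
  for (nm in c("cNa", "cK", "cCl", "cHCO3")) {
    check_range(get(nm), nm, 0, Inf)
  }
  (cNa + cK) - (cCl + cHCO3)
}

#' Measured strong ion difference
#'
#' Three variants of the measured SID:
#' `m3` = (cNa + cK) - cCl; `m4` = m3 - cLactate;
#' `m5` = m4 + 2 * cCa_ion (ionized calcium weighted by its +2 charge).
#'
#' @param cNa,cK,cCl,cLactate,cCa_ion Plasma concentrations (mmol/L).
#' @param variant One of `"m3"`, `"m4"`, `"m5"`.
#' @return SID (mEq/L).
#' @examples
#' sid_measured(140, 4, 104, 1, 1.2, "m5") # 41.4
#' @export
sid_measured <- function(cNa, cK, cCl, cLactate = 0, cCa_ion = 0,
                         variant = c("m3", "m4", "m5")) {
  variant <- match.arg(variant)
  for (nm in c("cNa", "cK", "cCl", "cLactate", "cCa_ion")) {
    check_range(get(nm), nm, 0, Inf)
  }
  m3 <- (cNa + cK) - cCl
  switch(variant,
    m3 = m3,
    m4 = m3 - cLactate,
    m5 = m3 - cLactate + 2 * cCa_ion
  )
}

#' Acid total of non-volatile weak buffers
#'
#' Linear estimate of the total non-volatile weak acid pool: 0.76 mEq/L per
#' g/L albumin, or 0.36 mEq/L per g/L total protein.
#'
#' @param conc Albumin or total protein concentration (g/L).
#' @param basis `"albumin"` or `"protein"`.
#' @inheritParams temperature_correct
#' @return Atot (mEq/L).
#' @examples
#' atot(30, "albumin") # 22.8
#' @export
atot <- function(conc, basis = c("albumin", "protein"),
                 constants = acidbase_constants()) {
  basis <- match.arg(basis)
  check_range(conc, "concentration", 0, Inf)
  coeff <- if (basis == "albumin") constants$atot_alb_coeff else
    constants$atot_prt_coeff
  coeff * conc
}

#' Strong ion gap
#'
#' SIG = Atot / (1 + 10^(pKa - pH)) - AG: the dissociated fraction of the
#' non-volatile buffer pool minus the anion gap.  Positive values indicate
#' unmeasured cations, negative values unmeasured anions beyond those
#' explained by protein buffering.
#'
#' @param atot Acid total (mEq/L), >= 0.
#' @param pH Plasma pH at 37 degrees C.
#' @param AG Anion gap (mEq/L).
#' @inheritParams temperature_correct
#' @return SIG (mEq/L).
#' @examples
#' strong_ion_gap(22, 7.06, 14) # -3: half-dissociated at pH = pKa
#' @export
strong_ion_gap <- function(atot, pH, AG, constants = acidbase_constants()) {
  check_range(atot, "atot", 0, Inf)
  atot / (1 + 10^(constants$pKa - pH)) - AG
}

#' pH-dependent charges of albumin, globulin and phosphate
#'
#' Linear charge models: albumin 0.141 * cAlb * (pH - 5.42), globulin
#' 0.04 * (cTP - cAlb) * (pH - 5.58), phosphate cPi * (0.309 * pH - 0.469);
#' all in mEq/L with proteins in g/L and phosphate in mmol/L.
#'
#' @param cAlbumin,cTotalProtein Protein concentrations (g/L);
#'   `cAlbumin <= cTotalProtein`.
#' @param cPi Inorganic phosphate (mmol/L).
#' @param pH Plasma pH at 37 degrees C.
#' @inheritParams temperature_correct
#' @return A tibble with columns `charge_albumin`, `charge_globulin`,
#'   `charge_phosphate`.
#' @examples
#' weak_acid_charges(35, 70, 2.0, 7.40)
#' @export
weak_acid_charges <- function(cAlbumin, cTotalProtein, cPi, pH,
                              constants = acidbase_constants()) {
  check_range(cAlbumin, "cAlbumin", 0, Inf)
  check_range(cTotalProtein, "cTotalProtein", 0, Inf)
  check_range(cPi, "cPi", 0, Inf)
  if (any(cAlbumin > cTotalProtein)) {
    stop("cAlbumin must not exceed cTotalProtein", call. = FALSE)
  }
  k <- constants
  tibble::tibble(
    charge_albumin = k$albumin_charge_slope * cAlbumin *
      (pH - k$albumin_charge_pivot),
    charge_globulin = k$globulin_charge_slope *
      (cTotalProtein - cAlbumin) * (pH - k$globulin_charge_pivot),
    charge_phosphate = cPi *
      (k$phosphate_charge_slope * pH - k$phosphate_charge_intercept)
  )
}

#' Effective charge of total magnesium
#'
#' Total magnesium carries a net charge of +1.38 (a divalent cation assumed
#' 69% dissociated), so charge = 1.38 * cMg_total.
#'
#' @param cMg_total Total magnesium (mmol/L).
#' @inheritParams temperature_correct
#' @return Magnesium charge concentration (mEq/L).
#' @examples
#' magnesium_effective_charge(1.0) # 1.38
#' @export
magnesium_effective_charge <- function(cMg_total,
                                       constants = acidbase_constants()) {
  check_range(cMg_total, "cMg_total", 0, Inf)
  constants$mg_net_charge * cMg_total
}

#' Unmeasured anions from the electroneutrality residual
#'
#' XA = cNa + cK + 2 cCa_ion + 1.38 cMg_total - cCl - cHCO3
#'      - albumin charge - globulin charge - phosphate charge.
#' A larger residual means measured cations exceed measured anionic
#' equivalents, i.e. more unmeasured anions are present (the formula is
#' reported literally; its sign is the cation-minus-anion residual).
#'
#' @param cNa,cK,cCa_ion,cMg_total,cCl Plasma concentrations (mmol/L).
#' @param cHCO3 Actual bicarbonate (mmol/L).
#' @param charge_albumin,charge_globulin,charge_phosphate Weak-acid charges
#'   (mEq/L), as from [weak_acid_charges()].
#' @inheritParams temperature_correct
#' @return XA (mEq/L).
#' @export
unmeasured_anions <- function(cNa, cK, cCa_ion, cMg_total, cCl, cHCO3,
                              charge_albumin, charge_globulin,
                              charge_phosphate,
                              constants = acidbase_constants()) {
  cNa + cK + 2 * cCa_ion +
    magnesium_effective_charge(cMg_total, constants) -
    cCl - cHCO3 - charge_albumin - charge_globulin - charge_phosphate
}

#' Derive all blood acid-base variables from raw panels
#'
#' Takes a data frame with one row per animal containing the raw venous
#' panel (`pH_v`, `pCO2_v`, `ctHb`, `body_temp`, `cNa`, `cK`, `cCa_ion`,
#' `cCl`, `cLactate`, `cPi`, `cMg_total`, `cAlbumin` and either
#' `cTotalProtein` or `cGlobulin`) and appends every derived acid-base
#' variable: temperature-corrected pH/pCO2, actual and standard
#' bicarbonate, actual and extracellular base excess, hematocrit, anion
#' gap, the three measured strong ion differences, acid totals, strong ion
#' gaps, the individual weak-acid charges, the unmeasured-anion residual
#' XA, and the albumin/globulin ratio.  All charge-model formulas use the
#' pH measured at 37 degrees C; temperature-corrected values are reported
#' alongside but never fed back into them.
#'
#' @param data A data frame of raw blood panels (see Details for columns).
#' @param constants An [acidbase_constants()] list.
#' @return The input as a tibble with derived columns appended.
#' @examples
#' panel <- tibble::tibble(
#'   pH_v = 7.39, pCO2_v = 48, ctHb = 11, body_temp = 38.6,
#'   cNa = 142, cK = 4.3, cCa_ion = 1.2, cCl = 104, cLactate = 0.8,
#'   cPi = 1.8, cMg_total = 0.9, cAlbumin = 31, cTotalProtein = 72)
#' derive_blood(panel)
#' @export
derive_blood <- function(data, constants = acidbase_constants()) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) return(data)

  need <- c("pH_v", "pCO2_v", "ctHb", "cNa", "cK", "cCa_ion", "cCl",
            "cLactate", "cPi", "cMg_total", "cAlbumin")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing blood panel column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"cTotalProtein" %in% names(data)) {
    if (!"cGlobulin" %in% names(data)) {
      stop("need either cTotalProtein or cGlobulin", call. = FALSE)
    }
    data$cTotalProtein <- data$cAlbumin + data$cGlobulin
  }
  if (!"cGlobulin" %in% names(data)) {
    data$cGlobulin <- data$cTotalProtein - data$cAlbumin
  }
  if (any(data$cAlbumin > data$cTotalProtein)) {
    stop("cAlbumin exceeds cTotalProtein in at least one record",
         call. = FALSE)
  }
  k <- constants

  out <- data
  if ("body_temp" %in% names(data)) {
    tc <- temperature_correct(data$pH_v, data$pCO2_v, data$body_temp, k)
    out$pH_BT <- tc$pH_BT
    out$pCO2_BT <- tc$pCO2_BT
  }
  out$cHCO3_act <- actual_bicarbonate(data$pH_v, data$pCO2_v, k)
  out$cHCO3_std <- standard_bicarbonate(data$pH_v, data$pCO2_v, data$ctHb, k)
  out$BE_act <- base_excess_actual(data$pH_v, data$pCO2_v, data$ctHb, k)
  out$BE_ecf <- base_excess_ecf(data$pH_v, data$pCO2_v, data$ctHb, k)
  out$Hct <- if ("Hct" %in% names(data) && !anyNA(data$Hct)) data$Hct else
    data$ctHb / k$mchc_gdl
  out$AG <- anion_gap(data$cNa, data$cK, data$cCl, out$cHCO3_act)
  out$SID_m3 <- sid_measured(data$cNa, data$cK, data$cCl, variant = "m3")
  out$SID_m4 <- sid_measured(data$cNa, data$cK, data$cCl, data$cLactate,
                             variant = "m4")
  out$SID_m5 <- sid_measured(data$cNa, data$cK, data$cCl, data$cLactate,
                             data$cCa_ion, variant = "m5")
  out$Atot_alb <- atot(data$cAlbumin, "albumin", k)
  out$Atot_prt <- atot(data$cTotalProtein, "protein", k)
  out$SIG_alb <- strong_ion_gap(out$Atot_alb, data$pH_v, out$AG, k)
  out$SIG_prt <- strong_ion_gap(out$Atot_prt, data$pH_v, out$AG, k)
  ch <- weak_acid_charges(data$cAlbumin, data$cTotalProtein, data$cPi,
                          data$pH_v, k)
  out$charge_albumin <- ch$charge_albumin
  out$charge_globulin <- ch$charge_globulin
  out$charge_phosphate <- ch$charge_phosphate
  out$XA <- unmeasured_anions(data$cNa, data$cK, data$cCa_ion,
                              data$cMg_total, data$cCl, out$cHCO3_act,
                              ch$charge_albumin, ch$charge_globulin,
                              ch$charge_phosphate, k)
  out$AGR <- data$cAlbumin / out$cGlobulin
  out
}
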