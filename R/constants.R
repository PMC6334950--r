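#' Physico-chemical constants of the plasma acid-base model
#'
#' Returns the constant set used throughout the blood acid-base calculus:
#' CO2 solubility and apparent carbonic-acid pK for the
#' Henderson-Hasselbalch bicarbonate, the effective pKa of the non-volatile
#' weak plasma buffers, the linear acid-total coefficients for albumin and
#' total protein, the net charge assigned to total magnesium (a divalent
#' cation assumed 69% dissociated, hence 2 x 0.69 = 1.38), and the linear
#' pH-dependent charge models for albumin, globulin and inorganic
#' phosphate.  All constants refer to plasma at 37 degrees C.
#'
#' @param ... Named overrides for individual constants (rarely needed;
#'   intended for sensitivity analyses).
#' @return A named list of class `acidbase_constants`.
#' @examples
#' acidbase_constants()$S
#' @export
acidbase_constants <- function(...) {
  defaults <- list(
    S                         = 0.0307,  # mmol/L per mmHg CO2
    pK1                       = 6.12,
    pKa                       = 7.06,
    atot_alb_coeff            = 0.76,    # mEq/L per g/L albumin
    atot_prt_coeff            = 0.36,    # mEq/L per g/L total protein
    mg_net_charge             = 1.38,    # 2 x 0.69 dissociation
    albumin_charge_slope      = 0.141,
    albumin_charge_pivot      = 5.42,
    globulin_charge_slope     = 0.04,
    globulin_charge_pivot     = 5.58,
    phosphate_charge_slope    = 0.309,
    phosphate_charge_intercept = 0.469,
    # Van Slyke base-excess form (Siggaard-Andersen); hemoglobin in g/dL
    vs_hb_space               = 0.0143,
    vs_hco3_ref               = 24.4,    # mmol/L at pH 7.40
    vs_buffer_hb_slope        = 1.63,
    vs_buffer_intercept       = 9.5,
    vs_ph_ref                 = 7.40,
    ecf_hb_dilution           = 3,       # ctHb/3 models extracellular fluid
    # analyzer temperature-correction convention
    temp_ph_slope             = -0.0147, # pH units per degree C
    temp_pco2_log_slope       = 0.019,   # log10 pCO2 per degree C
    mchc_gdl                  = 33       # g/dL, Hct = ctHb/MCHC fallback
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    stop("unknown constant(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  stopifnot(all(vapply(defaults, is.numeric, logical(1))))
  structure(defaults, class = "acidbase_constants")
}

#' Physiologic truncation bounds for simulated primitive measurements
#'
#' Lower/upper bounds used by the synthetic-cohort generator to clamp
#' Gaussian draws to physiologically possible values, and as validation
#' ranges for raw panels.  Units follow the cohort schema: plasma ions and
#' metabolites in mmol/L (BHB in umol/L), proteins in g/L, hemoglobin in
#' g/dL, enzyme activity in U/L, temperatures in degrees C.
#'
#' @return A tibble with columns `variable`, `low`, `high`, `unit`.
#' @export
physiologic_bounds <- function() {
  tibble::tribble(
    ~variable,     ~low,  ~high,  ~unit,
    "pH_v",         6.8,    7.8,  "",
    "pCO2_v",        20,     90,  "mmHg",
    "ctHb",           5,     18,  "g/dL",
    "body_temp",   36.5,   41.5,  "degC",
    "cNa",          120,    160,  "mmol/L",
    "cK",             2,      7,  "mmol/L",
    "cCa_ion",      0.5,    2.0,  "mmol/L",
    "cCl",           80,    125,  "mmol/L",
    "cGlucose",     1.0,    8.0,  "mmol/L",
    "cLactate",       0,    6.0,  "mmol/L",
    "cPi",          0.3,    4.0,  "mmol/L",
    "cMg_total",    0.3,    2.0,  "mmol/L",
    "cAlbumin",      15,     50,  "g/L",
    "cGlobulin",     15,     65,  "g/L",
    "cNEFA",       0.02,    4.0,  "mmol/L",
    "cBHB",         100,   8000,  "umol/L",
    "cCholesterol", 0.5,    8.0,  "mmol/L",
    "cUrea",        1.0,   12.0,  "mmol/L",
    "cBilirubin",   1.0,   60.0,  "umol/L",
    "aGLDH",          2,    150,  "U/L",
    "cNa_u",        0.5,    250,  "mmol/L",
    "cK_u",          20,    500,  "mmol/L",
    "cCa_u",        0.2,     20,  "mmol/L",
    "cMg_u",        0.5,     40,  "mmol/L",
    "cCl_u",        0.5,    250,  "mmol/L",
    "pH_u",         5.0,    9.5,  "",
    "cBE_u",          0,    600,  "mmol/L",
    "cAE_u",          0,    400,  "mmol/L",
    "cAmm_u",         0,    250,  "mmol/L",
    "DIM",            1,    120,  "days",
    "BCS",          1.5,    5.0,  "points"
  )
}

#' Literature reference intervals for blood, urine and metabolic variables
#'
#' Published reference bounds for adult dairy cattle used for qualitative
#' classification alongside internally derived intervals.  One-sided bounds
#' are stored with `-Inf`/`Inf` on the open side.  Sources are the common
#' veterinary clinical-chemistry reference ranges for the respective
#' variable.
#'
#' @return A tibble with columns `variable`, `low`, `high`, `unit`,
#'   `source` (always `"literature"`).
#' @export
literature_intervals <- function() {
  tibble::tribble(
    ~variable,       ~low,  ~high, ~unit,
    "pH_u",          8.17,   8.35, "",
    "NABE",           106,    210, "mmol/L",
    "BAR",            2.3,    3.6, "",
    "pH_v",          7.38,   7.40, "",
    "cHCO3_std",     27.0,   28.8, "mmol/L",
    "BE_ecf",         4.3,    6.5, "mmol/L",
    "AG",            13.5,   15.3, "mEq/L",
    "SID_m5",        42.6,   45.5, "mEq/L",
    "Atot_alb",      21.4,   25.5, "mEq/L",
    "Atot_prt",      24.5,   27.2, "mEq/L",
    "SIG_alb",        0.5,    3.4, "mEq/L",
    "SIG_prt",        2.4,    4.7, "mEq/L",
    "XA",             7.4,    8.8, "mEq/L",
    "cNEFA",         -Inf,   0.62, "mmol/L",
    "cBHB",          -Inf,   1200, "umol/L",
    "cCholesterol",   1.5,    Inf, "mmol/L",
    "cAlbumin",        30,     39, "g/L",
    "cGlobulin_g",   16.4,   30.4, "g/L"
  ) |>
    dplyr::mutate(source = "literature")
}

# internal: scalar/vector numeric validation with a named error
check_range <- function(x, name, low = -Inf, high = Inf,
                        open = FALSE, allow_na = FALSE) {
  if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
  xx <- x[!is.na(x)]
  if (!allow_na && anyNA(x)) stop(name, " contains missing values", call. = FALSE)
  ok <- if (open) xx > low & xx < high else xx >= low & xx <= high
  if (!all(ok)) {
    stop(name, " out of range ", if (open) "(" else "[", low, ", ",
         high, if (open) ")" else "]", call. = FALSE)
  }
  invisible(x)
}
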