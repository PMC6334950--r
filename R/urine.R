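#' Urinary net acid-base excretion
#'
#' NABE = cBE - (cAE + cAmm): titratable base excess minus the sum of
#' titratable acid excess and ammonium, all in mmol/L from the standard
#' urine titration (HCl to pH 4.0 for base excess, NaOH back to pH 7.0 for
#' acid excess, formaldehyde precipitation for ammonium).  Positive values
#' indicate net base excretion, the physiological state of herbivores.
#'
#' @param cBE Titratable base excess (mmol/L), >= 0.
#' @param cAE Titratable acid excess (mmol/L), >= 0.
#' @param cAmm Ammonium (mmol/L), >= 0.
#' @return NABE (mmol/L).
#' @examples
#' nabe(200, 50, 20) # 130
#' @export
nabe <- function(cBE, cAE, cAmm) {
  check_range(cBE, "cBE", 0, Inf)
  check_range(cAE, "cAE", 0, Inf)
  check_range(cAmm, "cAmm", 0, Inf)
  cBE - (cAE + cAmm)
}

#' Urinary base-acid ratio
#'
#' BAR = cBE / (cAE + cAmm).  Values above 1 indicate net base excretion
#' (NABE > 0).  A zero denominator is an error: the titration protocol
#' guarantees a nonzero acid component in practice, so zero signals a data
#' problem rather than infinite alkalinity.
#'
#' @inheritParams nabe
#' @return BAR (unitless ratio).
#' @examples
#' bar(200, 50, 20) # ~2.857
#' @export
bar <- function(cBE, cAE, cAmm) {
  check_range(cBE, "cBE", 0, Inf)
  check_range(cAE, "cAE", 0, Inf)
  check_range(cAmm, "cAmm", 0, Inf)
  denom <- cAE + cAmm
  if (any(denom == 0)) {
    stop("BAR undefined: cAE + cAmm is zero (titration data problem)",
         call. = FALSE)
  }
  cBE / denom
}

#' Derive urinary acid-base variables for a cohort
#'
#' Appends `NABE` and `BAR` columns computed from the titration components
#' `cBE_u`, `cAE_u`, `cAmm_u`.
#'
#' @param data A data frame with columns `cBE_u`, `cAE_u`, `cAmm_u`.
#' @return The input as a tibble with `NABE` and `BAR` appended.
#' @examples
#' derive_urine(tibble::tibble(cBE_u = 240, cAE_u = 60, cAmm_u = 20))
#' @export
derive_urine <- function(data) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) return(data)
  need <- c("cBE_u", "cAE_u", "cAmm_u")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing urine column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data |>
    dplyr::mutate(
      NABE = nabe(.data$cBE_u, .data$cAE_u, .data$cAmm_u),
      BAR  = bar(.data$cBE_u, .data$cAE_u, .data$cAmm_u)
    )
}
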