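#' Internal reference intervals from a reference group
#'
#' Derives "within-study" reference intervals as the interquartile range
#' (25th to 75th percentile, linear-interpolation quantiles) of each
#' variable over a designated reference group of animals — typically the
#' cluster showing no deviation in urine or metabolic variables.
#'
#' @param data A data frame holding the reference group's rows.
#' @param variables Character vector of numeric columns to derive
#'   intervals for; defaults to all numeric columns.
#' @param min_n Minimum non-missing values required per variable.
#' @return A tibble with columns `variable`, `low`, `high`, `source`
#'   (`"internal_IQR"`).
#' @examples
#' internal_intervals(data.frame(x = c(1, 2, 3, 4)), "x") # 1.75 - 3.25
#' @export
internal_intervals <- function(data, variables = NULL, min_n = 4) {
  stopifnot(is.data.frame(data))
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols) > 0) {
    stop("variable(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("variable ", v, " is not numeric", call. = FALSE)
    x <- x[!is.na(x)]
    if (length(x) < min_n) {
      stop("variable ", v, ": only ", length(x),
           " non-missing values (need >= ", min_n, ")", call. = FALSE)
    }
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    tibble::tibble(variable = v, low = q[1], high = q[2],
                   source = "internal_IQR")
  })
}

# ordered factor levels for qualitative calls
call_levels <- c("marked_below", "below", "within", "above", "marked_above")

#' Qualitative classification against a reference interval
#'
#' Classifies values as `within` when `low <= value <= high`,
#' `below`/`above` outside the bounds, and `marked_below`/`marked_above`
#' (double-arrow calls) when the value lies beyond the bound by more than
#' `marked_margin` times the interval width.  For one-sided (infinite
#' width) intervals no marked call is made.
#'
#' @param value Numeric vector to classify.
#' @param low,high Interval bounds (recycled against `value`).
#' @param marked_margin Fraction of the interval width beyond a bound at
#'   which a call becomes `marked_*`; default 0.5.
#' @return An ordered factor with levels
#'   `marked_below < below < within < above < marked_above`.
#' @examples
#' classify(c(1.9, 2.4, 3.0, 3.8, 4.6), low = 2.3, high = 3.6)
#' @export
classify <- function(value, low, high, marked_margin = 0.5) {
  if (any(low > high, na.rm = TRUE)) {
    stop("invalid interval: low > high", call. = FALSE)
  }
  check_range(marked_margin, "marked_margin", 0, Inf)
  width <- high - low
  call <- dplyr::case_when(
    is.finite(width) & value < low - marked_margin * width ~ "marked_below",
    value < low ~ "below",
    is.finite(width) & value > high + marked_margin * width ~ "marked_above",
    value > high ~ "above",
    TRUE ~ "within"
  )
  factor(call, levels = call_levels, ordered = TRUE)
}

#' Classify cohort variables against a reference interval set
#'
#' Joins a long or wide cohort table against an interval table (as
#' produced by [internal_intervals()] or [literature_intervals()]) and
#' emits one qualitative call per (animal, variable).
#'
#' @param data A data frame with an id column plus one column per
#'   variable, or per-cluster summary rows.
#' @param intervals A tibble with `variable`, `low`, `high` columns.
#' @param id_cols Columns identifying the row (kept in the output).
#' @param marked_margin Passed to [classify()].
#' @return A long tibble with columns `id_cols`, `variable`, `value`,
#'   `low`, `high`, `call`.
#' @export
classify_cohort <- function(data, intervals, id_cols = "animal_id",
                            marked_margin = 0.5) {
  stopifnot(is.data.frame(data), is.data.frame(intervals))
  vars <- intersect(intervals$variable, names(data))
  if (length(vars) == 0) {
    stop("no interval variable present in data", call. = FALSE)
  }
  data |>
    dplyr::select(dplyr::all_of(c(intersect(id_cols, names(data)), vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable",
                        values_to = "value") |>
    dplyr::inner_join(
      dplyr::select(intervals, "variable", "low", "high"),
      by = "variable"
    ) |>
    dplyr::mutate(call = classify(.data$value, .data$low, .data$high,
                                  marked_margin))
}

#' Strong-ion interpretation of qualitative calls
#'
#' Translates qualitative calls on the strong-ion variables into disorder
#' labels: a decreased SID indicates a strong-ion (metabolic) acidosis and
#' an increased SID a strong-ion alkalosis; an increased non-volatile
#' buffer pool (Atot) indicates a buffer-ion acidosis and a decreased pool
#' a buffer-ion alkalosis; an elevated unmeasured-anion residual XA or a
#' depressed strong ion gap indicates increased unidentified anions, and
#' the mirror pattern increased unidentified cations.  Mixed disorders
#' yield multiple labels.
#'
#' @param calls A data frame with columns `variable` and `call` (as from
#'   [classify_cohort()]) covering `SID_m5` and at least one of
#'   `Atot_alb`/`Atot_prt`; `SIG_alb`, `SIG_prt` and `XA` are used when
#'   present.
#' @return Character vector of labels; `"none"` when nothing deviates.
#' @examples
#' calls <- tibble::tibble(
#'   variable = c("SID_m5", "Atot_alb", "SIG_alb", "XA"),
#'   call = factor(c("below", "within", "within", "within")))
#' interpret_strong_ion(calls) # SID-acidosis
#' @export
interpret_strong_ion <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("variable", "call") %in% names(calls)))
  get_call <- function(v) {
    as.character(calls$call[match(v, calls$variable)])
  }
  sid <- get_call("SID_m5")
  if (is.na(sid)) stop("call for SID_m5 is required", call. = FALSE)
  atots <- stats::na.omit(c(get_call("Atot_alb"), get_call("Atot_prt")))
  if (length(atots) == 0) {
    stop("call for Atot_alb or Atot_prt is required", call. = FALSE)
  }
  sigs <- stats::na.omit(c(get_call("SIG_alb"), get_call("SIG_prt")))
  xa <- get_call("XA")

  is_up <- function(x) x %in% c("above", "marked_above")
  is_down <- function(x) x %in% c("below", "marked_below")

  labels <- character(0)
  if (is_down(sid)) labels <- c(labels, "SID-acidosis")
  if (is_up(sid)) labels <- c(labels, "SID-alkalosis")
  if (any(is_up(atots))) labels <- c(labels, "Atot-acidosis")
  if (any(is_down(atots))) labels <- c(labels, "Atot-alkalosis")
  if ((!is.na(xa) && is_up(xa)) || any(is_down(sigs))) {
    labels <- c(labels, "increased-unmeasured-anions")
  }
  if ((!is.na(xa) && is_down(xa)) || any(is_up(sigs))) {
    labels <- c(labels, "increased-unmeasured-cations")
  }
  if (length(labels) == 0) labels <- "none"
  unique(labels)
}
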