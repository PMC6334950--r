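# Synthetic seven-cluster cohort generator.
#
# Prototypes are built from the printed reference intervals and the
# qualitative per-cluster deviation pattern (arrow codes), then inverted
# to the primitive measured quantities; noise is applied only to
# primitives and every derived variable is recomputed forward, so each
# record is internally consistent.  This emulates the cohort's cluster
# structure, not the original animals.

# arrow codes: 0 = interval midpoint; +k/-k = k interval-widths beyond the
# upper/lower bound; +0.5p/-0.5p = half a width from the midpoint but
# still inside the interval (parenthesized arrows).
arrow_target <- function(interval, code) {
  mid <- mean(interval)
  w <- diff(interval)
  stopifnot(is.finite(w), w > 0)
  if (code == 0) return(mid)
  if (abs(code) < 1) return(mid + code * w)     # parenthesized: inside
  if (code > 0) interval[2] + code * w else interval[1] + code * w
}

# working intervals used to place prototype targets; two-sided internal
# reference bounds, with bounded working ranges standing in for the
# one-sided literature limits of NEFA, BHB and cholesterol.
prototype_intervals <- function() {
  list(
    pH_u         = c(8.17, 8.35),
    NABE         = c(106, 210),
    BAR          = c(2.3, 3.6),
    cHCO3        = c(27.0, 28.8),
    SID_m5       = c(42.6, 45.5),
    Atot_alb     = c(21.4, 25.5),
    gGlobulin    = c(16.4, 30.4),
    cNEFA        = c(0.10, 0.62),
    cBHB         = c(400, 1200),
    cCholesterol = c(1.5, 3.5)
  )
}

#' Default cluster prototypes of the synthetic cohort
#'
#' Builds the seven cluster prototypes (sizes 19, 37, 27, 44, 5, 10, 3;
#' 145 animals in total) that structure the synthetic post-parturient
#' cohort.  The reference cluster (cluster 2) sits at the midpoints of the
#' reference intervals; the other clusters are displaced per variable
#' following the qualitative deviation pattern of the emulated herd
#' (single deviation: one interval-width beyond the bound; marked: two
#' widths; relative-only: half a width from the midpoint, inside the
#' interval).  Targets set on derived quantities (bicarbonate, SID,
#' Atot, NABE, BAR) are inverted to the primitive measured variables:
#' pCO2 from the target bicarbonate via Henderson-Hasselbalch, albumin
#' and total protein from the acid totals, sodium from the target SID
#' given the cluster's chloride/calcium/lactate levels, and the urine
#' titration components from the target NABE and base-acid ratio.
#' Cluster-specific primitives not pinned by the deviation pattern (e.g.
#' hyperchloremia and high urinary NaCl in cluster 1, hypochloremia and a
#' high ammonium fraction in the ketotic cluster 5, low hematocrit and a
#' heavy sodium load in the high-lactation cluster 6, hyperchloremia with
#' hypocalcemia and liver strain in cluster 7) follow the per-cluster
#' physiological narrative of the emulated herd.
#'
#' @param constants An [acidbase_constants()] list.
#' @return A tibble with one row per cluster: `cluster`, `size`, and one
#'   column per primitive measured variable (the prototype target).
#' @examples
#' default_prototypes()$size # 19 37 27 44 5 10 3
#' @export
default_prototypes <- function(constants = acidbase_constants()) {
  iv <- prototype_intervals()
  k <- constants

  # per-cluster arrow codes (clusters 1..7)
  a <- list(
    pH_u         = c(0, 0, -1, -1, -1, 0, 1),
    NABE         = c(0, 0, -2, -1, -2, 1, 0),
    BAR          = c(-1, 0, -2, -1, -2, 1, 1),
    cHCO3        = c(-1, 0, 0, -1, -1, 0, 0),
    SID_m5       = c(-1, 0, -1, -1, 0, 0, -2),
    # cluster 4 carries the relative (within-interval) albumin increase
    Atot_alb     = c(0, 0, -1, 0.25, -1, 1, 2),
    gGlobulin    = c(-0.5, 0, 0.5, 0, 0, 1, 0),
    cNEFA        = c(1, 0, 1, 1, 1, -0.5, 3),
    cBHB         = c(0, 0, 0, 0, 2, -0.5, 0.5),
    cCholesterol = c(-0.5, 0, -0.5, 0, -0.5, 0.5, 0)
  )
  tgt <- lapply(names(a), function(v) {
    vapply(a[[v]], function(code) arrow_target(iv[[v]], code), numeric(1))
  })
  names(tgt) <- names(a)
  tgt$BAR <- pmax(tgt$BAR, 0.1)       # BAR cannot be negative
  tgt$cNEFA <- pmax(tgt$cNEFA, 0.05)

  # fixed / narrative-driven primitives
  proto <- tibble::tibble(
    cluster   = 1:7,
    size      = c(19L, 37L, 27L, 44L, 5L, 10L, 3L),
    pH_v      = rep(7.39, 7),
    body_temp = c(38.7, 38.6, 38.9, 38.7, 39.1, 38.3, 38.7),
    ctHb      = c(11.5, 11, 11, 11.5, 12, 9.8, 11),
    cK        = rep(4.3, 7),
    cCa_ion   = c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.0),
    cCl       = c(108, 104, 104, 104, 98, 104, 112),
    cLactate  = c(0.8, 0.8, 0.4, 0.8, 0.4, 0.8, 0.8),
    cPi       = rep(1.8, 7),
    cMg_total = c(0.9, 0.9, 0.75, 0.9, 0.9, 1.1, 0.9),
    cGlucose  = c(3.0, 3.0, 3.0, 3.0, 2.2, 3.0, 3.0),
    cUrea     = c(4, 4, 4, 4, 4, 4, 2.5),
    cBilirubin = c(5, 5, 5, 5, 8, 5, 15),
    aGLDH     = c(15, 15, 15, 15, 20, 15, 30),
    cNa_u     = c(50, 10, 10, 10, 10, 60, 10),
    cK_u      = rep(200, 7),
    cCa_u     = rep(2, 7),
    cMg_u     = rep(8, 7),
    cCl_u     = c(70, 20, 25, 40, 15, 35, 30),
    DIM       = c(3, 5, 6, 4, 8, 54, 1),
    BCS       = c(3.5, 3.25, 3.25, 3.25, 3.25, 2.5, 4.5),
    cNEFA     = tgt$cNEFA,
    cBHB      = tgt$cBHB,
    cCholesterol = tgt$cCholesterol,
    pH_u      = tgt$pH_u
  )

  # inversion: pCO2 such that the standard bicarbonate (the quantity the
  # deviation pattern is stated for) hits its target at the prototype pH
  proto$pCO2_v <- vapply(1:7, function(i) {
    stats::uniroot(function(p) {
      standard_bicarbonate(proto$pH_v[i], p, proto$ctHb[i], k) - tgt$cHCO3[i]
    }, c(20, 90), tol = 1e-9)$root
  }, numeric(1))
  # albumin from the acid total; globulin = target gamma fraction plus a
  # constant alpha+beta pool, letting the two protein axes vary
  # independently (total protein and Atot_prt follow as fallout)
  proto$cAlbumin <- tgt$Atot_alb / k$atot_alb_coeff
  proto$cGlobulin <- tgt$gGlobulin + 17
  stopifnot(all(proto$cGlobulin > 0))
  # sodium from the target SID_m5 given the other strong ions
  proto$cNa <- tgt$SID_m5 - proto$cK - 2 * proto$cCa_ion +
    proto$cCl + proto$cLactate

  # urine titration components from target NABE and BAR
  amm_frac <- c(0.25, 0.25, 0.25, 0.25, 0.5, 0.25, 0.25)
  nabe_t <- tgt$NABE
  bar_t <- tgt$BAR
  denom <- numeric(7)
  for (i in 1:7) {
    consistent <- abs(bar_t[i] - 1) > 0.05 &&
      sign(nabe_t[i]) == sign(bar_t[i] - 1) && nabe_t[i] != 0
    if (consistent) {
      denom[i] <- nabe_t[i] / (bar_t[i] - 1)
    } else if (nabe_t[i] > 0.5 * iv$NABE[1] && bar_t[i] <= 1.05) {
      # pattern asks for positive NABE with a depressed ratio: place the
      # ratio halfway between balance and the lower reference bound
      bar_adj <- 1 + 0.5 * (iv$BAR[1] - 1)
      denom[i] <- nabe_t[i] / (bar_adj - 1)
    } else {
      denom[i] <- 80   # typical titratable acid + ammonium load
    }
  }
  be_u <- nabe_t + denom
  stopifnot(all(be_u >= 0), all(denom > 0))
  proto$cBE_u <- be_u
  proto$cAE_u <- (1 - amm_frac) * denom
  proto$cAmm_u <- amm_frac * denom
  proto
}

# physiologic scale used for noise when a primitive has identical targets
# across all prototypes (typical within-herd biological variation)
noise_fallback_scale <- function() {
  c(
    pH_v = 0.015, pCO2_v = 2.5, ctHb = 0.9, body_temp = 0.2,
    cNa = 2.0, cK = 0.25, cCa_ion = 0.07, cCl = 2.0, cGlucose = 0.35,
    cLactate = 0.15, cPi = 0.2, cMg_total = 0.08, cAlbumin = 2.0,
    cGlobulin = 3.0, cNEFA = 0.15, cBHB = 150, cCholesterol = 0.4,
    cUrea = 0.7, cBilirubin = 2.0, aGLDH = 6, cNa_u = 4, cK_u = 40,
    cCa_u = 0.6, cMg_u = 2.5, cCl_u = 6, pH_u = 0.12, cBE_u = 25,
    cAE_u = 12, cAmm_u = 6, DIM = 2, BCS = 0.25
  )
}

rumen_fill_probs <- function() {
  m <- rbind(
    c(52.1, 47.9, 0), c(29.7, 54.1, 16.2), c(48.1, 48.1, 3.7),
    c(40.9, 52.3, 6.8), c(80, 20, 0), c(20, 50, 30), c(100, 0, 0)
  )
  m / rowSums(m)
}

#' Simulate a physiologically coupled synthetic cohort
#'
#' Draws each animal's primitive measured quantities from a Gaussian
#' around its cluster prototype's target, with per-variable standard
#' deviation `noise_sd` times the between-prototype spread of that
#' variable — the size-weighted standard deviation of the prototype
#' targets, i.e. the dispersion the prototypes alone would induce across
#' the cohort — falling back to a documented physiologic scale for
#' variables whose targets coincide across clusters, and truncated to
#' physiologic bounds.  Only primitives are sampled; use [derive_cohort()] to compute
#' the blood and urine acid-base variables forward so every record is
#' internally consistent.  The generating cluster is retained in
#' `true_cluster` (simulation-only ground truth).
#'
#' @param prototypes Prototype tibble as from [default_prototypes()].
#' @param noise_sd Within-cluster noise as a fraction of the
#'   between-prototype spread; default 0.2.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A tibble with `animal_id`, `farm`, `true_cluster`, `rumen_fill`
#'   and one column per primitive measured variable.
#' @examples
#' cohort <- simulate_cohort(seed = 42)
#' nrow(cohort) # 145
#' @export
simulate_cohort <- function(prototypes = default_prototypes(),
                            noise_sd = 0.2, seed = NULL) {
  stopifnot(is.data.frame(prototypes), all(prototypes$size >= 1))
  check_range(noise_sd, "noise_sd", 0, Inf)
  if (!is.null(seed)) set.seed(seed)

  bounds <- physiologic_bounds()
  fallback <- noise_fallback_scale()
  vars <- setdiff(names(prototypes), c("cluster", "size"))
  targets <- as.matrix(prototypes[, vars, drop = FALSE])
  w <- prototypes$size
  wmean <- colSums(targets * w) / sum(w)
  spread <- sqrt(colSums(w * sweep(targets, 2, wmean)^2) / sum(w))
  zero <- spread == 0
  spread[zero] <- fallback[vars[zero]]
  if (anyNA(spread)) {
    stop("no noise scale for: ",
         paste(vars[is.na(spread)], collapse = ", "), call. = FALSE)
  }

  n_farms <- c(4, 11, 11, 12, 4, 3, 1)
  fill_p <- rumen_fill_probs()

  rows <- purrr::map_dfr(seq_len(nrow(prototypes)), function(i) {
    n <- prototypes$size[i]
    draws <- vapply(seq_along(vars), function(j) {
      x <- stats::rnorm(n, mean = targets[i, j],
                        sd = noise_sd * spread[j])
      b <- bounds[bounds$variable == vars[j], ]
      if (nrow(b) == 1) x <- pmin(pmax(x, b$low), b$high)
      x
    }, numeric(n))
    draws <- matrix(draws, nrow = n,
                    dimnames = list(NULL, vars))
    out <- tibble::as_tibble(draws)
    ci <- prototypes$cluster[i]
    out$true_cluster <- ci
    out$farm <- paste0("F", ci, "_",
                       sample.int(n_farms[min(ci, length(n_farms))],
                                  n, replace = TRUE))
    out$rumen_fill <- sample.int(3, n, replace = TRUE,
                                 prob = fill_p[min(ci, nrow(fill_p)), ])
    out
  })
  rows$DIM <- pmax(1, round(rows$DIM))
  rows$animal_id <- sprintf("cow%03d", seq_len(nrow(rows)))
  dplyr::relocate(rows, "animal_id", "farm", "true_cluster", "rumen_fill")
}

#' Derive all blood and urine acid-base variables for a cohort
#'
#' Convenience wrapper: [derive_blood()] followed by [derive_urine()].
#'
#' @param data Raw cohort tibble (e.g. from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param constants An [acidbase_constants()] list.
#' @return Tibble with every derived acid-base variable appended.
#' @export
derive_cohort <- function(data, constants = acidbase_constants()) {
  data |>
    derive_blood(constants) |>
    derive_urine()
}

#' Write a cohort table to CSV
#'
#' Plain UTF-8 CSV with a header row, "." decimal separator and ","
#' delimiter; doubles are written losslessly so that
#' `read_cohort(write_cohort(x, f))` reproduces `x` exactly.
#'
#' @param data Cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  stopifnot(is.data.frame(data))
  tryCatch(
    readr::write_csv(data, path),
    error = function(e) {
      stop("failed to write cohort to '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV file as written by [write_cohort()].
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort file not found: '", path, "'", call. = FALSE)
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
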