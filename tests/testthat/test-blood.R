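test_that("temperature correction is identity at 37 C and shifts with the analyzer convention", {
  tc <- temperature_correct(7.40, 45, 37.0)
  expect_equal(tc$pH_BT, 7.40)
  expect_equal(tc$pCO2_BT, 45)

  warm <- temperature_correct(7.40, 45, 39.0)
  expect_lt(warm$pH_BT, 7.40)
  expect_gt(warm$pCO2_BT, 45)

  # frozen: 7.40 - 0.0147 * 1.5 and 40 * 10^(0.019 * 1.5)
  ex <- temperature_correct(7.40, 40, 38.5)
  expect_equal(ex$pH_BT, 7.37795, tolerance = 1e-8)
  expect_equal(ex$pCO2_BT, 42.7129917, tolerance = 1e-6)

  expect_error(temperature_correct(7.40, 45, 29), "body_temp")
  expect_error(temperature_correct(7.40, 45, 43.5), "body_temp")
})

test_that("actual bicarbonate follows Henderson-Hasselbalch and is monotone", {
  expect_equal(actual_bicarbonate(6.12, 40), 0.0307 * 40) # exponent zero
  expect_equal(actual_bicarbonate(7.40, 0), 0)
  expect_equal(actual_bicarbonate(7.40, 45), 26.3239398, tolerance = 1e-7)
  expect_error(actual_bicarbonate(7.40, -1), "non-negative")

  set.seed(11)
  pH <- runif(200, 6.9, 7.8); pCO2 <- runif(200, 20, 80)
  expect_true(all(actual_bicarbonate(pH + 0.01, pCO2) >
                    actual_bicarbonate(pH, pCO2)))
  expect_true(all(actual_bicarbonate(pH, pCO2 + 1) >
                    actual_bicarbonate(pH, pCO2)))
})

test_that("Van Slyke base excess zeroes at the reference point and tracks acidemia", {
  # reference point: pH 7.40 with bicarbonate 24.4 mmol/L
  pco2_ref <- 24.4 / (0.0307 * 10^(7.40 - 6.12))
  expect_equal(base_excess_actual(7.40, pco2_ref, 10), 0, tolerance = 1e-10)
  expect_equal(base_excess_ecf(7.40, pco2_ref, 10), 0, tolerance = 1e-10)

  expect_lt(base_excess_actual(7.30, 45, 10), 0)
  # frozen hand evaluations of the Van Slyke form at (7.45, 40, 10)
  expect_equal(base_excess_actual(7.45, 40, 10), 2.6945575, tolerance = 1e-6)
  expect_equal(base_excess_ecf(7.45, 40, 10), 2.4768677, tolerance = 1e-6)

  # zero hemoglobin: attenuation irrelevant
  expect_equal(base_excess_actual(7.45, 40, 0), base_excess_ecf(7.45, 40, 0))

  # monotone increasing in pH at fixed pCO2
  pHs <- seq(7.0, 7.7, by = 0.05)
  be <- base_excess_actual(pHs, 45, 10)
  expect_true(all(diff(be) > 0))
})

test_that("standard bicarbonate is the bicarbonate at pCO2 40 on the sample's buffer line", {
  k <- acidbase_constants()
  # fixed point: a sample already at 40 mmHg is unchanged
  expect_equal(standard_bicarbonate(7.38, 40, 11),
               actual_bicarbonate(7.38, 40), tolerance = 1e-8)
  # acidotic sample sits below the healthy range
  expect_lt(standard_bicarbonate(7.20, 45, 11), 24)

  # oracle: the reported value must lie at pCO2 40 with unchanged BE
  std <- standard_bicarbonate(7.35, 50, 10)
  pH40 <- k$pK1 + log10(std / (k$S * 40))
  expect_equal(base_excess_actual(pH40, 40, 10),
               base_excess_actual(7.35, 50, 10), tolerance = 1e-7)
})

test_that("anion gap and measured SID variants are exact charge arithmetic", {
  expect_equal(anion_gap(140, 4, 104, 26), 14.0)
  expect_equal(anion_gap(100, 0, 50, 50), 0)
  expect_equal(anion_gap(137, 4.5, 99, 28), 14.5)

  expect_equal(sid_measured(140, 4, 104, variant = "m3"), 40.0)
  expect_equal(sid_measured(140, 4, 104, 0, 1.2, variant = "m4"),
               sid_measured(140, 4, 104, variant = "m3"))
  # ionized calcium enters with its +2 charge
  expect_equal(sid_measured(140, 4, 104, 1, 1.2, variant = "m5"), 41.4)
  expect_error(sid_measured(140, 4, 104, variant = "m9"))
})

test_that("acid totals, SIG and weak-acid charges match the linear models", {
  expect_equal(atot(0, "albumin"), 0)
  expect_equal(atot(30, "albumin"), 22.8)
  expect_equal(atot(70, "protein"), 25.2)
  expect_error(atot(-1, "albumin"))

  # half-dissociation at pH = pKa
  expect_equal(strong_ion_gap(22, 7.06, 14), -3.0)
  expect_equal(strong_ion_gap(0, 7.40, 14), -14.0)
  expect_equal(strong_ion_gap(22.8, 7.40, 14), 1.6476459, tolerance = 1e-6)

  ch0 <- weak_acid_charges(0, 0, 0, 7.40)
  expect_equal(unlist(ch0), c(charge_albumin = 0, charge_globulin = 0,
                              charge_phosphate = 0))
  ch <- weak_acid_charges(35, 70, 2.0, 7.40)
  expect_equal(ch$charge_albumin, 9.7713, tolerance = 1e-9)
  expect_equal(ch$charge_globulin, 2.548, tolerance = 1e-9)
  expect_equal(ch$charge_phosphate, 3.6352, tolerance = 1e-9)
  # albumin charge vanishes at its pivot pH
  expect_equal(weak_acid_charges(35, 70, 0, 5.42)$charge_albumin, 0)
  expect_error(weak_acid_charges(40, 30, 0, 7.4), "exceed")
})

test_that("magnesium carries the 69%-dissociation net charge", {
  expect_equal(magnesium_effective_charge(0), 0)
  expect_equal(magnesium_effective_charge(1.0), 1.38)
  expect_equal(magnesium_effective_charge(0.9), 1.242)
})

test_that("unmeasured-anion residual matches hand bookkeeping", {
  expect_equal(unmeasured_anions(0, 0, 0, 0, 0, 0, 0, 0, 0), 0)
  # hand arithmetic: 140+4+2.4+1.38-104-26-9.7713-2.548-3.6352
  ch <- weak_acid_charges(35, 70, 2.0, 7.40)
  expect_equal(
    unmeasured_anions(140, 4, 1.2, 1.0, 104, 26, ch$charge_albumin,
                      ch$charge_globulin, ch$charge_phosphate),
    1.8255, tolerance = 1e-9
  )
})

test_that("XA recovers an injected unmeasured-anion load on electroneutral panels", {
  for (u in c(0, 0.5, 1, 3, 7.5)) {
    panel <- electroneutral_panel(u)
    d <- derive_blood(panel)
    expect_equal(d$XA, u, tolerance = 1e-6)
  }
  # adding 1 mmol/L unmeasured monovalent anion raises XA by exactly 1
  d0 <- derive_blood(electroneutral_panel(2))
  d1 <- derive_blood(electroneutral_panel(3))
  expect_equal(d1$XA - d0$XA, 1, tolerance = 1e-9)
})

test_that("derive_blood populates every derived variable and honours identities", {
  set.seed(21)
  panels <- random_panels(50)
  d <- derive_blood(panels)
  expect_true(all(c("pH_BT", "pCO2_BT", "cHCO3_act", "cHCO3_std", "BE_act",
                    "BE_ecf", "Hct", "AG", "SID_m3", "SID_m4", "SID_m5",
                    "Atot_alb", "Atot_prt", "SIG_alb", "SIG_prt",
                    "charge_albumin", "charge_globulin", "charge_phosphate",
                    "XA", "AGR") %in% names(d)))
  expect_equal(d$AG, d$SID_m3 - d$cHCO3_act, tolerance = 1e-9)
  expect_true(all(d$SID_m4 <= d$SID_m3))
  expect_true(all(d$Atot_alb >= 0 & d$Atot_prt >= 0))

  # degenerate protein: Atot_alb = 0 and SIG_alb = -AG
  p0 <- random_panels(1)
  p0$cAlbumin <- 0
  d0 <- derive_blood(p0)
  expect_equal(d0$Atot_alb, 0)
  expect_equal(d0$SIG_alb, -d0$AG)

  # determinism
  expect_identical(derive_blood(panels), derive_blood(panels))
  # header-only input passes through empty
  expect_equal(nrow(derive_blood(panels[0, ])), 0)
  expect_error(derive_blood(dplyr::select(panels, -cNa)), "cNa")
})

test_that("SIG identities hold across random panels", {
  set.seed(31)
  p <- random_panels(300)
  d <- derive_blood(p)
  frac <- 1 / (1 + 10^(acidbase_constants()$pKa - p$pH_v))
  expect_equal(d$SIG_alb - d$SIG_prt,
               (d$Atot_alb - d$Atot_prt) * frac, tolerance = 1e-9)
  # high-pH limit: fully dissociated buffers
  expect_equal(strong_ion_gap(25, 12, 10), 25 - 10, tolerance = 1e-3)
})

test_that("a healthy reference panel lands inside the published reference ranges", {
  # constructed by inverting the formulas from mid-reference targets
  k <- acidbase_constants()
  pco2 <- stats::uniroot(
    function(p) standard_bicarbonate(7.39, p, 11, k) - 27.9,
    c(20, 90), tol = 1e-9
  )$root
  panel <- tibble::tibble(
    pH_v = 7.39, pCO2_v = pco2, ctHb = 11,
    body_temp = 38.6, cK = 4.3, cCa_ion = 1.2, cCl = 104, cLactate = 0.8,
    cPi = 1.8, cMg_total = 0.9,
    cAlbumin = 23.45 / k$atot_alb_coeff, cGlobulin = 40.4,
    cNa = 44.05 - 4.3 - 2 * 1.2 + 104 + 0.8
  )
  d <- derive_blood(panel)
  lit <- literature_intervals()
  for (v in c("SID_m5", "Atot_alb", "cHCO3_std", "BE_ecf", "pH_v")) {
    b <- lit[lit$variable == v, ]
    expect_gte(d[[v]], b$low)
    expect_lte(d[[v]], b$high)
  }
})
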