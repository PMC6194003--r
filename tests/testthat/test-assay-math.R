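test_that("inhibition rate matches hand evaluation and edge anchors", {
  expect_equal(inhibitionRate(1.16, 0.10, 1.16), 0)
  expect_equal(inhibitionRate(1.20, 0.10, 0.10), 100)
  expect_equal(inhibitionRate(1.20, 0.10, 0.65), 50)
  # explicit sample blank d
  expect_equal(inhibitionRate(1.20, 0.10, 0.70, d = 0.15), 50)
  # raw values outside [0, 100] are preserved
  expect_gt(inhibitionRate(1.20, 0.10, 0.05), 100)
  expect_lt(inhibitionRate(1.20, 0.10, 1.50), 0)
})

test_that("inhibition rate is invariant to OD scaling and signals bad plates", {
  base <- inhibitionRate(1.20, 0.10, 0.65)
  for (k in c(0.5, 2, 7.3)) {
    expect_equal(inhibitionRate(k * 1.20, k * 0.10, k * 0.65), base)
  }
  # adding a constant to all four ODs also cancels (both differences shift)
  for (s in c(0.05, 0.4)) {
    expect_equal(inhibitionRate(1.20 + s, 0.10 + s, 0.65 + s, 0.10 + s), base)
  }
  expect_error(inhibitionRate(0.10, 0.10, 0.05), class = "galQuant_plate_invalid")
  expect_error(inhibitionRate(0.05, 0.10, 0.05), class = "galQuant_plate_invalid")
})

test_that("control aggregation averages roles and names missing ones", {
  wells <- data.frame(
    row = rep("A", 4), column = 1:4,
    role = c("full_reaction_control", "full_reaction_control", "blank", "sample"),
    group_id = c("ctl", "ctl", "blank", "s1"),
    concentration = NA_real_, od450 = c(1.2, 1.0, 0.1, 0.6))
  cs <- aggregateControls(new("PlateReadout", wells = wells))
  expect_equal(cs@a, 1.1)
  expect_equal(cs@b, 0.1)
  expect_equal(cs@nControl, 2L)
  noblank <- new("PlateReadout", wells = wells[wells$role != "blank", ])
  expect_error(aggregateControls(noblank), "blank")
})

test_that("control mean over the printed control ODs is ~1.16", {
  wells <- data.frame(
    row = rep(LETTERS[1:2], c(9, 1)), column = c(1:9, 1),
    role = c(rep("full_reaction_control", 9), "blank"),
    group_id = c(rep("ctl", 9), "blank"),
    concentration = NA_real_, od450 = c(tab1_control_od, 0.10))
  cs <- aggregateControls(new("PlateReadout", wells = wells))
  expect_equal(cs@a, 1.16, tolerance = 0.005)
})

test_that("noiseless calibration points are refit to the generating parameters", {
  pts <- make_exact_points(A = -95, t = 2, y0 = 95)
  fit <- fitCalibration(pts)
  expect_true(fit@converged)
  expect_true(isUsable(fit))
  expect_equal(unname(coef(fit)), c(-95, 2, 95), tolerance = 1e-6)
  expect_equal(fit@xMin, 0.039)
  expect_equal(fit@xMax, 20)
  expect_lt(fit@residualSS, 1e-10)
})

test_that("degenerate and undersized calibration designs are refused", {
  flat <- data.frame(concentration = rep(c(1, 2, 4, 8), each = 3),
                     inhibition = 0)
  fit <- fitCalibration(flat)
  expect_false(isUsable(fit))
  expect_error(quantifySample(fit, 0.5, new("ControlSet", a = 1, b = 0,
                                            nControl = 1L, nBlank = 1L)),
               "not usable")
  few <- data.frame(concentration = rep(c(1, 2, 4), each = 3),
                    inhibition = rep(c(10, 30, 60), each = 3))
  expect_error(fitCalibration(few), class = "galQuant_insufficient_design")
})

test_that("prediction and inversion are closed-form exact and round-trip", {
  fit <- make_fit(A = -100, t = 2.885, y0 = 100)
  expect_equal(predictInhibition(fit, 0), 0)
  expect_equal(predictInhibition(fit, 1e9), 100)
  expect_equal(predictInhibition(fit, 2.885 * log(2)), 50)
  expect_equal(invertCalibration(fit, 50), 2.885 * log(2))
  # round-trip identity across the validity range
  for (x in c(0.039, 0.1, 0.5, 1.25, 2, 7, 19.9)) {
    expect_equal(invertCalibration(fit, predictInhibition(fit, x)), x,
                 tolerance = 1e-9)
  }
  expect_error(invertCalibration(fit, 100), class = "galQuant_above_range")
  expect_error(invertCalibration(fit, 120), class = "galQuant_above_range")
  # below the inhibition at the lowest standard
  y_low <- predictInhibition(fit, 0.039)
  expect_error(invertCalibration(fit, y_low / 2), class = "galQuant_below_range")
})

test_that("fitted curve is monotone increasing on the validity range when A < 0", {
  pts <- make_exact_points(A = -80, t = 4, y0 = 90)
  fit <- fitCalibration(pts)
  xs <- seq(fit@xMin, fit@xMax, length.out = 200)
  expect_true(all(diff(predictInhibition(fit, xs)) > 0))
})

test_that("IC50 inverts at 50% and is unreachable below a 50% plateau", {
  expect_equal(ic50(make_fit(A = -100, t = 2.885, y0 = 100)), 2.885 * log(2))
  expect_error(ic50(make_fit(A = -40, t = 2, y0 = 40)),
               class = "galQuant_ic50_unreachable")
  # the repeatability summary of four run-level IC50s reproduces Table 4
  s <- summaryStats(tab4_inter)
  expect_equal(s$mean, 6.49, tolerance = 0.005)
  expect_equal(s$cv_percent, 8.07, tolerance = 0.005)
})

test_that("LDL selection follows the first-detected-above-undetected rule", {
  # deterministic detection by construction: low levels hover around zero,
  # higher levels are clearly positive
  series <- c(0.01, 0.02, 0.04, 0.08, 0.16)
  pts <- data.frame(
    concentration = rep(series, each = 3),
    inhibition = c(-1, 0.5, -0.2,   0.3, -0.4, 0.1,   # F, F
                   8, 9, 10,   15, 16, 14,   30, 28, 29))  # T, T, T
  res <- determineLdl(pts)
  expect_equal(res$ldl, 0.04)
  expect_true(res$anchored)
  expect_identical(unname(res$detected), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # all detected: LDL defaults to the lowest level, unanchored
  all_det <- data.frame(concentration = rep(series, each = 3),
                        inhibition = rep(c(5, 10, 20, 40, 60), each = 3) +
                          rep(c(-0.5, 0, 0.5), 5))
  res2 <- determineLdl(all_det)
  expect_equal(res2$ldl, 0.01)
  expect_false(res2$anchored)
  # nothing detected: assay failure
  none <- data.frame(concentration = rep(series, each = 3),
                     inhibition = rep(c(-0.5, 0, 0.5), 5))
  expect_error(determineLdl(none), class = "galQuant_assay_failure")
})

test_that("LDL falls back to 3-sigma of the negative reference below 3 replicates", {
  pts <- data.frame(concentration = c(0.01, 0.02, 0.04),
                    inhibition = c(1, 2, 10))
  neg <- c(-2, 1, 0, 2, -1)  # sd ~ 1.6 -> threshold ~ 4.9
  res <- determineLdl(pts, negRefInhibition = neg)
  expect_equal(res$ldl, 0.04)
  expect_identical(unname(res$detected), c(FALSE, FALSE, TRUE))
})

test_that("mass_to_epitopes is linear", {
  cc <- buildConversionConstants()
  m1 <- 1.3e-9; m2 <- 4.2e-8
  expect_identical(epitopeCount(massToEpitopes(m1 + m2, cc)),
                   epitopeCount(massToEpitopes(m1, cc)) +
                     epitopeCount(massToEpitopes(m2, cc)))
})

test_that("sample quantification runs the full chain with correct arithmetic", {
  fit <- make_fit(A = -100, t = 2.885, y0 = 100)
  controls <- new("ControlSet", a = 1.20, b = 0.10, nControl = 3L, nBlank = 3L)
  # ODs chosen to give exactly 50% inhibition -> 2.0 ug/mL at the well
  res <- quantifySample(fit, c(0.65, 0.65, 0.65), controls, sampleId = "s1",
                        dilutionFactor = 2, massMg = 5, massBasis = "wet")
  expect_identical(res@censoring, "quantified")
  expect_equal(res@inhibitionMean, 50)
  expect_equal(res@concentration, 2 * 2.885 * log(2), tolerance = 1e-9)
  expected_count <- res@concentration * 0.1 * 1e-6 *
    epitopesPerGram(buildConversionConstants()) / 5
  expect_equal(epitopeCount(res@quantity), expected_count, tolerance = 1e-12)
  expect_identical(quantityBasis(res@quantity), "per_mg_wet")
  # per-cell normalization
  resc <- quantifySample(fit, c(0.65, 0.65, 0.65), controls, cells = 1e6)
  expect_identical(quantityBasis(resc@quantity), "per_cell")
  expect_equal(epitopeCount(resc@quantity),
               2.885 * log(2) * 0.1 * 1e-6 *
                 epitopesPerGram(buildConversionConstants()) / 1e6,
               tolerance = 1e-12)
})

test_that("quantification censors out-of-range samples instead of failing", {
  fit <- make_fit(A = -100, t = 2.885, y0 = 100, ldl = 0.156)
  controls <- new("ControlSet", a = 1.20, b = 0.10, nControl = 3L, nBlank = 3L)
  # inhibition ~ plateau -> above range
  high <- quantifySample(fit, c(0.100, 0.101, 0.102), controls)
  expect_identical(high@censoring, "above_range")
  expect_true(is.na(high@concentration))
  # inhibition corresponding to x ~ 0.08 < ldl = 0.156 -> below LDL
  y_low <- predictInhibition(fit, 0.08)
  od_low <- 1.20 - y_low / 100 * (1.20 - 0.10)
  low <- quantifySample(fit, rep(od_low, 3), controls)
  expect_identical(low@censoring, "below_ldl")
  expect_identical(epitopeCount(low@quantity), 0)
  # single replicate is accepted with a warning (default design is 3 wells)
  expect_warning(quantifySample(fit, 0.65, controls), "3 parallel")
})

test_that("tissue and cell conversions agree with the printed application values", {
  cc <- buildConversionConstants()
  # WT porcine fibroblasts: 67.43e-7 ug Gal-BSA equivalent per cell
  wt <- epitopeCount(massToEpitopes(67.43e-7 * 1e-6, cc))
  expect_equal(signif(wt, 3), 1.22e9, tolerance = 0.01)
  # antigen reduction of the decellularized dural graft vs pericardium
  u <- new("EpitopeQuantity", count = 2.49e15, basis = "per_mg_wet",
           galbsaEquivalentMass = 2.49e15 / epitopesPerGram(cc))
  t <- new("EpitopeQuantity", count = 1.6e13, basis = "per_mg_wet",
           galbsaEquivalentMass = 1.6e13 / epitopesPerGram(cc))
  expect_equal(antigenReduction(u, t), 99.36, tolerance = 0.005)
  expect_equal(antigenReduction(u, u), 0)
  z <- new("EpitopeQuantity", count = 0, basis = "per_mg_wet",
           galbsaEquivalentMass = 0)
  expect_equal(antigenReduction(u, z), 100)
  perCell <- new("EpitopeQuantity", count = 1, basis = "per_cell",
                 galbsaEquivalentMass = 0)
  expect_error(antigenReduction(u, perCell), "basis mismatch")
})
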