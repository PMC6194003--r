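# Printed validation-table data used as oracles across the suite.

# OD values, 100%-reaction control vs negative reference material (n = 9)
tab1_control_od <- c(0.93, 1.30, 1.33, 1.10, 1.36, 1.07, 1.37, 0.99, 1.00)
tab1_negative_od <- c(1.12, 1.64, 0.92, 1.14, 1.17, 1.10, 1.30, 1.55, 1.20)

# positive reference material content determinations, x 1e14 epitopes/mg (n = 9)
tab2_content <- c(5.78, 6.88, 6.81, 5.45, 6.65, 6.83, 6.65, 6.44, 8.43)

# stability of the positive reference under storage, mean/sd per condition (n = 3),
# with the certified (identified) value 6.66 +- 0.83 (n = 9); `starred` marks
# the conditions reported as significantly degraded
tab3_groups <- data.frame(
  condition = c("-20C_1mo", "-20C_6mo", "-20C_12mo",
                "freeze_thaw_1", "freeze_thaw_3", "freeze_thaw_5",
                "4C_3d", "4C_7d", "4C_14d", "4C_30d",
                "25C_3d", "25C_7d", "25C_14d",
                "37C_1d", "37C_3d", "37C_7d"),
  mean = c(6.06, 6.71, 6.97, 6.49, 6.73, 6.48, 6.40, 6.31, 6.16, 5.87,
           7.49, 6.70, 7.10, 6.24, 4.34, 4.67),
  sd = c(0.20, 0.10, 0.20, 0.62, 0.15, 0.23, 0.49, 0.40, 0.49, 1.02,
         0.72, 1.83, 1.19, 1.31, 0.81, 0.69),
  n = rep(3L, 16))
tab3_starred <- c("37C_3d", "37C_7d")
tab3_identified <- list(mean = 6.66, sd = 0.83, n = 9L)

# repeatability IC50s (ug/mL Gal-BSA equivalent), 4 inter-day + 4 intra-day runs
tab4_inter <- c(6.65, 6.62, 5.73, 6.94)
tab4_intra <- c(6.08, 5.71, 5.07, 4.60)

# the ten-level Gal-BSA calibration dilution series, ug/mL
standard_series <- c(20, 10, 5, 2.5, 1.25, 0.625, 0.313, 0.156, 0.078, 0.039)

# noiseless replicate calibration points generated directly from the curve
# Y = A exp(-x/t) + y0 (independent of the simulator)
make_exact_points <- function(A = -95, t = 2, y0 = 95,
                              series = standard_series, reps = 3) {
  data.frame(concentration = rep(series, each = reps),
             inhibition = rep(A * exp(-series / t) + y0, each = reps))
}

# absolute +-band check for printed 2-decimal table cells
expect_within <- function(actual, printed, band = 0.01) {
  expect_lt(abs(actual - printed), band + 1e-12)
}

make_fit <- function(A = -100, t = 2.885, y0 = 100, xMin = 0.039, xMax = 20,
                     ldl = 0.039) {
  new("CalibrationFit", A = A, t = t, y0 = y0, residualSS = 0,
      converged = TRUE, usable = A < 0 && t > 0, xMin = xMin, xMax = xMax,
      ldl = ldl, ldlAnchored = TRUE)
}
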