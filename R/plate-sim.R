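#' Build a SimulationConfig
#'
#' Defaults reflect the method's study conditions: control OD near 1.16 with
#' a 0.10 blank, the ten-level Gal-BSA dilution series 20 down to 0.039
#' ug/mL, 3 parallel wells, and an idealized inhibition curve with 0%
#' inhibition at x = 0 and a 100% plateau (A = -100, y0 = 100, t = 3 ug/mL).
#'
#' @param truth named numeric (A, t, y0) of the generating inhibition curve
#' @param controlOdA mean 100%-control OD
#' @param blankOdB mean blank OD
#' @param noiseCv multiplicative OD read-noise CV in percent
#' @param standardSeries standard concentrations, ug/mL
#' @param replicates wells per group
#' @param samples data.frame with columns sample_id, concentration (true
#'   ug/mL at the loaded dilution), dilution; may be empty
#' @param seed integer random seed
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(truth = c(A = -100, t = 3, y0 = 100),
                             controlOdA = 1.16, blankOdB = 0.10,
                             noiseCv = 10,
                             standardSeries = c(20, 10, 5, 2.5, 1.25, 0.625,
                                                0.313, 0.156, 0.078, 0.039),
                             replicates = 3L,
                             samples = data.frame(sample_id = character(),
                                                  concentration = numeric(),
                                                  dilution = numeric()),
                             seed = 1L) {
  new("SimulationConfig", truth = truth, controlOdA = controlOdA,
      blankOdB = blankOdB, noiseCv = noiseCv,
      standardSeries = standardSeries, replicates = as.integer(replicates),
      samples = samples, seed = as.integer(seed))
}

# expected OD of a well at concentration x under the forward model:
# inhibition Y(x) maps back through the rate formula to
# c = b + (a - b) * (1 - Y/100)
.expectedOd <- function(x, truth, a, b) {
  y <- truth[["A"]] * exp(-x / truth[["t"]]) + truth[["y0"]]
  b + (a - b) * (1 - y / 100)
}

.noisyOd <- function(expected, noiseCv) {
  od <- expected * (1 + stats::rnorm(length(expected), 0, noiseCv / 100))
  pmax(od, 0)  # truncate rather than resample
}

#' Simulate one 96-well inhibition plate
#'
#' Forward model from a true inhibition curve to noisy OD450 readings: each
#' well's expected OD is derived by pushing the expected inhibition back
#' through the rate formula, then multiplied by `(1 + eps)` with
#' `eps ~ N(0, noiseCv/100)`, truncated at OD 0 (plate-reader noise scales
#' with signal). Blank and control wells use the same noise model around
#' their configured means. Deterministic under a fixed seed.
#'
#' @param config a [SimulationConfig-class]
#' @return a [PlateReadout-class]
#' @examples
#' plate <- simulatePlate(simulationConfig(noiseCv = 0))
#' head(plateWells(plate))
#' @export
simulatePlate <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  a <- config@controlOdA; b <- config@blankOdB
  rep_n <- config@replicates

  rows <- list()
  add <- function(role, group, conc, od) {
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, group_id = group,
      concentration = if (is.na(conc)) NA_real_ else conc, od450 = od)
  }
  for (i in seq_len(rep_n)) add("blank", "blank", NA, .noisyOd(b, config@noiseCv))
  for (i in seq_len(rep_n))
    add("full_reaction_control", "control", NA, .noisyOd(a, config@noiseCv))
  for (x in config@standardSeries) {
    exp_od <- .expectedOd(x, config@truth, a, b)
    for (i in seq_len(rep_n))
      add("standard", sprintf("std_%g", x), x, .noisyOd(exp_od, config@noiseCv))
  }
  if (nrow(config@samples)) {
    for (j in seq_len(nrow(config@samples))) {
      s <- config@samples[j, ]
      exp_od <- .expectedOd(s$concentration, config@truth, a, b)
      for (i in seq_len(rep_n))
        add("sample", as.character(s$sample_id), NA,
            .noisyOd(exp_od, config@noiseCv))
    }
  }
  df <- do.call(rbind, rows)
  if (nrow(df) > 96L)
    stop("design exceeds 96 wells (", nrow(df), ")", call. = FALSE)
  idx <- seq_len(nrow(df)) - 1L           # row-major A1..A12, B1..B12, ...
  df <- cbind(row = LETTERS[idx %/% 12L + 1L], column = idx %% 12L + 1L, df)
  new("PlateReadout", wells = df)
}

#' Simulate a set of independent plates
#'
#' Plates get sequentially derived sub-seeds (`seed + plateIndex - 1`), so a
#' whole validation dataset is reproducible from one seed.
#'
#' @param config a [SimulationConfig-class]
#' @param nPlates number of plates (>= 1)
#' @return list of [PlateReadout-class]
#' @export
simulateValidationDataset <- function(config, nPlates) {
  stopifnot(is(config, "SimulationConfig"), nPlates >= 1)
  lapply(seq_len(nPlates), function(i) {
    cfg <- config
    cfg@seed <- config@seed + i - 1L
    simulatePlate(cfg)
  })
}

#' @rdname PlateReadout-class
#' @param x a PlateReadout
#' @return `plateWells()`: the underlying well data.frame
#' @export
plateWells <- function(x) {
  stopifnot(is(x, "PlateReadout"))
  x@wells
}

#' Extract the calibration series from a plate as replicate points
#'
#' Computes per-well inhibition rates for the standard wells against the
#' plate's own controls, in the long replicate-point layout
#' [fitCalibration()] consumes.
#'
#' @param plate a [PlateReadout-class]
#' @param controls optional [ControlSet-class]; computed from the plate when
#'   omitted
#' @return data.frame with columns `concentration`, `inhibition`
#' @export
calibrationPoints <- function(plate, controls = aggregateControls(plate)) {
  stopifnot(is(plate, "PlateReadout"))
  w <- plate@wells
  std <- w[w$role == "standard", ]
  if (!nrow(std)) stop("plate has no standard wells", call. = FALSE)
  data.frame(concentration = std$concentration,
             inhibition = inhibitionRate(controls@a, controls@b, std$od450))
}

setMethod("show", "PlateReadout", function(object) {
  w <- object@wells
  cat(sprintf("PlateReadout: %d wells\n", nrow(w)))
  tab <- table(w$role)
  for (r in names(tab)) cat(sprintf("  %-22s %d\n", r, tab[[r]]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  truth: A = %g, t = %g, y0 = %g\n", object@truth[["A"]],
              object@truth[["t"]], object@truth[["y0"]]))
  cat(sprintf("  controls: a = %g, b = %g; noise CV %g%%; %d replicates\n",
              object@controlOdA, object@blankOdB, object@noiseCv,
              object@replicates))
  cat(sprintf("  standards: %s ug/mL\n",
              paste(object@standardSeries, collapse = ", ")))
  cat(sprintf("  samples: %d; seed %d\n", nrow(object@samples), object@seed))
})
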