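#' @import methods
NULL

.WELL_ROLES <- c("blank", "full_reaction_control", "standard", "sample",
                 "positive_reference", "negative_reference")

#' PlateReadout: per-well OD450 values with roles
#'
#' Container for one 96-well plate of an M86 ELISA inhibition run. Each well
#' carries its grid position, an assay role, a replicate-group label, the
#' measured OD450, and (for calibration standards only) the Gal-BSA-equivalent
#' concentration of the loaded lysate in ug/mL on the pre-mix basis.
#'
#' @slot wells a data.frame with columns `row` (letter A-H), `column`
#'   (integer 1-12), `role` (one of blank, full_reaction_control, standard,
#'   sample, positive_reference, negative_reference), `group_id` (character
#'   replicate-group label), `concentration` (numeric, ug/mL; `NA` except for
#'   standards) and `od450` (numeric, >= 0).
#'
#' @seealso [readPlateCsv()], [simulatePlate()], [plateWells()]
#' @export
setClass("PlateReadout", representation(wells = "data.frame"))

setValidity("PlateReadout", function(object) {
  w <- object@wells
  needed <- c("row", "column", "role", "group_id", "concentration", "od450")
  if (!all(needed %in% names(w)))
    return(paste("wells must have columns:", paste(needed, collapse = ", ")))
  msgs <- character()
  if (!all(w$row %in% LETTERS[1:8]))
    msgs <- c(msgs, "row must be a letter A-H")
  if (!all(w$column %in% 1:12))
    msgs <- c(msgs, "column must be an integer 1-12")
  if (!all(w$role %in% .WELL_ROLES))
    msgs <- c(msgs, paste("role must be one of:", paste(.WELL_ROLES, collapse = ", ")))
  if (any(!is.finite(w$od450)) || any(w$od450 < 0))
    msgs <- c(msgs, "od450 must be finite and >= 0")
  key <- paste0(w$row, w$column)
  if (anyDuplicated(key))
    msgs <- c(msgs, paste("duplicate well position:", key[duplicated(key)][1]))
  std <- w$role == "standard"
  if (any(std) && (any(is.na(w$concentration[std])) || any(w$concentration[std] <= 0)))
    msgs <- c(msgs, "standard wells must carry concentration > 0")
  if (any(!std & !is.na(w$concentration)))
    msgs <- c(msgs, "only standard wells may carry a concentration")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ControlSet: plate-level signal window
#'
#' Mean OD of the 100%-reaction (non-inhibitory) control wells (`a`) and of
#' the blank wells (`b`), with replicate counts. A plate is only usable when
#' `a > b`, i.e. there is a positive signal window for inhibition rates.
#'
#' @slot a mean OD450 of the 100%-reaction control wells
#' @slot b mean OD450 of the blank wells
#' @slot nControl number of control replicates
#' @slot nBlank number of blank replicates
#' @seealso [aggregateControls()], [inhibitionRate()]
#' @export
setClass("ControlSet",
         representation(a = "numeric", b = "numeric",
                        nControl = "integer", nBlank = "integer"))

setValidity("ControlSet", function(object) {
  if (length(object@a) != 1L || length(object@b) != 1L)
    return("a and b must be scalars")
  if (!is.finite(object@a) || !is.finite(object@b))
    return("a and b must be finite")
  if (object@a <= object@b)
    return("invalid plate: control mean OD (a) must exceed blank mean OD (b)")
  TRUE
})

#' CalibrationFit: fitted standard curve Y = A*exp(-x/t) + y0
#'
#' Parameters of the exponential-saturation inhibition curve fitted to the
#' Gal-BSA calibration series, together with its validity range (the span of
#' standard concentrations), the lower detection limit, and fit diagnostics.
#' For an increasing inhibition curve `A < 0` and `t > 0`; the curve rises
#' from `A + y0` at x = 0 toward the plateau `y0`.
#'
#' @slot A amplitude constant (percent, expected < 0)
#' @slot t decay scale (ug/mL, > 0)
#' @slot y0 plateau inhibition (percent)
#' @slot residualSS sum of squared residuals over all replicate points
#' @slot converged logical, optimizer convergence
#' @slot usable logical, converged and monotone increasing (A < 0, t > 0)
#' @slot xMin,xMax validity range: smallest/largest standard concentration
#' @slot ldl lower detection limit (ug/mL), NA when not determined
#' @slot ldlAnchored logical; TRUE when an undetected level below the LDL
#'   anchors it, FALSE when every level was detected and the LDL defaulted to
#'   the lowest tested concentration
#' @seealso [fitCalibration()], [predictInhibition()], [invertCalibration()],
#'   [ic50()]
#' @export
setClass("CalibrationFit",
         representation(A = "numeric", t = "numeric", y0 = "numeric",
                        residualSS = "numeric", converged = "logical",
                        usable = "logical", xMin = "numeric", xMax = "numeric",
                        ldl = "numeric", ldlAnchored = "logical"))

setValidity("CalibrationFit", function(object) {
  if (object@converged && object@t <= 0)
    return("decay scale t must be > 0")
  if (object@xMin >= object@xMax)
    return("xMin must be < xMax")
  if (!is.na(object@ldl) && (object@ldl < object@xMin || object@ldl > object@xMax))
    return("ldl must lie within [xMin, xMax]")
  TRUE
})

#' ConversionConstants: Gal-BSA mass to epitope-count conversion
#'
#' Traceable constants converting grams of Gal-BSA into numbers of alpha-Gal
#' epitopes: the BSA molar mass, the epitope substitution per molecule, and
#' the derived molecules/g and epitopes/g densities.
#'
#' @slot bsaMolarMassKda molar mass of the carrier protein in kDa
#' @slot epitopesPerMolecule epitopes conjugated per Gal-BSA molecule
#' @slot avogadro the Avogadro constant, per mol
#' @slot moleculesPerGram derived molecules per gram
#' @slot epitopesPerGram derived epitopes per gram
#' @seealso [buildConversionConstants()], [massToEpitopes()]
#' @export
setClass("ConversionConstants",
         representation(bsaMolarMassKda = "numeric",
                        epitopesPerMolecule = "numeric",
                        avogadro = "numeric",
                        moleculesPerGram = "numeric",
                        epitopesPerGram = "numeric"))

setValidity("ConversionConstants", function(object) {
  if (object@bsaMolarMassKda <= 0) return("bsaMolarMassKda must be > 0")
  if (object@epitopesPerMolecule < 1) return("epitopesPerMolecule must be >= 1")
  # derived fields must satisfy the defining identities exactly
  mg <- object@avogadro / (object@bsaMolarMassKda * 1000)
  if (object@moleculesPerGram != mg)
    return("moleculesPerGram inconsistent with avogadro / molar mass")
  if (object@epitopesPerGram != mg * object@epitopesPerMolecule)
    return("epitopesPerGram inconsistent with moleculesPerGram * epitopesPerMolecule")
  TRUE
})

.QUANTITY_BASES <- c("per_reaction", "per_mg_wet", "per_mg_dry", "per_cell")

#' EpitopeQuantity: an epitope count with its basis
#'
#' A number of alpha-Gal epitopes together with the basis it is expressed on
#' (per reaction aliquot, per mg wet or freeze-dried tissue, or per cell) and
#' the Gal-BSA-equivalent mass carrying the same count. Counts are stored as
#' doubles (they exceed 1e17 for tissues).
#'
#' @slot count number of epitopes (>= 0)
#' @slot basis one of per_reaction, per_mg_wet, per_mg_dry, per_cell
#' @slot galbsaEquivalentMass grams of Gal-BSA with the same epitope count
#' @seealso [massToEpitopes()], [antigenReduction()]
#' @export
setClass("EpitopeQuantity",
         representation(count = "numeric", basis = "character",
                        galbsaEquivalentMass = "numeric"))

setValidity("EpitopeQuantity", function(object) {
  if (!object@basis %in% .QUANTITY_BASES)
    return(paste("basis must be one of:", paste(.QUANTITY_BASES, collapse = ", ")))
  if (!is.finite(object@count) || object@count < 0)
    return("count must be finite and >= 0")
  TRUE
})

#' SampleResult: quantification result for one sample
#'
#' @slot sampleId sample label
#' @slot inhibitionMean mean inhibition rate over replicates (percent)
#' @slot inhibitionSd sample SD of replicate inhibition rates (percent; NA
#'   with a single replicate)
#' @slot concentration interpolated Gal-BSA-equivalent concentration (ug/mL,
#'   dilution-corrected; NA when censored)
#' @slot quantity an [EpitopeQuantity-class] (count 0 placeholder when censored)
#' @slot censoring one of quantified, below_ldl, above_range
#' @slot dilutionFactor dilution factor applied to the loaded lysate (>= 1)
#' @seealso [quantifySample()]
#' @export
setClass("SampleResult",
         representation(sampleId = "character", inhibitionMean = "numeric",
                        inhibitionSd = "numeric", concentration = "numeric",
                        quantity = "EpitopeQuantity", censoring = "character",
                        dilutionFactor = "numeric"))

setValidity("SampleResult", function(object) {
  if (!object@censoring %in% c("quantified", "below_ldl", "above_range"))
    return("censoring must be quantified, below_ldl or above_range")
  if (object@dilutionFactor < 1)
    return("dilutionFactor must be >= 1")
  TRUE
})

#' ReferenceMaterialSpec: certified reference-material description
#'
#' @slot kind "positive" or "negative"
#' @slot certifiedValue certified epitopes/mg (positive materials only; NA
#'   for negative)
#' @slot certifiedSd SD of the certified value, same units
#' @slot certifiedN number of determinations behind the certified value
#' @slot storageNote free-text storage recommendation
#' @seealso [positiveAccuracyGate()], [stabilityCompare()]
#' @export
setClass("ReferenceMaterialSpec",
         representation(kind = "character", certifiedValue = "numeric",
                        certifiedSd = "numeric", certifiedN = "integer",
                        storageNote = "character"))

setValidity("ReferenceMaterialSpec", function(object) {
  if (!object@kind %in% c("positive", "negative"))
    return("kind must be 'positive' or 'negative'")
  if (object@kind == "positive" &&
      (is.na(object@certifiedValue) || object@certifiedValue <= 0))
    return("positive reference material requires certifiedValue > 0")
  TRUE
})

#' QCReport: gate outcomes and repeatability CVs for a run
#'
#' @slot negativeGate list: pass, p_value, neg_mean_od, control_mean_od
#' @slot positiveGate list: pass, measured_mean, certified_value,
#'   deviation_percent
#' @slot repeatability list: inter_day, intra_day, total (each a
#'   mean/sd/cv_percent/n summary), possibly empty
#' @seealso [negativeSpecificityGate()], [positiveAccuracyGate()],
#'   [repeatabilityReport()]
#' @export
setClass("QCReport",
         representation(negativeGate = "list", positiveGate = "list",
                        repeatability = "list"))

#' SimulationConfig: forward model settings for synthetic plates
#'
#' Describes the data-generating truth for [simulatePlate()]: the inhibition
#' curve parameters, the control/blank OD levels, the multiplicative read
#' noise CV, the calibration dilution series, replicate counts, samples and
#' the random seed.
#'
#' @slot truth named numeric (A, t, y0) of the true inhibition curve
#' @slot controlOdA mean OD of the 100%-reaction control
#' @slot blankOdB mean OD of the blank
#' @slot noiseCv multiplicative OD noise CV in percent (>= 0)
#' @slot standardSeries standard concentrations, ug/mL
#' @slot replicates wells per standard level / sample / control group
#' @slot samples data.frame with columns sample_id, concentration (true
#'   ug/mL at the loaded dilution), dilution
#' @slot seed integer random seed
#' @seealso [simulatePlate()], [simulateValidationDataset()]
#' @export
setClass("SimulationConfig",
         representation(truth = "numeric", controlOdA = "numeric",
                        blankOdB = "numeric", noiseCv = "numeric",
                        standardSeries = "numeric", replicates = "integer",
                        samples = "data.frame", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (!all(c("A", "t", "y0") %in% names(object@truth)))
    return("truth must be a named numeric with A, t, y0")
  if (object@truth[["t"]] <= 0) return("truth t must be > 0")
  if (object@blankOdB < 0) return("blank OD must be >= 0")
  if (object@controlOdA <= object@blankOdB)
    return("control OD must exceed blank OD")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (any(object@standardSeries <= 0))
    return("standard concentrations must be > 0")
  if (nrow(object@samples) &&
      !all(c("sample_id", "concentration", "dilution") %in% names(object@samples)))
    return("samples needs columns sample_id, concentration, dilution")
  TRUE
})
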