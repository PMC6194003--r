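#' Read a plate CSV into a PlateReadout
#'
#' The plate dialect is long-format, one row per well, with a header row and
#' columns `well` (e.g. "A1", row letter + column number), `role`,
#' `group_id`, `concentration` (ug/mL on the pre-mix lysate basis; empty for
#' non-standards) and `od450`. Lines starting with `#` are comments. All
#' PlateWell invariants are enforced with row-level error messages.
#'
#' @param path CSV file path
#' @return a [PlateReadout-class]
#' @seealso [writePlateCsv()]
#' @export
readPlateCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("well", "role", "group_id", "concentration", "od450")
  if (!all(needed %in% names(df)))
    stop("plate CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  well <- as.character(df$well)
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (any(!ok))
    stop("malformed well id '", well[!ok][1], "' (expected e.g. A1..H12)",
         call. = FALSE)
  if (anyDuplicated(well))
    stop("duplicate well: ", well[duplicated(well)][1], call. = FALSE)
  bad_role <- !df$role %in% .WELL_ROLES
  if (any(bad_role))
    stop("unknown role '", df$role[bad_role][1], "'; allowed: ",
         paste(.WELL_ROLES, collapse = ", "), call. = FALSE)
  od <- suppressWarnings(as.numeric(df$od450))
  bad_od <- !is.finite(od) | od < 0
  if (any(bad_od))
    stop("invalid od450 at data row ", which(bad_od)[1],
         " (must be a number >= 0)", call. = FALSE)
  wells <- data.frame(
    row = substr(well, 1, 1),
    column = as.integer(substring(well, 2)),
    role = df$role,
    group_id = as.character(df$group_id),
    concentration = suppressWarnings(as.numeric(df$concentration)),
    od450 = od)
  new("PlateReadout", wells = wells)
}

#' Write a PlateReadout to the plate CSV dialect
#'
#' @param plate a [PlateReadout-class]
#' @param path output path
#' @return `path`, invisibly
#' @seealso [readPlateCsv()]
#' @export
writePlateCsv <- function(plate, path) {
  stopifnot(is(plate, "PlateReadout"))
  w <- plate@wells
  out <- data.frame(well = paste0(w$row, w$column), role = w$role,
                    group_id = w$group_id, concentration = w$concentration,
                    od450 = w$od450)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# galQuant plate readout; concentrations are pre-mix lysate ug/mL",
             con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# round-half-away-from-zero at `digits` decimals (base round() halves to even)
.roundHalfAway <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

.fitToList <- function(fit) {
  list(A = fit@A, t = fit@t, y0 = fit@y0, residual_ss = fit@residualSS,
       x_min = fit@xMin, x_max = fit@xMax, ldl = fit@ldl,
       converged = fit@converged, usable = fit@usable)
}

#' Write a calibration fit as JSON
#'
#' Keys: A, t, y0, residual_ss, x_min, x_max, ldl, converged, usable.
#'
#' @param fit a [CalibrationFit-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCalibrationJson <- function(fit, path) {
  stopifnot(is(fit, "CalibrationFit"))
  jsonlite::write_json(.fitToList(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a calibration fit from JSON
#'
#' @param path JSON file written by [writeCalibrationJson()]
#' @return a [CalibrationFit-class]
#' @export
readCalibrationJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("CalibrationFit", A = num(j$A), t = num(j$t), y0 = num(j$y0),
      residualSS = num(j$residual_ss), converged = isTRUE(j$converged),
      usable = isTRUE(j$usable), xMin = num(j$x_min), xMax = num(j$x_max),
      ldl = num(j$ldl), ldlAnchored = NA)
}

.resultToRow <- function(r) {
  q <- r@quantity
  data.frame(
    sample_id = r@sampleId,
    inhibition_mean = .roundHalfAway(r@inhibitionMean),
    inhibition_sd = .roundHalfAway(r@inhibitionSd),
    concentration_ug_ml = r@concentration,
    epitopes = if (r@censoring == "quantified") signif(q@count, 3) else NA_real_,
    basis = q@basis,
    censoring = r@censoring,
    dilution_factor = r@dilutionFactor)
}

#' Write a quantification report
#'
#' JSON is the canonical machine report; CSV and text are projections of the
#' same content. Per sample: inhibition mean/SD (2 decimals,
#' half-away-from-zero), interpolated concentration, epitope count at 3
#' significant figures with its basis, and the censoring flag (a sample below
#' the detection limit renders as `< LDL` with the LDL value in the text
#' projection). A calibration section lists (A, t, y0), residual SS, LDL and
#' the validity range; the QC section mirrors the [QCReport-class].
#'
#' @param results list of [SampleResult-class] (may be empty for a QC-only
#'   report)
#' @param qc a [QCReport-class] or NULL
#' @param fit a [CalibrationFit-class] or NULL
#' @param path output path
#' @param format "json", "csv" or "text"
#' @return `path`, invisibly
#' @export
writeReport <- function(results, qc = NULL, fit = NULL, path,
                        format = c("json", "csv", "text")) {
  format <- match.arg(format)
  stopifnot(is.list(results))
  rows <- if (length(results)) do.call(rbind, lapply(results, .resultToRow))
          else NULL
  if (format == "json") {
    payload <- list(
      samples = if (is.null(rows)) list() else rows,
      calibration = if (is.null(fit)) NULL else .fitToList(fit),
      qc = if (is.null(qc)) NULL else list(
        negative_gate = qc@negativeGate,
        positive_gate = qc@positiveGate,
        repeatability = qc@repeatability))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows", pretty = TRUE)
  } else if (format == "csv") {
    if (is.null(rows))
      rows <- data.frame(sample_id = character(), censoring = character())
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("alpha-Gal antigen quantification report", con)
    if (!is.null(fit)) {
      writeLines(sprintf(
        "calibration: A = %.6g, t = %.6g, y0 = %.6g; residual SS %.6g",
        fit@A, fit@t, fit@y0, fit@residualSS), con)
      writeLines(sprintf("  range [%.4g, %.4g] ug/mL; LDL %.4g ug/mL",
                         fit@xMin, fit@xMax, fit@ldl), con)
    }
    for (r in results) {
      if (r@censoring == "quantified") {
        writeLines(sprintf("%s: %.3g epitopes (%s); %.4g ug/mL; inhibition %.2f%%",
                           r@sampleId, r@quantity@count, r@quantity@basis,
                           r@concentration, .roundHalfAway(r@inhibitionMean)),
                   con)
      } else if (r@censoring == "below_ldl") {
        writeLines(sprintf("%s: < LDL (%.4g ug/mL); inhibition %.2f%%",
                           r@sampleId, if (is.null(fit)) NA_real_ else fit@ldl,
                           .roundHalfAway(r@inhibitionMean)), con)
      } else {
        writeLines(sprintf("%s: above calibration range; inhibition %.2f%%",
                           r@sampleId, .roundHalfAway(r@inhibitionMean)), con)
      }
    }
    if (!is.null(qc)) {
      if (length(qc@negativeGate))
        writeLines(sprintf("QC specificity: %s (p = %.4g)",
                           if (isTRUE(qc@negativeGate$pass)) "PASS" else "FAIL",
                           qc@negativeGate$p_value), con)
      if (length(qc@positiveGate))
        writeLines(sprintf("QC accuracy: %s (deviation %.2f%%)",
                           if (isTRUE(qc@positiveGate$pass)) "PASS" else "FAIL",
                           qc@positiveGate$deviation_percent), con)
    }
  }
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' Recognized keys (all optional): `reaction_volume_ml` (default 0.1),
#' `replicates` (3), `alpha` (0.05), `positive_gate_threshold` (15),
#' `homogeneity_threshold` (15), `certified_value`, `certified_sd`,
#' `certified_n`, `antibody_dilution` (informational, default "1:200 final").
#' Lines starting with `#` are comments.
#'
#' @param path file path, or NULL for pure defaults
#' @return named list of settings
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- list(reaction_volume_ml = 0.1, replicates = 3L, alpha = 0.05,
              positive_gate_threshold = 15, homogeneity_threshold = 15,
              certified_value = NA_real_, certified_sd = NA_real_,
              certified_n = NA_integer_, antibody_dilution = "1:200 final")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
      cfg[[key]] <- if (key == "antibody_dilution") val else as.numeric(val)
    }
  }
  if (cfg$reaction_volume_ml <= 0)
    stop("reaction_volume_ml must be > 0", call. = FALSE)
  if (cfg$positive_gate_threshold <= 0 || cfg$homogeneity_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  cfg
}
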