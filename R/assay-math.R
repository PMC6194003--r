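#' M86 inhibition rate from plate ODs
#'
#' Computes `100 * ((a - b) - (c - d)) / (a - b)` where `a` is the mean OD of
#' the 100%-reaction (non-inhibitory) control, `b` the blank OD, `c` the
#' sample well OD and `d` the blank applicable to the sample well. With a
#' single shared plate blank `d = b` (the default), so the rate reduces to
#' `100 * (a - c) / (a - b)`. Raw values outside [0, 100] are preserved;
#' flagging is the caller's concern (clamping would bias curve fits).
#'
#' @param a mean OD of the 100%-reaction control (must exceed `b`)
#' @param b mean OD of the blank
#' @param c sample well OD (vectorized)
#' @param d blank OD applicable to the sample well; defaults to `b`
#' @return inhibition rate(s) in percent
#' @examples
#' inhibitionRate(1.20, 0.10, 0.65)  # 50
#' @export
inhibitionRate <- function(a, b, c, d = b) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (any(c(a, b, c, d) < 0))
    stop("ODs must be >= 0", call. = FALSE)
  if (a <= b)
    stop(errorCondition(
      sprintf("invalid plate: no non-inhibitory signal window (a = %.4g <= b = %.4g)",
              a, b),
      class = c("galQuant_plate_invalid", "error")))
  100 * ((a - b) - (c - d)) / (a - b)
}

#' Aggregate control and blank wells into a ControlSet
#'
#' @param plate a [PlateReadout-class]
#' @return a [ControlSet-class] with `a` = mean control OD, `b` = mean blank
#'   OD and replicate counts
#' @export
aggregateControls <- function(plate) {
  stopifnot(is(plate, "PlateReadout"))
  w <- plate@wells
  ctl <- w$od450[w$role == "full_reaction_control"]
  blk <- w$od450[w$role == "blank"]
  if (!length(ctl))
    stop("plate has no 'full_reaction_control' wells", call. = FALSE)
  if (!length(blk))
    stop("plate has no 'blank' wells", call. = FALSE)
  new("ControlSet", a = mean(ctl), b = mean(blk),
      nControl = length(ctl), nBlank = length(blk))
}

# deterministic initialization for the exponential-saturation fit: y0 from the top
# of the observed inhibition, A from the drop at the lowest level, t from a
# log-linear regression of (y0 - Y) on x.
.calibStart <- function(x, y) {
  y0 <- max(y)
  mlow <- mean(y[x == min(x)])
  A <- mlow - y0
  if (A >= 0) A <- -max(1, diff(range(y)))
  resid0 <- y0 - y
  keep <- resid0 > 0
  t0 <- NA_real_
  if (sum(keep) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(resid0[keep]) ~ x[keep]))[2])
    if (is.finite(sl) && sl < 0) t0 <- -1 / sl
  }
  if (!is.finite(t0) || t0 <= 0) t0 <- stats::median(x)
  list(A = A, logt = log(t0), y0 = y0)
}

#' Fit the calibration curve Y = A*exp(-x/t) + y0
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) over all replicate
#' points of the Gal-BSA standard series, with `t > 0` enforced by optimizing
#' `log t`. The validity range is the span of standard concentrations; the
#' lower detection limit is determined from the same replicate data (see
#' [determineLdl()]). A converged fit with `A >= 0` (non-increasing curve) is
#' flagged not usable and downstream quantification refuses it.
#'
#' @param points data.frame with columns `concentration` (ug/mL, > 0) and
#'   `inhibition` (percent), one row per replicate measurement
#' @param alpha significance level for the per-level detectability test used
#'   for the LDL; default 0.05
#' @param negRefInhibition optional numeric vector of negative-reference
#'   inhibition rates, used as the LDL fallback criterion below 3 replicates
#' @return a [CalibrationFit-class]
#' @examples
#' x <- c(20, 10, 5, 2.5, 1.25, 0.625, 0.313, 0.156, 0.078, 0.039)
#' pts <- data.frame(concentration = rep(x, each = 3),
#'                   inhibition = rep(-95 * exp(-x / 2) + 95, each = 3))
#' fit <- fitCalibration(pts)
#' coef(fit)
#' @export
fitCalibration <- function(points, alpha = 0.05, negRefInhibition = NULL) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "inhibition") %in% names(points)))
  x <- points$concentration
  y <- points$inhibition
  if (any(!is.finite(x)) || any(x <= 0))
    stop("standard concentrations must be finite and > 0", call. = FALSE)
  if (length(unique(x)) < 4L)
    stop(errorCondition(
      "insufficient design: need >= 4 distinct standard concentrations to fit 3 parameters",
      class = c("galQuant_insufficient_design", "error")))

  start <- .calibStart(x, y)
  fitEnv <- data.frame(x = x, y = y)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / exp(logt)) + y0,
                      data = fitEnv, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(nls_fit)) {
    return(new("CalibrationFit", A = NA_real_, t = NA_real_, y0 = NA_real_,
               residualSS = NA_real_, converged = FALSE, usable = FALSE,
               xMin = min(x), xMax = max(x), ldl = NA_real_,
               ldlAnchored = NA))
  }
  cf <- stats::coef(nls_fit)
  A <- unname(cf["A"]); t <- exp(unname(cf["logt"])); y0 <- unname(cf["y0"])
  rss <- sum(stats::resid(nls_fit)^2)
  usable <- A < 0 && t > 0

  ldl <- NA_real_
  anchored <- NA
  if (usable) {
    det <- tryCatch(
      determineLdl(points, alpha = alpha, negRefInhibition = negRefInhibition),
      galQuant_assay_failure = function(e) NULL)
    if (is.null(det)) {
      usable <- FALSE  # no level detected: the series carries no signal
    } else {
      ldl <- det$ldl
      anchored <- det$anchored
    }
  }
  new("CalibrationFit", A = A, t = t, y0 = y0, residualSS = rss,
      converged = TRUE, usable = usable, xMin = min(x), xMax = max(x),
      ldl = ldl, ldlAnchored = anchored)
}

#' Predicted inhibition at a concentration
#'
#' Evaluates `A * exp(-x/t) + y0` for a converged fit.
#'
#' @param fit a converged [CalibrationFit-class]
#' @param x concentration(s), ug/mL
#' @return predicted inhibition rate(s), percent
#' @export
predictInhibition <- function(fit, x) {
  stopifnot(is(fit, "CalibrationFit"))
  if (!fit@converged) stop("fit did not converge", call. = FALSE)
  fit@A * exp(-x / fit@t) + fit@y0
}

#' Inverse prediction: concentration at a given inhibition rate
#'
#' Exact inverse of [predictInhibition()]: `x = -t * log((y - y0)/A)`.
#' Signals a classed error `galQuant_above_range` when `y` is at or above the
#' plateau `y0` or the inverted concentration exceeds the validity range, and
#' `galQuant_below_range` when it falls below the lowest standard.
#'
#' @param fit a usable [CalibrationFit-class]
#' @param y inhibition rate, percent (scalar)
#' @param enforceRange censor outside `[xMin, xMax]` (default TRUE); set
#'   FALSE for diagnostic extrapolation
#' @return concentration in ug/mL on the standard-curve basis
#' @export
invertCalibration <- function(fit, y, enforceRange = TRUE) {
  stopifnot(is(fit, "CalibrationFit"), length(y) == 1L, is.finite(y))
  if (!fit@converged) stop("fit did not converge", call. = FALSE)
  if (!fit@usable)
    stop("fit is not usable (non-monotone or degenerate); quantification refused",
         call. = FALSE)
  ratio <- (y - fit@y0) / fit@A
  if (ratio <= 0)
    stop(errorCondition(
      sprintf("inhibition %.4g%% is at or above the fitted plateau (y0 = %.4g%%)",
              y, fit@y0),
      class = c("galQuant_above_range", "error")))
  xhat <- -fit@t * log(ratio)
  if (enforceRange) {
    if (xhat > fit@xMax)
      stop(errorCondition(
        sprintf("interpolated concentration %.4g exceeds the validity range (max %.4g ug/mL)",
                xhat, fit@xMax),
        class = c("galQuant_above_range", "error")))
    if (xhat < fit@xMin)
      stop(errorCondition(
        sprintf("interpolated concentration %.4g is below the lowest standard (%.4g ug/mL)",
                xhat, fit@xMin),
        class = c("galQuant_below_range", "error")))
  }
  xhat
}

#' IC50 of the fitted calibration curve
#'
#' Concentration giving 50% inhibition of M86 binding. Decellularized
#' biomaterials often never reach 50% inhibition; in that case (plateau below
#' 50%) a classed error `galQuant_ic50_unreachable` is signalled.
#'
#' @param fit a usable [CalibrationFit-class]
#' @return IC50 in ug/mL
#' @export
ic50 <- function(fit) {
  stopifnot(is(fit, "CalibrationFit"))
  if (!fit@converged) stop("fit did not converge", call. = FALSE)
  if (fit@y0 <= 50)
    stop(errorCondition(
      sprintf("curve plateau (%.4g%%) never reaches 50%% inhibition", fit@y0),
      class = c("galQuant_ic50_unreachable", "error")))
  invertCalibration(fit, 50, enforceRange = FALSE)
}

#' Lower detection limit of the calibration series
#'
#' A standard level is "detected" when its replicate inhibition rates are
#' significantly greater than zero: a one-sided one-sample t-test at level
#' `alpha` with >= 3 replicates; with fewer, a level is detected when its
#' mean inhibition exceeds 3 times the SD of the negative-reference
#' inhibition rates (which must then be supplied). The LDL is the lowest
#' detected concentration whose next lower tested level (if any) is not
#' detected; when every tested level is detected the LDL defaults to the
#' lowest tested concentration, flagged unanchored.
#'
#' @inheritParams fitCalibration
#' @return list with `ldl` (ug/mL), `anchored` (logical: an undetected level
#'   sits below it), and `detected` (named logical per ascending level)
#' @export
determineLdl <- function(points, alpha = 0.05, negRefInhibition = NULL) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "inhibition") %in% names(points)))
  levs <- sort(unique(points$concentration))
  detected <- vapply(levs, function(lv) {
    vals <- points$inhibition[points$concentration == lv]
    if (length(vals) >= 3L && stats::sd(vals) > 0) {
      stats::t.test(vals, mu = 0, alternative = "greater")$p.value < alpha
    } else if (!is.null(negRefInhibition) && length(negRefInhibition) >= 2L) {
      mean(vals) > 3 * stats::sd(negRefInhibition)
    } else {
      # degenerate (constant or short) replicate set without a negative
      # reference: fall back to a strict positivity check
      all(vals > 0) && mean(vals) > 0
    }
  }, logical(1))
  names(detected) <- as.character(levs)
  if (!any(detected))
    stop(errorCondition(
      "assay failure: no standard concentration is detectable",
      class = c("galQuant_assay_failure", "error")))
  # lowest detected level whose next lower tested level is undetected;
  # runs of undetected levels above it are ignored (monotone reading)
  first_det <- which(detected)[1]
  if (first_det == 1L) {
    list(ldl = levs[1], anchored = FALSE, detected = detected)
  } else {
    list(ldl = levs[first_det], anchored = TRUE, detected = detected)
  }
}

#' Quantify a sample against a fitted calibration curve
#'
#' Runs the full quantification chain for one sample: per-replicate
#' inhibition rates from the plate controls, inverse prediction of the
#' Gal-BSA-equivalent concentration, dilution correction, conversion to an
#' epitope count in the reaction aliquot, and normalization per mg tissue or
#' per cell. Out-of-range signals become censoring flags rather than errors:
#' `below_ldl` when the interpolated concentration falls below the fit's
#' detection limit (or below the lowest standard), `above_range` when the
#' inhibition sits at/above the plateau or beyond the highest standard.
#'
#' @param fit a usable [CalibrationFit-class]
#' @param sampleOds numeric vector of replicate OD450 values for the sample
#' @param controls a [ControlSet-class] from the same plate
#' @param sampleId sample label
#' @param dilutionFactor dilution applied to the lysate before loading
#'   (>= 1); the reported concentration is multiplied by it
#' @param massMg sample mass (mg) contained in the reaction aliquot of the
#'   undiluted lysate, for a per-mg result
#' @param cells cell count in the reaction aliquot of the undiluted lysate,
#'   for a per-cell result
#' @param massBasis "wet" or "dry" (freeze-dried), metadata carried on the
#'   per-mg basis; no wet/dry conversion is attempted
#' @param reactionVolumeMl volume of sample lysate loaded per reaction (mL);
#'   default 0.1 (the 100 uL aliquot)
#' @param constants a [ConversionConstants-class]
#' @return a [SampleResult-class]
#' @export
quantifySample <- function(fit, sampleOds, controls, sampleId = "sample",
                           dilutionFactor = 1, massMg = NULL, cells = NULL,
                           massBasis = c("wet", "dry"),
                           reactionVolumeMl = 0.1,
                           constants = buildConversionConstants()) {
  stopifnot(is(fit, "CalibrationFit"), is(controls, "ControlSet"),
            is.numeric(sampleOds), length(sampleOds) >= 1L)
  if (!fit@converged || !fit@usable)
    stop("calibration fit is not usable; quantification refused", call. = FALSE)
  if (reactionVolumeMl <= 0) stop("reactionVolumeMl must be > 0", call. = FALSE)
  if (!is.null(massMg) && !is.null(cells))
    stop("give massMg or cells, not both", call. = FALSE)
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1", call. = FALSE)
  massBasis <- match.arg(massBasis)
  if (length(sampleOds) < 3L)
    warning("fewer than 3 replicate wells; the method's default design is 3 parallel wells")

  inh <- inhibitionRate(controls@a, controls@b, sampleOds)
  inh_mean <- mean(inh)
  inh_sd <- if (length(inh) >= 2L) stats::sd(inh) else NA_real_

  xhat <- tryCatch(invertCalibration(fit, inh_mean),
                   galQuant_above_range = function(e) "above",
                   galQuant_below_range = function(e) "below")
  emptyQ <- new("EpitopeQuantity", count = 0, basis = "per_reaction",
                galbsaEquivalentMass = 0)
  if (identical(xhat, "above")) {
    return(new("SampleResult", sampleId = sampleId, inhibitionMean = inh_mean,
               inhibitionSd = inh_sd, concentration = NA_real_,
               quantity = emptyQ, censoring = "above_range",
               dilutionFactor = dilutionFactor))
  }
  if (identical(xhat, "below") || (!is.na(fit@ldl) && xhat < fit@ldl)) {
    return(new("SampleResult", sampleId = sampleId, inhibitionMean = inh_mean,
               inhibitionSd = inh_sd, concentration = NA_real_,
               quantity = emptyQ, censoring = "below_ldl",
               dilutionFactor = dilutionFactor))
  }

  conc <- xhat * dilutionFactor                      # ug/mL, undiluted lysate
  mass_g <- conc * reactionVolumeMl * 1e-6           # g Gal-BSA equivalent
  q <- massToEpitopes(mass_g, constants)
  if (!is.null(massMg)) {
    if (massMg <= 0) stop("massMg must be > 0", call. = FALSE)
    q <- new("EpitopeQuantity", count = q@count / massMg,
             basis = if (massBasis == "wet") "per_mg_wet" else "per_mg_dry",
             galbsaEquivalentMass = q@galbsaEquivalentMass / massMg)
  } else if (!is.null(cells)) {
    if (cells <= 0) stop("cells must be > 0", call. = FALSE)
    q <- new("EpitopeQuantity", count = q@count / cells, basis = "per_cell",
             galbsaEquivalentMass = q@galbsaEquivalentMass / cells)
  }
  new("SampleResult", sampleId = sampleId, inhibitionMean = inh_mean,
      inhibitionSd = inh_sd, concentration = conc, quantity = q,
      censoring = "quantified", dilutionFactor = dilutionFactor)
}

#' @rdname CalibrationFit-class
#' @param object a CalibrationFit
#' @param ... unused
#' @export
setMethod("coef", "CalibrationFit", function(object, ...) {
  c(A = object@A, t = object@t, y0 = object@y0)
})

#' @rdname CalibrationFit-class
#' @export
ldl <- function(object) {
  stopifnot(is(object, "CalibrationFit"))
  object@ldl
}

#' @rdname CalibrationFit-class
#' @export
isUsable <- function(object) {
  stopifnot(is(object, "CalibrationFit"))
  isTRUE(object@usable)
}

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit: Y = A*exp(-x/t) + y0\n")
  if (object@converged) {
    cat(sprintf("  A = %.4g, t = %.4g ug/mL, y0 = %.4g %%\n",
                object@A, object@t, object@y0))
    cat(sprintf("  residual SS = %.4g; usable: %s\n",
                object@residualSS, object@usable))
  } else {
    cat("  <not converged>\n")
  }
  cat(sprintf("  validity range: [%.4g, %.4g] ug/mL; LDL = %.4g ug/mL%s\n",
              object@xMin, object@xMax, object@ldl,
              if (isTRUE(!object@ldlAnchored)) " (unanchored)" else ""))
})

setMethod("show", "ControlSet", function(object) {
  cat(sprintf("ControlSet: a = %.4g (n = %d), b = %.4g (n = %d)\n",
              object@a, object@nControl, object@b, object@nBlank))
})

setMethod("show", "SampleResult", function(object) {
  cat(sprintf("SampleResult '%s': inhibition %.2f%%", object@sampleId,
              object@inhibitionMean))
  if (!is.na(object@inhibitionSd)) cat(sprintf(" (SD %.2f)", object@inhibitionSd))
  cat("\n")
  if (object@censoring == "quantified") {
    cat(sprintf("  concentration %.4g ug/mL; %.3g epitopes (%s)\n",
                object@concentration, object@quantity@count,
                object@quantity@basis))
  } else {
    cat(sprintf("  censored: %s\n", object@censoring))
  }
})
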