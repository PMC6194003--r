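#' Mean, sample SD and coefficient of variation
#'
#' The summary convention used throughout the method's validation tables:
#' sample SD (n - 1 denominator) and CV (synonymously RSD) as
#' `100 * sd/mean` percent.
#'
#' @param values numeric vector, length >= 2
#' @return list with `mean`, `sd`, `cv_percent`, `n`
#' @examples
#' summaryStats(c(5.78, 6.88, 6.81, 5.45, 6.65, 6.83, 6.65, 6.44, 8.43))
#' @export
summaryStats <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L)
    stop("dispersion undefined: need at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  list(mean = m, sd = s, cv_percent = 100 * s / m, n = length(values))
}

# Welch two-sample t-test from summary statistics (no raw data needed);
# returns the two-sided p-value.
.welchFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 == 0) return(if (m1 == m2) 1 else 0)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Specificity gate: negative reference vs 100%-reaction control
#'
#' The negative reference (human-derived, alpha-Gal free) must be
#' indistinguishable from the non-inhibitory control: a Welch two-sample
#' t-test of the OD values, passing when `p > alpha` (no inhibition, hence no
#' false positive). With zero variance in both groups the exact-equality rule
#' applies: pass iff the means are equal.
#'
#' @param negOds OD450 values of negative-reference wells (>= 2)
#' @param controlOds OD450 values of 100%-reaction control wells (>= 2)
#' @param alpha significance level, default 0.05
#' @return list with `pass`, `p_value`, `neg_mean_od`, `control_mean_od`
#' @export
negativeSpecificityGate <- function(negOds, controlOds, alpha = 0.05) {
  stopifnot(is.numeric(negOds), is.numeric(controlOds))
  if (length(negOds) < 2L || length(controlOds) < 2L)
    stop("need at least 2 OD values per group", call. = FALSE)
  if (stats::sd(negOds) == 0 && stats::sd(controlOds) == 0) {
    p <- if (mean(negOds) == mean(controlOds)) 1 else 0
  } else {
    p <- stats::t.test(negOds, controlOds, var.equal = FALSE)$p.value
  }
  list(pass = p > alpha, p_value = p,
       neg_mean_od = mean(negOds), control_mean_od = mean(controlOds))
}

#' Accuracy gate: measured positive reference vs certified value
#'
#' The sensitivity check of the run: the measured mean epitope content of the
#' positive reference material must deviate from its certified value by less
#' than `threshold` percent (default 15).
#'
#' @param measured measured epitopes/mg values (>= 1)
#' @param spec a positive [ReferenceMaterialSpec-class], or a single numeric
#'   certified value
#' @param threshold maximal relative deviation, percent
#' @return list with `pass`, `measured_mean`, `certified_value`,
#'   `deviation_percent`
#' @export
positiveAccuracyGate <- function(measured, spec, threshold = 15) {
  stopifnot(is.numeric(measured), length(measured) >= 1L)
  if (is(spec, "ReferenceMaterialSpec")) {
    if (spec@kind != "positive")
      stop("accuracy gate requires a positive reference material", call. = FALSE)
    certified <- spec@certifiedValue
  } else {
    certified <- spec
  }
  if (!is.numeric(certified) || is.na(certified) || certified <= 0)
    stop("certified value missing or non-positive", call. = FALSE)
  m <- mean(measured)
  dev <- 100 * abs(m - certified) / certified
  list(pass = dev < threshold, measured_mean = m,
       certified_value = certified, deviation_percent = dev)
}

#' Repeatability report: inter-day, intra-day and pooled CVs
#'
#' Summarizes repeated IC50 (or content) determinations: per-group
#' [summaryStats()] plus a pooled summary over all values.
#'
#' @param interDay inter-day values (>= 2 for a CV), or NULL
#' @param intraDay intra-day values (>= 2 for a CV), or NULL
#' @return list with `inter_day`, `intra_day`, `total` summaries (a missing
#'   group yields a partial report with a warning)
#' @examples
#' repeatabilityReport(c(6.65, 6.62, 5.73, 6.94), c(6.08, 5.71, 5.07, 4.60))
#' @export
repeatabilityReport <- function(interDay = NULL, intraDay = NULL) {
  if (is.null(interDay) && is.null(intraDay))
    stop("need at least one of interDay, intraDay", call. = FALSE)
  if (is.null(interDay) || is.null(intraDay))
    warning("partial repeatability design: one group missing")
  out <- list(inter_day = NULL, intra_day = NULL, total = NULL)
  if (!is.null(interDay)) out$inter_day <- summaryStats(interDay)
  if (!is.null(intraDay)) out$intra_day <- summaryStats(intraDay)
  out$total <- summaryStats(c(interDay, intraDay))
  out
}

#' Homogeneity check of a reference-material batch
#'
#' Between-unit homogeneity is accepted when the RSD over units is below the
#' threshold (default 15%).
#'
#' @param unitValues epitopes/mg per unit (>= 3 units)
#' @param rsdThreshold maximal RSD, percent
#' @return list with `pass`, `rsd_percent`, `mean`, `sd`, `n`
#' @export
homogeneityCheck <- function(unitValues, rsdThreshold = 15) {
  stopifnot(is.numeric(unitValues))
  if (length(unitValues) < 3L)
    stop("insufficient units: homogeneity needs >= 3", call. = FALSE)
  s <- summaryStats(unitValues)
  list(pass = s$cv_percent < rsdThreshold, rsd_percent = s$cv_percent,
       mean = s$mean, sd = s$sd, n = s$n)
}

#' Stability comparison of stored reference material against its certified value
#'
#' Each storage-condition group (given as mean/SD/n summaries) is compared to
#' the certified (identified) value with a Welch t-test computed from summary
#' statistics. A condition is flagged unstable only for degradation: `p <
#' alpha` AND group mean below the identified mean; significantly elevated
#' means are reported but not flagged.
#'
#' @param groups data.frame with columns `condition`, `mean`, `sd`, `n`
#' @param identified list with `mean`, `sd`, `n` of the certified value
#' @param alpha significance level, default 0.05
#' @return the input data.frame with added columns `p_value`, `unstable`
#'   (groups with n < 2 are skipped with a warning, p = NA)
#' @export
stabilityCompare <- function(groups, identified, alpha = 0.05) {
  stopifnot(is.data.frame(groups),
            all(c("condition", "mean", "sd", "n") %in% names(groups)),
            all(c("mean", "sd", "n") %in% names(identified)))
  p <- rep(NA_real_, nrow(groups))
  for (i in seq_len(nrow(groups))) {
    if (groups$n[i] < 2L) {
      warning("condition '", groups$condition[i], "' skipped: n < 2")
      next
    }
    p[i] <- .welchFromSummary(groups$mean[i], groups$sd[i], groups$n[i],
                              identified$mean, identified$sd, identified$n)
  }
  groups$p_value <- p
  groups$unstable <- !is.na(p) & p < alpha & groups$mean < identified$mean
  groups
}

#' Assemble a QC report from gate outcomes
#'
#' @param negativeGate result of [negativeSpecificityGate()] (or empty list)
#' @param positiveGate result of [positiveAccuracyGate()] (or empty list)
#' @param repeatability result of [repeatabilityReport()] (or empty list)
#' @return a [QCReport-class]
#' @export
qcReport <- function(negativeGate = list(), positiveGate = list(),
                     repeatability = list()) {
  new("QCReport", negativeGate = negativeGate, positiveGate = positiveGate,
      repeatability = repeatability)
}

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  ng <- object@negativeGate
  if (length(ng))
    cat(sprintf("  specificity (negative ref): %s (p = %.4g)\n",
                if (isTRUE(ng$pass)) "PASS" else "FAIL", ng$p_value))
  pg <- object@positiveGate
  if (length(pg))
    cat(sprintf("  accuracy (positive ref)   : %s (deviation %.2f%%)\n",
                if (isTRUE(pg$pass)) "PASS" else "FAIL", pg$deviation_percent))
  rp <- object@repeatability
  if (length(rp) && !is.null(rp$total))
    cat(sprintf("  repeatability total CV    : %.2f%%\n", rp$total$cv_percent))
})
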