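#' Build the Gal-BSA mass-to-epitope conversion constants
#'
#' Derives the molecule and epitope number densities of the Gal-BSA
#' calibration antigen from the carrier molar mass and the epitope
#' substitution degree. With the defaults (66.33 kDa, 20 epitopes/molecule)
#' the densities are 9.08e18 molecules/g and 1.82e20 epitopes/g at three
#' significant figures.
#'
#' @param bsaMolarMassKda molar mass of the carrier protein in kDa (> 0);
#'   default 66.33 (BSA)
#' @param epitopesPerMolecule alpha-Gal epitopes per Gal-BSA molecule
#'   (>= 1); default 20
#' @return a [ConversionConstants-class] object
#' @examples
#' cc <- buildConversionConstants()
#' signif(moleculesPerGram(cc), 3)  # 9.08e18
#' signif(epitopesPerGram(cc), 3)   # 1.82e20
#' @export
buildConversionConstants <- function(bsaMolarMassKda = 66.33,
                                     epitopesPerMolecule = 20) {
  if (!is.numeric(bsaMolarMassKda) || length(bsaMolarMassKda) != 1L ||
      !is.finite(bsaMolarMassKda) || bsaMolarMassKda <= 0)
    stop("bsaMolarMassKda must be a single positive number", call. = FALSE)
  if (!is.numeric(epitopesPerMolecule) || length(epitopesPerMolecule) != 1L ||
      !is.finite(epitopesPerMolecule) || epitopesPerMolecule < 1)
    stop("epitopesPerMolecule must be a single number >= 1", call. = FALSE)
  avogadro <- 6.02214e23
  mpg <- avogadro / (bsaMolarMassKda * 1000)  # kDa -> g/mol
  new("ConversionConstants",
      bsaMolarMassKda = bsaMolarMassKda,
      epitopesPerMolecule = epitopesPerMolecule,
      avogadro = avogadro,
      moleculesPerGram = mpg,
      epitopesPerGram = mpg * epitopesPerMolecule)
}

#' @describeIn buildConversionConstants derived molecules per gram
#' @param x a ConversionConstants object
#' @export
moleculesPerGram <- function(x) {
  stopifnot(is(x, "ConversionConstants"))
  x@moleculesPerGram
}

#' @describeIn buildConversionConstants derived epitopes per gram
#' @export
epitopesPerGram <- function(x) {
  stopifnot(is(x, "ConversionConstants"))
  x@epitopesPerGram
}

#' Convert a Gal-BSA-equivalent mass to an epitope count
#'
#' The core quantification arithmetic: a sample whose inhibition matches that
#' of `mass` grams of Gal-BSA carries `mass * epitopesPerGram` alpha-Gal
#' epitopes. The returned quantity is on the per-reaction basis; normalize to
#' per-mg or per-cell with [quantifySample()].
#'
#' @param mass grams of Gal-BSA equivalent (>= 0)
#' @param constants a [ConversionConstants-class]; default
#'   `buildConversionConstants()`
#' @return an [EpitopeQuantity-class] with basis `per_reaction`
#' @examples
#' q <- massToEpitopes(3.9e-9)  # the 0.039 ug/mL level in a 100 uL reaction
#' signif(epitopeCount(q), 2)   # 7.1e11
#' @export
massToEpitopes <- function(mass, constants = buildConversionConstants()) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass < 0)
    stop("mass must be a single non-negative number (grams)", call. = FALSE)
  new("EpitopeQuantity", count = mass * constants@epitopesPerGram,
      basis = "per_reaction", galbsaEquivalentMass = mass)
}

#' @rdname EpitopeQuantity-class
#' @param x an EpitopeQuantity
#' @export
epitopeCount <- function(x) {
  stopifnot(is(x, "EpitopeQuantity"))
  x@count
}

#' @rdname EpitopeQuantity-class
#' @export
quantityBasis <- function(x) {
  stopifnot(is(x, "EpitopeQuantity"))
  x@basis
}

#' Percent antigen reduction between an untreated and a treated sample
#'
#' `100 * (1 - treated/untreated)` on matching bases; the decellularization
#' efficiency metric.
#'
#' @param untreated,treated [EpitopeQuantity-class] objects on the same basis
#' @return percent reduction (may be negative if treated exceeds untreated)
#' @examples
#' u <- new("EpitopeQuantity", count = 2.49e15, basis = "per_mg_wet",
#'          galbsaEquivalentMass = 0)
#' t <- new("EpitopeQuantity", count = 1.6e13, basis = "per_mg_wet",
#'          galbsaEquivalentMass = 0)
#' antigenReduction(u, t)  # 99.36
#' @export
antigenReduction <- function(untreated, treated) {
  stopifnot(is(untreated, "EpitopeQuantity"), is(treated, "EpitopeQuantity"))
  if (untreated@basis != treated@basis)
    stop("basis mismatch: untreated is '", untreated@basis,
         "', treated is '", treated@basis, "'", call. = FALSE)
  if (untreated@count <= 0)
    stop("untreated count must be > 0", call. = FALSE)
  100 * (1 - treated@count / untreated@count)
}

setMethod("show", "ConversionConstants", function(object) {
  cat("ConversionConstants\n")
  cat(sprintf("  carrier molar mass : %.2f kDa\n", object@bsaMolarMassKda))
  cat(sprintf("  epitopes/molecule  : %g\n", object@epitopesPerMolecule))
  cat(sprintf("  molecules/g        : %.3g\n", object@moleculesPerGram))
  cat(sprintf("  epitopes/g         : %.3g\n", object@epitopesPerGram))
})

setMethod("show", "EpitopeQuantity", function(object) {
  cat(sprintf("EpitopeQuantity: %.3g epitopes (%s)\n",
              object@count, object@basis))
})
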