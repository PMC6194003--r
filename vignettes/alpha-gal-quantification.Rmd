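---
title: "Quantifying alpha-Gal antigen by M86 ELISA inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alpha-Gal antigen by M86 ELISA inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galQuant)
```

## The assay and its model

The alpha-Gal epitope (Gal&alpha;1-3Gal&beta;1-4GlcNAc-R) is the major
xenoantigen of non-primate mammalian tissue; quantifying how much of it
remains in a decellularized biomaterial or a GGTA1-knockout cell line is a
core safety question for animal-derived implants. galQuant implements the
quantitative workflow of an ELISA *inhibition* assay with the monoclonal
anti-Gal IgM antibody M86: sample antigen is pre-incubated with M86,
antigen-bound antibody is removed, and the *remaining* antibody is read out
on a Gal-BSA-coated plate. Signal therefore **decreases** with increasing
sample antigen.

Two small equations carry the whole method.

**Inhibition rate.** For a well with OD450 `c`, against the plate's
100%-reaction (non-inhibitory) control `a` and blank `b`:

$$I = 100 \times \frac{(a-b)-(c-d)}{a-b}\ \%$$

`d` is the blank applicable to the sample well. The assay runs a single
shared plate blank (lysis buffer alone), so `d = b` and the rate reduces to
`100(a-c)/(a-b)`. A plate with `a <= b` has no signal window and is
rejected outright. Raw rates below 0% or above 100% are *kept* — clamping
them would bias the curve fit — and only flagged at reporting time.

**Calibration curve.** Inhibition versus the concentration `x` (&mu;g/mL) of
a Gal-BSA standard series follows an exponential saturation curve

$$Y(x) = A\,e^{-x/t} + y_0,$$

with amplitude `A` (negative for an increasing curve), decay scale `t`
(&mu;g/mL) and plateau `y0` (%). The idealized curve anchored by the rate
formula has `A = -100`, `y0 = 100`: 0% inhibition with no antigen, complete
inhibition at saturation. Inverse prediction is closed-form,
`x = -t log((y - y0)/A)`, and `quantifySample()` uses it to interpolate each
sample's Gal-BSA-equivalent concentration.

**From concentration to epitopes.** Gal-BSA has molar mass ~66.33 kDa and
~20 epitopes per molecule, giving $6.02214\times 10^{23} / 66330 \approx
9.08\times10^{18}$ molecules/g and $1.82\times10^{20}$ epitopes/g. A sample
interpolated at `x` &mu;g/mL in the 100 &mu;L reaction aliquot carries
$x \cdot 0.1\,\mathrm{mL} \cdot 10^{-6} \cdot 1.82\times10^{20}$ epitopes per
reaction, normalized per mg tissue or per cell by the loaded amount. These
constants are treated as exact method parameters; counts are stored as
doubles (tissue-level counts exceed $10^{17}$, so integer storage adds
nothing).

```{r constants}
cc <- buildConversionConstants()
signif(moleculesPerGram(cc), 3)
signif(epitopesPerGram(cc), 3)
# epitopes in a 100 uL reaction at the 0.039 ug/mL detection limit
signif(epitopeCount(massToEpitopes(0.039 * 0.1 * 1e-6, cc)), 2)
```

## Fitting: choices and numerical behaviour

`fitCalibration()` minimizes unweighted squared residuals over **all
replicate points** (not replicate means) with Levenberg–Marquardt
(`minpack.lm::nlsLM`). Positivity of `t` is enforced by optimizing `log t`;
`A` and `y0` are unconstrained, but a converged fit with `A >= 0` — a flat
or decreasing curve — is flagged unusable and quantification against it is
refused. Initialization is deterministic and inside the basin for monotone
data: `y0` starts at the maximum observed inhibition, `A` at the
lowest-level mean minus that, and `t` from a log-linear regression of
`y0 - Y` on `x`, falling back to the median concentration when the
regression is uninformative.

The fitted curve's validity range is the span of the standard series
(default 20 down to 0.039 &mu;g/mL in ten two-fold steps). There is **no
extrapolation**: an inhibition at or above the plateau, or mapping beyond
the highest standard, censors the sample as `above_range`; one mapping
below the detection limit censors as `below_ldl`. Censoring is a result,
not an error.

## Detection limit

The assay defines its lower detection limit operationally: dilute the
standard until a level is no longer detectable; the next level up is the
LDL. The method leaves "detectable" qualitative, so the package fixes an
explicit criterion: a level is detected when its replicate inhibition
rates are significantly above zero by a one-sided one-sample *t*-test at
`alpha = 0.05`; with fewer than three replicates it falls back to the mean
exceeding three standard deviations of the negative-reference inhibition
values. When every tested level is detected, the LDL defaults to the lowest
tested concentration and is flagged *unanchored* — the true limit may lie
lower. At the series above, the limit sits at 0.039 &mu;g/mL, i.e. 3.9 ng
Gal-BSA or about $7.1\times10^{11}$ epitopes in the 100 &mu;L reaction.

## QC gates and validation statistics

* **Specificity** (`negativeSpecificityGate()`): ODs of the alpha-Gal-free
  (human-derived) negative reference must be statistically
  indistinguishable from the 100%-reaction control — a Welch two-sample
  *t*-test passing at `p > alpha`. With two exactly constant groups the
  gate degenerates to an equality test. Welch's form is used for all
  two-group comparisons; with two groups the classical one-way ANOVA is the
  pooled-variance special case, and Welch is the robust choice at n = 3 vs
  n = 9.
* **Accuracy/sensitivity** (`positiveAccuracyGate()`): the measured mean of
  the certified positive reference must deviate from its certified
  epitopes/mg value by < 15%. (A CV against a single fixed value is not
  otherwise defined, so the gate reads the 15% figure as relative
  deviation.)
* **Repeatability** (`repeatabilityReport()`): CVs of inter-day and
  intra-day IC50 determinations plus a pooled total. All SDs are sample SDs
  (n-1); CV and RSD are synonyms, `100 * sd/mean`.
* **Homogeneity** (`homogeneityCheck()`): between-unit RSD < 15% over at
  least 3 units.
* **Stability** (`stabilityCompare()`): storage-condition groups arrive as
  mean/SD/n summaries, so the comparison against the certified value is a
  Welch *t*-test computed from summary statistics. Only *degradation* is
  flagged (p < alpha **and** mean below certified): an elevated mean is
  reported but not treated as instability. No multiplicity correction is
  applied across conditions; with 16 conditions at alpha = 0.05 the
  expected false-flag count is below one, but users comparing many
  conditions should keep this caveat in mind.

One reporting caveat found while reproducing printed validation tables of
this method family: CV cells are sometimes derived from already-rounded
means and SDs, which can differ from the CV of the raw values by a few
tenths of a percent. `summaryStats()` always computes from unrounded
values; rounding happens only at display time (percentages to 2 decimals,
half away from zero; epitope counts to 3 significant figures).

## The plate simulator

`simulatePlate()` inverts the model: from a true curve `(A, t, y0)` and
control levels `(a, b)`, each well at concentration `x` gets expected OD
`b + (a-b)(1 - Y(x)/100)`, then multiplicative Gaussian read noise
`OD * (1 + eps)`, `eps ~ N(0, cv/100)`, truncated at 0 (plate-reader noise
scales with signal; truncation rather than resampling keeps the model
simple and is irrelevant at realistic CVs). Controls and blanks are drawn
with the same noise model. Defaults mirror the assay's study conditions:
control OD near 1.16, the ten-level two-fold series from 20 to 0.039
&mu;g/mL, and 3 parallel wells per group. Plates in
`simulateValidationDataset()` take sub-seeds `seed + plateIndex - 1`, so a
whole dataset is reproducible from one integer.

What the simulator does *not* emulate: well-position (edge) effects,
drift between plates, antibody-depletion kinetics, matrix effects that
differ between standards and samples, and non-Gaussian reader noise. A
green closed-loop test therefore shows the estimator chain is correct and
stable under idealized noise — not that any particular laboratory run meets
the gates.

Under the default conditions (10% OD noise, 3 replicates, ten levels) the
median relative error of a mid-curve interpolated concentration is ~6–7%,
and roughly 88% of plates land within 15% of truth — the interpolation
error budget is dominated by the three sample wells' read noise pushed
through the exponential curve, with the fitted-curve and control noise
contributing the rest. Test problem sizes are kept modest for a laptop-class
run: 200 plates for the stochastic recovery suites, 1000-fold checks only
in exploratory analysis.

## Worked example

```{r example}
samples <- data.frame(sample_id = "graft", concentration = 2.5, dilution = 1)
plate <- simulatePlate(simulationConfig(noiseCv = 5, samples = samples,
                                        seed = 7L))
fit <- fitCalibration(calibrationPoints(plate))
fit
controls <- aggregateControls(plate)
w <- plateWells(plate)
res <- quantifySample(fit, w$od450[w$group_id == "graft"], controls,
                      sampleId = "graft", massMg = 2, massBasis = "wet")
res
```

## Known limitations

* Only the exponential-saturation family is fitted; 4PL/5PL alternatives,
  weighting schemes and interval estimates for inverse predictions are out
  of scope.
* Wet vs freeze-dried mass bases are carried as metadata only; no
  conversion between them is attempted.
* The LDL detectability criterion is this package's explicit choice
  (documented above) — laboratories with an in-house definition should
  check agreement on their own series.
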