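---
title: "Methods: fingerprint PCA, DP4+ scoring, and ECD comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint PCA, DP4+ scoring, and ECD comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpcrevise)
```

This vignette documents the models behind `fpcrevise`, the choices made
where the underlying methods leave room, and what the synthetic-data
generators do and do not emulate. The package covers the post-processing
half of a structure-revision workflow for formyl phloroglucinol
meroterpenoids (FPCs): it consumes conformer energies, GIAO isotropic
shieldings, and TDDFT rotatory strengths, and never runs quantum
chemistry itself.

## Fingerprint model

A fingerprint is a fixed 12-slot vector: the six phloroglucinol core
carbons C-1…C-6, the carbonyl carbons C-7 and C-9, and up to two
aldehydic plus two phenolic proton shifts, all in CDCl₃. Compounds with a
single aldehyde or phenolic proton leave the second slot missing.

**Imputation.** Missing slots are filled with the column mean over
observed values. Zero-filling would be far outside any chemical range
(an aldehydic proton lives near 10 ppm, never 0) and would distort every
downstream covariance; dropping incomplete records would discard a large
part of a realistic table. The imputation mask is kept so reports can
list which slots were evaluated.

**PCA.** The model is an eigendecomposition of the covariance of the
centered, autoscaled matrix, population convention (divide by *n*).
Autoscaling (unit variance per slot) is the default because protons
(0–20 ppm) and carbons (0–230 ppm) live on incommensurate scales;
without it the carbons dominate every component. A toggle is provided
since centering-only is also defensible when all slots are carbons.
Loadings have a fixed sign convention — the largest-magnitude element of
each column is positive — so scores and plots are reproducible across
platforms. Classification uses nearest class centroids in the first
k = 2 components by Euclidean distance, matching the visual PC1/PC2
analysis such fingerprint tables are built for; k is configurable.
Mahalanobis distance was considered and rejected for the default: with
class sizes around 30 the per-class covariance in PC space is noisy, and
the nearest-centroid rule is what a scatter-plot reading corresponds to.
Ties break to the lexicographically smallest class label.

**Misassignment rule.** A compound is flagged iff its PCA-nearest class
differs from its reported class, or its largest deviation from the
reported class's diagnostic shift ranges (per-slot min/max over records,
requiring at least 3 observations) exceeds a threshold. The threshold
defaults to 1.0 ppm on the carbon scale — the smallest deviation treated
as diagnostic in this compound family, where misassigned ring systems
show per-position deviations of roughly 1–13 ppm.

## DFT-NMR post-processing

Per candidate structure, conformers above 3.0 kcal/mol relative energy
are removed (boundary inclusive: a conformer at exactly 3.0 is kept;
the minimum-energy conformer can never be removed). Boltzmann weights
use T = 298.15 K and R = 1.9872041×10⁻³ kcal mol⁻¹ K⁻¹, computed with
max-subtraction so large energies cannot underflow the partition sum.
Shieldings are weighted-averaged per nucleus; equivalence groups
(methyl protons, enantiotopic pairs) declared in the input table are
collapsed to their unweighted mean *after* Boltzmann averaging, giving
one value per experimental assignment.

Two shielding-to-shift routes are implemented and labelled distinctly:

- **Global empirical scaling** δ = (intercept − σ_iso)/(−slope) using
  repository-style regression factors (`inst/extdata/scaling_factors.json`,
  with a provenance string; users substitute the factors for their exact
  level of theory). MAE/RMSD in reports are computed on this route.
- **DP4+ branches**: the unscaled route δᵤ = σ_ref − σ_iso from a
  per-element reference shielding, and the scaled route, a per-candidate
  least-squares regression of calculated on experimental shifts per
  element (≥3 paired nuclei required), scaled value = (δ_calc − b)/m.

**DP4+.** Each error contributes a location-scale Student-t
log-likelihood, parameters keyed by branch and element, and for unscaled
carbons additionally by hybridization (sp² vs sp³, whose systematic
errors differ). Candidate probabilities are softmax of summed
log-likelihoods; component probabilities (scaled-only, unscaled-only,
carbon-only, proton-only) come from the corresponding partial sums. All
accumulation is in log space, so multiplying every likelihood by a
constant provably cannot move a probability. The parameter table is a
config file, not hardcoded: the bundled entry uses the published
scaled-shift t-statistics (¹³C σ = 2.306 ppm, ν = 11.38; ¹H σ = 0.185
ppm, ν = 14.18) for the scaled branch and package-estimated spreads
(¹³C σ = 6 ppm, ν = 6; ¹H σ = 0.30 ppm, ν = 8) for the unscaled branch,
whose errors are dominated by the systematic stretch that the empirical
slope (≈ −1.05) corrects. The file's provenance string says exactly
this; for publication-grade work users should transcribe the
level-of-theory-specific tables from the DP4+ literature. Headline
probabilities are displayed rounded to the nearest percent; full
precision is kept in machine-readable output.

Both protons and carbons enter the reported statistics; per-element
MAE/RMSD are always reported separately (`error_stats` with element
`"C"`, `"H"`, or `"all"`), so exchangeable-proton questions can be
resolved by the reader rather than by a hidden filter.

## ECD synthesis and comparison

Rotatory strengths are broadened on the energy axis with Gaussian bands,

Δε(E) = Σᵢ Eᵢ Rᵢ /(γ σ √π) · exp(−((E − Eᵢ)/σ)²),

σ = 0.23 eV by default, interpreted as the half-width at Δε_max/e (the
convention of the common spectral-comparison tools; the exponent form is
config-switchable via the prefactor). γ = 22.97 is the cgs prefactor for
R in 10⁻⁴⁰ esu² cm² and is exposed in the API since other conventions
differ. The curve is evaluated on a wavelength grid (default 180–400 nm
at 1 nm) via E[eV] = 1239.84193/λ[nm]. Conformer spectra are combined
with the same Boltzmann weights as the NMR arm.

UV corrections are wavelength translations of the *calculated* spectrum,
resampled onto the original grid by linear interpolation; points leaving
the grid become missing and are excluded from comparisons. Agreement is
the normalized overlap (cosine) ∫fg / √(∫f² ∫g²) by trapezoidal
integration on the common window, scanned over shifts in ±15 nm (1 nm
steps, covering the −8/+7 nm scale of corrections typical in practice),
ties resolved to the smallest |shift|. Cosine was chosen over the
spectral-similarity factors of dedicated matching software because it is
parameter-free, bounded in [−1, 1] by Cauchy–Schwarz, and exactly
antisymmetric under enantiomer flips; the comparison function is a
config hook where another metric can be swapped in.

## Synthetic-data generators

The generators exist so that every stage has inputs with the right
statistical structure, at desk scale, with no downloads.

- **Fingerprints**: class templates draw each slot Normal(mean, sd) with
  per-slot missingness. Base means echo the compound family
  (core/olefinic carbons 90–170 ppm, carbonyls 185–200 ppm, aldehydic
  ¹H 9.5–10.5, phenolic ¹H 11–14). Class structure lives on two
  uncorrelated axes — a ring-system axis moving (C2, C4, C6) together
  and a carbonyl-substitution axis moving (C1, C7, C9) — in multiples of
  the separation parameter (default 4 ppm, within-class sd 1 ppm). Slots
  co-move because that is how ring-system changes act on real cores, and
  a two-axis layout makes the class structure recoverable in the PC1/PC2
  plane that the classifier uses.
- **DP4+ scenarios** (defaults: 25 carbons, 15 protons, 5 conformers,
  Exponential(mean 1 kcal/mol) energy spread): "true" shifts are drawn
  in plausible ranges; shieldings are built by *inverse* application of
  the same scaling factors used in analysis, plus weight-centered
  conformer jitter, so the Boltzmann-averaged scaled shifts equal the
  planted targets exactly. The correct candidate's targets deviate from
  experiment by N(0, 1.9 ppm) ¹³C / N(0, 0.13 ppm) ¹H; the incorrect
  candidate additionally carries 6 carbons offset by Uniform(5, 12) ppm
  with random sign — the localized deviations a wrong ring system
  produces.
- **ECD scenarios**: sparse random transition sets in 200–380 nm; the
  "experimental" trace is the broadened Boltzmann average displaced by a
  known shift (default +7 nm) plus additive noise, with the planted
  shift returned for recovery testing.

All generators are pure functions of (config, seed) and draw from
purpose-specific sub-streams of the master seed, so adding one generator
call cannot perturb fixtures produced by another.

**What passing tests do not show.** The shieldings and transitions are
statistical stand-ins: they have the right error structure relative to
experiment but no physics (no conformer-shift correlation from actual
geometry, no solvent or rovibrational effects, Gaussian errors rather
than the heavy-tailed, position-correlated errors of real DFT).
Recovery rates on synthetic scenarios therefore validate the
*machinery* — weighting, scaling, likelihoods, normalization, scanning —
not the accuracy of any particular level of theory on real compounds.

## Numerical choices and degenerate inputs

- Softmax-style normalizations (Boltzmann weights, DP4+) always subtract
  the maximum before exponentiating.
- PCA eigenvalues are clamped at zero (symmetric eigensolves can return
  −1e−17); a zero-variance slot under autoscaling is an error naming the
  slot rather than a silent division.
- The energy-window filter cannot empty an ensemble (the re-based
  minimum 0 is always retained); an all-identical dataset yields zero
  scores and zero explained variance rather than an error.
- Spectrum shifts exceeding the grid span, empty energy lists, weight
  vectors not summing to 1, and nucleus-coverage mismatches between
  candidates are all hard errors, not warnings.
- DP4+ ties (identical candidates) resolve to exactly 1/N by
  construction; the pipeline verdict breaks ties lexicographically and
  warns.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 200
replicate two-candidate scenarios of 40 nuclei and 5 conformers each for
the discrimination rate, a 180-record six-class fingerprint table for
leave-one-out accuracy, 100 random ensembles for the window-filter
check, and 1000 random error vectors for the MAE ≤ RMSD property. These
sizes give stable rates while keeping a full run in tens of seconds.

## Known limitations

- The bundled DP4+ parameters and scaling factors are functional
  defaults with honest provenance strings; they are user-replaceable
  config, and serious use should supply level-of-theory-specific values.
- Nearest-centroid classification assumes roughly isotropic,
  comparable-spread classes in PC space; strongly elongated classes
  would favor a Mahalanobis variant.
- The ECD arm compares shapes, not absolute magnitudes, and does not
  model velocity/length gauge differences or vibronic structure.
- No parsing of quantum-chemistry output files is provided; inputs are
  the documented CSV/TSV schemas.
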