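---
title: "Methods: ion mobility statistics for ether lipid annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion mobility statistics for ether lipid annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etherims)
```

## The scientific problem

Mammalian ether phospholipids occur as two sn-1 subclasses: 1-O-alkyl
lipids (shorthand prefix `O-`) with a saturated ether linkage, and
1-O-alkenyl lipids or plasmalogens (prefix `P-`) carrying a vinyl ether
double bond at the Delta-1 position. Because the shorthand convention does
not count the Delta-1 bond, `PE P-n:d` and `PE O-n:(d+1)` have identical
elemental formulas and are indistinguishable by m/z alone. Trapped ion
mobility spectrometry (TIMS) measures a collision cross section (CCS, in
Å²) that differs slightly between the two isobars, so the question this
package quantifies is: *at a given ion mobility resolving power, how
reliably can the CCS dimension assign an isobaric ether lipid feature to
the right subclass?*

The package implements the full analysis chain as reusable, tested
stages: shorthand parsing and monoisotopic `[M-H]⁻` masses, a synthetic
cohort generator, per-sample CCS calibration and retention-time (RT)
alignment, matched structural pair deltas, five-coefficient linear trend
models with a measured-vs-database comparison, and a Gaussian two-peak
overlap model.

## The Gaussian overlap model

Two isobaric species are modelled as equal-width, equal-abundance
Gaussians in CCS space separated by $\Delta$ (Å²) around a mean CCS
$\bar{C}$. The instrument's resolving power fixes the peak width:

$$R_p = \bar{C} / \mathrm{FWHM}, \qquad \mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma.$$

Two derived quantities summarize the geometry:

- **resolution** (base-width convention) $R_s = \Delta / (4\sigma)$,
  with $R_s = 1.5$ conventionally called baseline separation;
- **annotation error probability**: classifying each observation of a
  1:1 mixture to the nearer peak center misassigns with probability
  $p_{err} = \Phi(-\Delta/(2\sigma))$, the minimal-error rule for
  equal-variance, equal-prior Gaussians.

These conventions are not interchangeable with the alternatives
(e.g. $R_s = \Delta/\mathrm{FWHM}$): only this combination makes the three
scenario triples computed by `overlap_from_resolving_power()`,
`required_resolving_power()` and `resolving_power_for_resolution()`
mutually consistent, which the acceptance tests verify. The inverse
solvers are closed-form and round-trip to machine precision.

```{r}
overlap_from_resolving_power(1.28, 268.4, 87)
```

The model deliberately assumes Gaussian peaks and an equimolar mixture.
Real mobilograms can be asymmetric, and in tissue one subclass usually
dominates quantitatively (which makes misannotation *more* likely than
the 1:1 figure suggests); neither refinement is modelled.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` emulates a knockout-contrast design: three tissues
(heart, cerebellum, cerebrum) × two genotypes (wild type and
plasmanylethanolamine-desaturase-deficient `dPeds1`) × 3 replicates
= 18 samples, with a PE species grid of cumulative carbons
CC ∈ {34, 36, 38, 40} and double bonds DB ∈ 0–7 for each of the three
sn-1 linkages. Occupancy encodes the biology of the knockout: 1-acyl
species are in every sample, alkenyl species only in wild type, alkyl
species only in the knockout — so alkyl/alkenyl pairs never share a
sample.

The generative model uses the structural effect sizes the pair-delta
analysis is meant to recover:

| effect | RT (multiplicative) | CCS (additive, Å²) |
|---|---|---|
| +1 side-chain carbon | ×1.25 per 2 C | +2.7 |
| +1 downstream DB | ×(1 − 0.117) | −1.0 |
| Delta-1 vinyl ether DB | ×(1 − 0.020) | +0.3 |
| ether linkage offset | ×1.08 | −1.0 |

RT effects are log-linear so relative (%) differences are scale-free;
CCS effects are additive in Å². The implied isobaric alkenyl-vs-alkyl
contrasts are +0.980/0.883 − 1 = +10.99 % in RT and
+0.3 − (−1.0) = +1.3 Å² in CCS. The CCS intercept (172.85 Å²) is set so
the grid-average ether lipid lands at 268.4 Å²; the RT intercept puts
the cohort in a realistic 9–40 min reversed-phase window. Neither
intercept is identified by relative effect sizes, so both are package
choices, made once.

Stochastic components, all driven by the single design seed:

- per-species deviations (CCS sd 0.4 Å², log-RT sd 0.01): composition
  effects the cumulative shorthand cannot encode; these set the
  across-pair SDs to the ~0.5–1 Å² / ~1–2 % scale seen in practice;
- per-observation noise (CCS sd 0.5 Å², log-RT sd 0.002, m/z 2 ppm);
- a per-sample affine CCS distortion (slope 0.97–1.03, intercept ±5 Å²)
  defining the uncalibrated raw mobility values; and a mild per-sample
  affine RT distortion (slope 0.98–1.02, intercept ±0.05 min). The RT
  distortion is a package addition: linear RT alignment exists as a
  pipeline stage, so the generator produces the misalignment it is
  there to remove.

Tissues differ only through abundance weights over the DB grid (heart
enriched in low-DB, cerebrum in high-DB species), not through RT/CCS
shifts — tissue effects on the physics would contradict the premise that
the structural trends generalize across tissues.

With `molecular = TRUE`, ether species are emitted at molecular level
(sn-1 16:0 ether chain) and species whose sn-2 chain carries ≥ 4 double
bonds receive a fixed +1.5 Å² offset, emulating the bimodal CCS
deviations of polyunsaturated chains. This offset is deliberately *not*
part of the species-level default: it is a deterministic function of DB,
so leaving it on would bias the trend model's DB coefficient (~+0.29 Å²)
and contradict the package's own recovery invariants; at species level
the seeded mean-zero deviation plays its role instead.

A green test on this cohort therefore establishes that the estimators
recover known effects under realistic noise and the knockout occupancy
structure. It does not establish anything about chromatographic
peak shapes, isotope envelopes, missing-value mechanisms, annotation
ambiguity, or absolute accuracy of any real instrument.

## Calibration and alignment

`fit_ccs_calibration()` is ordinary least squares of reference CCS on raw
mobility, per sample, using 1-acyl PE anchors only (ether species are the
analytes under test and are never anchors; their CCS values are obtained
by applying the fitted acyl map). Plain OLS is intentional — the stage
models a simple linear instrument response; no outlier rejection is
applied. m/z values are never recalibrated. `align_rt()` maps each
sample's RTs onto a reference sample (by default the one with the most
annotated species, maximizing anchors) with per-sample OLS over shared
species. Degenerate inputs (fewer than two anchors, zero mobility
variance, disjoint species sets, non-positive alignment slope) raise
explicit errors rather than silently producing a bad map.

## Pair deltas

`enumerate_pairs()` matches species under four transformations: chain
elongation (`plus2CH2`), an additional downstream double bond
(`plusDB_downstream`; all non-Delta-1 bonds are treated as downstream,
their position is not resolved), the Delta-1 bond alone
(`plusDB_delta1`: `O-n:d` → `P-n:d`) and the isobaric contrast
(`alkenyl_vs_alkyl_isobar`: `O-n:(d+1)` → `P-n:d`). Deltas are RT as
transformed-minus-reference relative percent and CCS as absolute Å².
Pairs co-occurring in samples are paired within sample first (cancelling
residual sample effects) and then averaged; alkyl/alkenyl pairs, which
never co-occur under the knockout design, are bridged through per-tissue
species means within each genotype. Summaries are unweighted mean ± SD
across pairs. At zero noise the additive/log-linear structure makes the
composition identity exact:
`delta(isobar) = delta(plusDB_delta1) − delta(plusDB_downstream)`
in CCS, and its log analogue in RT.

## Trend models and database comparison

`fit_trend()` fits the deliberately small five-coefficient model
`response ~ 1 + CC + DB + I(alkyl) + I(alkenyl)` on per-species means.
Per-term explained sums of squares use term deletion (RSS increase when
the term is removed), which is order-independent, unlike sequential SS.
Because the generator's RT structure is multiplicative, `transform =
"log"` linearizes RT; CCS uses the identity. On default cohorts the CC
term carries the largest deletion SS for CCS and the DB term for RT.
Bilinear interactions are available (`interactions = TRUE`) but off by
default: with a categorical-ish design they mostly add overfitting risk.

`compare_to_predictions()` regresses measured on predicted CCS per
subclass *through the origin*: that is the only convention under which
"slope 1" means best possible agreement, and the slope directly reads
out a multiplicative database bias (a free-intercept mode exists behind
`intercept = TRUE`). Model quality is the standard
`AIC = n ln(RSS/n) + 2k`, where *lower* is better; reports stating the
reverse reading exist in the literature, and this package documents and
keeps the standard convention. The published database comparison itself
(external prediction tool, hundreds of molecular species) is not
desk-reproducible; the stage is verified by recovering constructed
subclass biases (e.g. ×1.09) exactly from synthetic prediction tables
(`synthetic_predicted_table()`).

## Numerical and degenerate-input choices

- Atomic masses are hard-coded NIST monoisotopic values (≥ 7 decimals);
  the proton mass is the H-atom mass minus the electron mass. Only the
  `[M−H]⁻` adduct is in scope (negative-mode ESI).
- `weighted_sd()` is the population-form frequency-weighted SD
  (denominator Σw), matching the descriptive-statistics convention for
  pooled spread, not the unbiased sample form.
- `mean_isobar_separation()` averages *absolute* per-pair CCS deltas:
  sign exceptions occur case by case, and for overlap geometry only the
  separation magnitude matters.
- Report rounding: resolution 2 decimals, resolving power integer,
  probabilities 2 significant figures.
- Reproducibility: every random draw flows from the single design seed;
  CLI outputs embed the package version and an md5 hash of the config.

## Known limitations

- Species-level only for the statistics: sn-positional isomers and DB
  positions beyond Delta-1-vs-downstream are not modelled.
- PE is the only head group; other classes, oxidized lipids and
  isotopologue patterns are out of scope.
- The calibration operates in CCS space, not in inverse-mobility (1/K0)
  space; the Mason–Schamp conversion and instrument ramp physics are not
  modelled.
- The overlap model's 1:1 mixture assumption understates the error for
  the abundance-imbalanced mixtures typical of real tissue.
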