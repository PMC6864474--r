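---
title: "Predicting leaf antioxidant parameters from NIR spectra: methods and design"
author: "leafNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting leaf antioxidant parameters from NIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafNIR)
```

## The problem

Wet-chemistry assays of leaf antioxidant activity — total phenolic content
(TPC, mg gallic acid equivalents/g dry leaf, Folin-Ciocalteu), total
flavonoid content (TFC, mg catechin equivalents/g dry leaf, AlCl~3~) and
total antioxidant capacity (TAC, mM Trolox equivalents/g dry leaf, ABTS) —
are accurate but slow and reagent-hungry. Near-infrared (NIR) diffuse
reflectance of dried, milled leaf powder captures the C-H/O-H/N-H overtone
and combination bands of the same phenolic constituents, so a multivariate
calibration can replace the assay once it is built. `leafNIR` implements
that calibration workflow for blueberry (*Vaccinium corymbosum* and
*V. ashei*) leaves: 27 cultivars, three growing regions (RA Northern
Coast, RB Northern Inland, RC South Inland) and three harvest seasons
(May/spring, September/fall, December/winter), with the per-cultivar assay
results shipped as packaged tables (`referenceFixture()`,
`plantsFixture()`).

Because no raw spectra were ever deposited for this system, the package
carries a first-class synthetic spectra generator whose default
configuration mirrors the study design; every pipeline stage is validated
against it and against closed-form oracles.

## The calibration model

Spectra are recorded in 10000–4000 cm^-1^ at 8 cm^-1^ spacing (751
points), five replicate spectra per sample. The model chain is:

1. **Standard normal variate (SNV)** — each spectrum is centered and
   scaled to unit sample (n−1) standard deviation, removing per-repack
   offset and multiplicative scatter.
2. **Savitzky-Golay first derivative** — a 15-point window, 2nd-order
   local polynomial, 1st derivative (per index step on the constant grid).
   Edge points are dropped rather than extrapolated, so the grid shrinks
   from 751 to 737 points; the surviving grid is carried explicitly.
3. **Mean centering** — column means computed on the calibration rows only
   and applied to whatever rows are being predicted; this lives inside
   `fitPLS()` so cross-validation recenters per fold.
4. **PLS1 by NIPALS** — deterministic NIPALS with deflation of X only;
   the regression vector is b = W(PᵀW)⁻¹q. Model complexity (number of
   latent variables, LVs) is selected by leave-one-*sample*-out
   cross-validation: all five replicate spectra of a sample leave
   together, because leaving out one replicate while its siblings remain
   in training is leakage. The spectrum-level variant is available
   (`split_level`, per-row `groups`) for fidelity experiments.
5. **LV parsimony rule** — the smallest component count whose RMSECV is
   within 2% (configurable) of the curve minimum, capped at 10. A pure
   global minimum tends to overfit with grouped folds this small.
6. **Spectral region search** — the working range is divided into five
   base windows (defaults 10000–7501, 7500–6316, 6315–5390, 5389–4926,
   4925–4073 cm^-1^; closed intervals, configurable via `regionScheme()`)
   and all 2^5^−1 = 31 non-empty combinations are scored by grouped
   LOOCV. The winner has the lowest RMSECV at its selected LV count.
   Combinations whose RMSECV differs from the best by less than a
   numerical tolerance (10^-8^ × the response range) are treated as tied
   and resolved to fewer intervals, then fewer LVs, then enumeration
   order: without this, combinations that are *exactly* equivalent in
   exact arithmetic (e.g. a superset adding an empty window) would be
   ranked by floating-point rounding noise.

Accuracy is reported in the conventional figures of merit: RMSEC/RMSECV/
RMSEP, R²~C~/R²~CV~/R²~P~, and the range error ratio RER = Δy/RMSEP,
where Δy is the reference range of the prediction set (configurable to
the calibration set or all samples). RER ≥ 10 is read as adequate for
quality control, RER ≥ 15 as adequate for quantification, below 10 as
insufficient (`classifyQuality()`).

The calibration/prediction split is 70/30 at the sample level, stratified
by reference-value quartile so the prediction set spans the calibration
range, with a default seed of 2017 (the harvest year). Region and LV
optimization only ever sees calibration rows.

## The six data-set designs and transferability

`datasetDesign(1:6)` encodes the six season/region subsets used
throughout: (1) everything; (2) region RA, all seasons; (3) spring, all
regions; (4) spring RA; (5) fall RA; (6) winter RA.
`transferabilityMatrix()` trains under design i's full protocol and
evaluates on design j's samples; the diagonal reduces to `runDesign()`.
Degraded off-diagonal figures of merit quantify how much season- or
region-specific spectral background a calibration absorbs.

## What the synthetic generator emulates

`simulationConfig()` fixes the study conditions; they are deliberately not
tuned per analysis:

- **Sampling frame** — 27 cultivars; RA sampled in all three seasons, RB
  and RC in spring only (the study's collection plan); all cultivars
  present in every region; 5 replicate spectra per sample; 751-point
  grid.
- **Reference values** — each cultivar draws a stable base value
  uniformly inside the observed study ranges (TPC 39.6–272.8, TFC
  41.2–269.1, TAC 22.6–124.8), then season offsets (spring 0, fall −15,
  winter +45) and region offsets (RA +10, RB −5, RC −5) shift it,
  with clipping back to the range. This reproduces the qualitative field
  pattern — winter leaves richest, region RA richest — while keeping each
  cultivar's profile coherent across seasons. Reported assay SDs are a
  1–3% uniform fraction of the mean.
- **Spectra** — absorbance is a sum of concentration-scaled Gaussian
  analyte bands, fixed water interferent bands (6900 and 5200 cm^-1^,
  amplitudes 1.0 and 1.2), a per-replicate linear baseline
  (intercept SD 0.02, slope SD 0.01), per-replicate multiplicative
  scatter (SD 0.02) and additive white noise (SD 0.001 by default,
  roughly the repeatability of a 64-scan FT-NIR average). The water
  background dominating the spectrum is the physically realistic regime
  for plant tissue and also keeps the SNV scaling close to linear in the
  concentrations, which is what makes the noise-free study recoverable by
  a linear calibration.
- **Analyte bands** — two to three Gaussians per parameter, all inside
  the two informative windows 6315–5390 and 4925–4073 cm^-1^, with the
  sharing pattern arranged so that *no single window identifies any
  parameter alone* (each parameter shares its band in one window with a
  different parameter); only the joint pair of windows separates all
  three. This gives the exhaustive region search a recoverable, non-trivial
  truth.
- **Season-specific background** (`season_baseline`) — off by default; a
  per-season amplitude applied to a broad 5100 cm^-1^ background band
  plus a flat intercept. A *flat* seasonal shift alone is exactly removed
  by SNV, so the curved component is what actually carries the
  season signature through preprocessing; it emulates moisture/background
  differences between harvests and is what the transferability analysis
  exercises.

What the generator does **not** emulate: radiative transfer in powdered
leaves, instrument line shape, the 64-scan averaging process, band-shape
nonlinearity with concentration, or cultivar-specific spectral
signatures beyond the three analytes. Passing the recovery tests
therefore demonstrates that the chemometric machinery is correct, not
that any field calibration will attain the same figures of merit.

## Validation strategy and numerical choices

Each stage is checked against an independent oracle implemented along a
different algebraic route:

- Savitzky-Golay output vs an explicit windowed polynomial least-squares
  fit at each interior point (agreement to 10^-10^);
- NIPALS PLS1 vs the Krylov-subspace least-squares characterization of
  PLS1, and vs ordinary least squares when all components are used on
  full-rank data (10^-8^);
- grouped LOOCV vs brute-force per-fold refits with the Krylov oracle;
- Welch's comparison of summary statistics vs `t.test()` on samples
  engineered to the same moments.

The region-recovery validation runs the generator with baseline, scatter
and noise all zero and SNV disabled. SNV is a scatter correction; with no
scatter to remove, its only effect is to divide by the spectrum's global
standard deviation, a quantity that depends on *all* concentrations —
which makes every window weakly informative and the "which window carries
the signal" question ill-posed. Disabling it isolates the search itself;
with the default (scatter-bearing) generator SNV stays on.

Other numerical conventions: NIPALS stops early (with a warning) when the
residual covariance underflows, so requested component counts past the
effective rank truncate rather than fail; LOOCV reports `NA` for
component counts unreachable in some fold; degenerate region combinations
(no columns, or zero variance) are kept in the audit report with `NA`
RMSECV and excluded from selection; zero-variance spectra are an error in
SNV, as is a zero RMSEP in the RER (reported as +Inf with a warning).

Problem sizes used by the shipped validation runs — design 4 of the
default study (27 samples, 135 spectra) for end-to-end recovery, 12-cultivar
single-season sets for the region search, designs 4–6 for the transfer
matrix — were chosen as the smallest sets that exercise each property at
full spectral resolution.

## Worked wet-chemistry arithmetic

`fitStandardCurve()` and `concentrationToContent()` carry the assay
arithmetic: 50 mg leaf in 20 mL solvent and dilution factors 50/10/50
(TPC/TFC/TAC), so e.g. a diluted TPC reading of 10 mg/L gallic acid maps
to 10 × 50 × 0.020/0.050 = 200 mg GA/g dry leaf. `compareGroups()`
implements Welch's two-sample test from published mean ± SD quadruplicate
summaries; the underlying study never names its test, so Welch is this
package's declared choice (robust to unequal variances), with an optional
Bonferroni correction.

## Known limitations

- The five base windows are a package default; the original instrument
  study partitioned its spectra with boundaries that were never published
  in full. Results with other schemes are obtained via `regionScheme()`.
- Whether replicate spectra should be averaged before modelling is left
  to the user (`loocv` groups them; nothing averages them by default).
- The synthetic generator's band system is a three-analyte idealization;
  real leaf spectra contain hundreds of overlapping constituents.
- Published figures of merit for the original field data cannot be
  reproduced without the raw spectra; the package validates the method,
  and reproduces every quantity computable from the published tables.

```{r example, eval = FALSE}
# end-to-end example (see README for printed output)
st <- simulateStudy(simulationConfig(seed = 2017))
runDesign(st$spectra, st$reference, design = 4, parameter = "TPC")
```
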