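---
title: "Quantifying protein agglomeration versus aggregation: models and methods"
author: "AggloAssay authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein agglomeration versus aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AggloAssay)
```

## The scientific problem

Point mutations at the surface of oligomeric proteins can drive
self-assembly into micron-scale puncta or filaments while every subunit
remains natively folded. Such *agglomerates* are mechanistically distinct
from *aggregates*, which are driven by misfolding and engage chaperones
and the degradation machinery. Telling the two apart in living yeast
cells requires a battery of quantitative readouts, each of which this
package implements with a synthetic-data generator standing in for the
instruments:

1. **Per-cell puncta detection** from two-channel fluorescence images.
2. **A wild-type dissolution assay**: if the mutant is folded, co-expressed
   wild-type subunits enter the same oligomers and competitively dissolve
   the assembly, so the fraction of foci-bearing cells falls as the
   wild-type:mutant expression ratio rises. Misfolded aggregates are
   indifferent to wild-type levels.
3. **Co-localization** of puncta with chaperone/proteostasis markers by an
   intersection-over-union score.
4. **Fitness costs** from growth curves and two-strain competitions.
5. **Circular-dichroism divergence** between wild-type and mutant spectra.
6. **Proteome responses** via differential abundance and a resampling
   category-enrichment test.

## Puncta detection and the foci classifier

For each segmented cell the detector finds candidate pixels with
intensity at least `2.5 × cell median` **and** at least `100 AU` above the
field background (both conditions are required; both thresholds are
inclusive at the pixel level and configurable via `quantParams()`). The
background is the median of non-cell pixels, a definition this package
fixes because "background" is otherwise ambiguous; it can be overridden.
Candidates are grouped into connected components (8-connectivity by
default, 4 optional) and only the **largest** component is kept, with ties
broken by lowest minimum row then column so results are reproducible.

Shape is summarized by circularity $4\pi A / P^2$, with the perimeter $P$
from the standard weighted border-crossing estimator. Small discrete
discs can overshoot 1 slightly (a radius-2 disc reaches ~1.28); regions
of one or two pixels are defined to have circularity 1.0 because the
estimator's perimeter vanishes there. Under this estimator a filled
ellipse needs an aspect ratio of roughly 6 before circularity drops below
the 0.4 filter; the synthetic filament generator therefore defaults to
aspect 6, and filaments are anchored at the cell centre so they are not
clipped into compact stubs by the cell boundary.

A **cell** is called foci-positive when its max/median green ratio
*strictly* exceeds 2.5 — a ratio of exactly 2.5 is negative. The
classifier is scale-invariant (the ratio cancels any multiplicative gain)
and cells with zero median are flagged and classified positive.

## The dissolution assay

Cells are binned into ten empirical quantiles of their red/green
(wild-type:mutant) intensity ratio, computed per construct, and the
foci-positive fraction per bin is reported with a 95% Wilson score
interval (well behaved at fractions of 0 and 1; a normal-approximation
interval is available). The construct is then placed on the
agglomerate–aggregate continuum by the **dissolution index**

$$\mathrm{index} = 1 - \frac{\text{foci fraction, top ratio tercile}}
{\text{foci fraction, bottom tercile}},$$

clipped to $[-1, 1]$. Full dissolution gives 1; a flat profile gives 0.
Labels default to *agglomerate* at index ≥ 0.8 and *aggregate* at ≤ 0.2,
with *intermediate* between. These cutoffs are this package's
formalization of a call usually made by eye; they are exposed as
arguments. When the bottom-tercile fraction is zero the index is
undefined and the call is flagged intermediate.

The synthetic population generator draws the focus probability as a
logistic in log-ratio: `plogis(-k x)` in agglomerate mode, a constant in
aggregate mode, and `0.35 (0.45 + 0.55 plogis(-k x))` in intermediate
mode — a partial-dissolution curve with a floor, chosen once so that the
intermediate regime genuinely occupies the middle of the index scale,
with dimmer foci (peak fold drawn around 3.2, some below the 2.5
classification line). The exact per-cell probability is recorded in the
truth table, making every downstream estimator testable.

## Co-localization

Within each cell the `ceiling(0.10 × area)` brightest pixels are selected
per channel (ties resolved in raster order so scores are reproducible)
and scored by the Jaccard index of the two pixel sets. Because only
ranks matter, the score is invariant under any strictly monotone
intensity transform of either channel and symmetric under channel swap.
Cells with a shared focus typically score above 0.45 and unrelated
channels below 0.3; these numbers are reported as annotations, never used
as filters. Strain-level summaries average over foci-positive cells only
and report `NA_too_few_cells` below 20 qualifying cells or
`NA_no_signal` when a channel is flat. The construct-by-marker matrix is
clustered with average linkage on Euclidean distances over
pairwise-complete entries; row/column pairs sharing no observation get
the maximal finite distance.

## Growth and fitness

Doubling time comes from the maximal slope of `log2(OD)` over all sliding
windows of at least 5 points that reach $R^2 \ge 0.99$ (earliest window
on ties); it is exact on noise-free exponentials and excludes the
plateau of logistic curves. The area under the curve is a trapezoidal
integral in OD·h.

A serial 1:1000 dilution cycle implies $\log_2 1000 = 9.97 \approx 10$
generations. Competition fitness regresses the log odds of the mutant
frequency on cumulative generations; the slope is $\ln(1+s)$ and the
reported $s = e^{\mathrm{slope}} - 1$ is the per-generation rate
difference. Checkpoints at frequency 0 or 1 are dropped (a +0.5 Haldane
correction is optional). The selective advantage is
$S_{x/y} = (r_x - r_y)/r_{\mathrm{ref}}$ with $r_{\mathrm{ref}}$
defaulting to the competitor's rate, the usual wild-type normalizer, and
the SE over replicates is the sample SD divided by $\sqrt{n}$. The
synthetic competition treats growth as deterministic and injects
binomial noise only at the imaging step, matching image-based strain
counting.

## Spectral divergence

`deltaCD()` linearly interpolates both spectra onto the union grid over
their overlapping wavelength range and integrates the absolute
difference by the trapezoid rule, subdividing segments at sign crossings
of the difference so the integral is exact for the piecewise-linear
interpolants. Units are preserved as supplied; no mean-residue
conversion is applied. The synthetic generator builds spectra as smooth
Gaussian mixtures and computes the reference integral on a grid at least
100-fold finer; perturbation bumps are kept broad (widths 0.2–0.3 of the
range) and of one coherent sign, because a sampled-then-integrated
spectrum can only be expected to track the continuous truth when the
curve is resolved by the sampling step.

## Proteomics

Proteins need ≥ 2 unique peptides and detection in ≥ 80% of samples
(inclusive, so 5/6 passes). Quantile normalization delegates to limma's
implementation; note that on small simulated universes (hundreds of
proteins) it visibly attenuates fold changes of proteins in sparse tail
regions of the intensity distribution — with thousands of proteins, as
in real experiments, the effect is minor. Imputation offers `half_min`
(left-censoring assumption) and a correlation-kNN that imputes at the
target row's own mean level plus the donors' within-sample deviation;
borrowing donors' absolute levels would mix unrelated proteins'
abundances. Testing is a two-sided Welch t on log2 intensities with BH
adjustment — deliberately a plain, clearly-labelled statistic rather
than a moderated one. Hits require adjusted p < 0.05 **and** a fold
change strictly greater than 1.68-fold in either direction; exclusive
hit calling returns the set differences between two contrasts sharing a
universe.

Category enrichment resamples `n = |hits|` proteins without replacement
from the universe (default $10^6$ iterations) and reports, per category
with at least one observed hit, the fraction of iterations reaching the
observed count. One joint draw per iteration serves all categories; the
marginals equal the hypergeometric upper tail either way, which the
tests verify against exhaustive enumeration on small universes. A zero
count is reported at the resolution floor $1/m$ and flagged, and BH is
applied across tested categories.

## Reproducibility and numerical conventions

* One global integer seed fans out to per-operation child seeds through
  `childSeed()` (a fixed polynomial hash of the operation tag modulo
  $2^{31}-1$), so partial reruns are stable and all generators are
  bit-reproducible.
* Coordinates are 1-based (row, column) everywhere, the R convention;
  percentiles use linear interpolation (`quantile` type 7); the even-count
  median is the mean of the central pair.
* Pipeline runs (`runPipeline()`) echo parameters, record per-file MD5
  checksums in a manifest, and abort with the stage name on failure.

## What the synthetic data does and does not show

The generator emulates: elliptical non-touching cells with log-normal
base intensity, Gaussian spot/ridge foci scaled to a stated
peak-over-median fold, ratio-dependent focus probability, logistic
growth, deterministic competition with binomial counting noise, and
log-normal abundance tables with spiked effects, dropout and random
annotations. It does **not** model point-spread functions, shot noise,
touching or budding cells, cell-cycle morphology, batch effects, or
missing-not-at-random dropout. Passing tests therefore demonstrate the
estimators' correctness and calibration on data obeying the stated
models, not robustness to every artefact of real microscopy or mass
spectrometry. The intensity distribution of real cells is not
established; log-normal is an assumption, flagged as such.

Problem sizes used by the test-suite and the acceptance script — 200
random oracle images, $10^5$ enrichment iterations on enumerable
universes, 200 competition replicates per effect size, and 100
populations of 5,000 cells for the end-to-end discrimination — were
chosen so each stochastic check has comfortable statistical resolution
at desk scale.
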