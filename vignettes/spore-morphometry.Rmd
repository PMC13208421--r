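---
title: "Convex-hull morphometry of basidiospore silhouettes"
author: "SporeHull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex-hull morphometry of basidiospore silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SporeHull)
```

## The measurement problem

The three Mediterranean *Cyanoboletus* species — *C. pulverulentus*,
*C. mediterraneensis* and *C. poikilochromus* — overlap broadly in classical
spore dimensions. Length–width clouds of collection averages are not
separable enough for confident identification, and field characters are
variable. What does separate them is an asymmetry of the spore profile in
side view: *C. pulverulentus* spores show a pronounced *suprahilar
depression*, a concave indentation of the ventral flank just above the
apiculus, whereas in *C. mediterraneensis* the depression is shallow and in
*C. poikilochromus* minimal.

SporeHull quantifies that asymmetry with a convex-hull concavity statistic.
For a closed silhouette polygon with area $A$ and convex hull area
$A_{hull}$, the suprahilar-depression percentage is

$$D = 100 \, \frac{A_{hull} - A}{A_{hull}} = 100\,(1 - \text{solidity}).$$

Both areas are computed with the shoelace formula; the hull is the standard
planar convex hull of the vertices. $D$ is zero exactly for convex shapes,
is invariant under rotation, translation and uniform scaling, and the
identification key uses the regimes $D > 3\%$ (pronounced, pulverulentus)
and $D < 2.5\%$ (shallow, mediterraneensis); the band between the two
printed bounds is deliberately left unassigned and the classifier reports
it as indeterminate rather than rounding it into a branch.

## The synthetic silhouette generator

No public micrograph corpus accompanies the species descriptions, so the
package ships a parametric generator that makes every downstream stage
testable against known ground truth.

**Base profile.** A spore outline is two half-superellipses sharing the
width axis. The proximal (hilar) half is elliptic (exponent 2); the apical
half has exponent $2 - 0.9\,s$, where $s \in [0, 1]$ is `apexSharpness`
(0 = blunt elliptic apex, 1 = acute). This family is smooth, always a
simple polygon, and spans the shape vocabulary used for these species
(blunt ellipsoid through narrowly amygdaliform).

**Apiculus.** For amygdaliform profiles only, a small ventral raised-cosine
bump (height 0.35 µm, chord 0.9 µm) renders the lateralised apiculus at the
attachment point `apiculusOffset` × width below the long axis. It is part
of the silhouette — the measured object is the full spore — but it is
placed on the flank so it does not extend the long-axis caliper:
sporological convention measures length and width excluding the hilar
appendix, and the generator's nominal L and W stay calibrated to the
measured Feret axes within 1%.

**Suprahilar notch.** The depression itself is a raised-cosine inward
indentation of chord `notchWidthFrac` × L (default 0.45) on the proximal
ventral flank. Its depth is calibrated by bisection against the measured
concavity fraction until the target is met within ±0.0005 (absolute, on
the fraction scale); the calibration property is asserted over targets in
[0, 0.08]. Targets outside the attainable range of the sampled geometry
raise a typed error naming the attainable bound; the population pipeline
catches it and regenerates at that bound, counting the clamps.

**Hierarchy.** Populations follow the standard n-spores / m-basidiomes /
p-collections design. Collection-level (L, W) means are bivariate normal
with the published between-collection means and SDs; per-spore values are
drawn around their collection mean with SD = `withinSdFactor` × the
between-collection SD. The published descriptions only report SDs of
collection averages, so the within-collection factor is a free parameter;
the default 1.5 reflects that individual spores vary substantially more
than collection means, and it is configurable. The published (703/14/17)
notation lists fewer basidiomes than collections — an artefact of pooled
counting we do not reproduce; the generator treats m as a per-collection
count. Length–width correlation defaults to 0.5, a typical value for spore
dimensions. Per-spore concavity is lognormal (strictly positive,
right-skewed), with preset medians 4% (pulverulentus), 1.5%
(mediterraneensis) and 1% (poikilochromus) and log-SD 0.25, chosen once to
respect the key's stated regimes. Non-positive or width-exceeding
dimension draws are resampled rather than clipped (no point mass at the
bounds); a resampling rate above 1% warns.

```{r presets}
speciesPreset("mediterraneensis")
```

## From raster to measurement

`rasterize()` scanline-fills a polygon at a chosen scale (a pixel is
foreground iff its centre is inside); `extractContour()` recovers the
boundary at the 0.5 iso-level of the binary raster (marching squares),
which is subpixel and roughly halves rasterization bias relative to
pixel-boundary polygons. `segmentImage()` thresholds grayscale input
(Otsu default, fixed threshold for reproducibility), auto-detects polarity
by border sampling, keeps the largest component and fills holes.

Two biases are characterised by the round-trip tests rather than
corrected. First, pixel-count areas converge to the polygon area as
O(scale) and the round-trip Hausdorff distance stays below 2 px at
0.02 µm/px. Second, the marching-squares boundary of a *binary* raster is
a sawtooth at pixel scale: its convex hull rides the sawtooth crests while
the polygon area averages them, so depression measured on extracted
contours carries a positive bias of a few tenths of a percentage point at
0.02 µm/px (bounded at 0.5% for convex shapes in the tests). Regime
classification therefore uses the polygon estimator on the generated or
segmented silhouette, where the statistic is exact.

```{r roundtrip}
ct <- sporeContourFixture("pulverulentus")
measureContour(ct)
```

Axis measurement is Feret-based: length is the maximum caliper diameter
over convex-hull vertices, width the maximal extent perpendicular to the
length axis. A deliberate regression pin documents that the Feret length
of a rectangle is its diagonal — silhouette-based axes stand in for manual
ocular measurements, and any systematic offset is characterised, not
corrected. Whether the original measurements included the apiculus is not
stated in the descriptions; both conventions are available (profile
families with and without the apiculus bump), neither asserted as "the"
published convention.

## Hierarchical summaries

Species descriptions follow the convention "(minimum) mean ± SD (maximum)"
computed over *collection averages*, with counts [n/m/p]. The package pins
that convention: per-collection means first, then range statistics with
the sample SD. The min/max are read as extremes over collection means (the
natural reading of the stated protocol); with unbalanced collections this
deliberately differs from pooled-spore summaries, and a regression test
fixes the choice. Display rounding is decimal round-half-up (1.555 renders
"1.56", unlike binary-float rounding); all internal arithmetic is full
precision.

```{r summaries}
cfg <- speciesPreset("mediterraneensis", pCollections = 6, mBasidiomes = 3,
                     nPerBasidiome = 5, seed = 7)
m <- measurePopulation(samplePopulation(cfg), scaleUmPerPx = 0.03)
formatSummary(summarizeByCollection(m, "L_um"))
```

Derived metrics are computed per spore and then averaged: $Q = L/W$ and
the rotation-ellipsoid volume $apV = \pi L W^2 / 6$. The silhouette area
is measured, not approximated as an ellipse — the published species means
(57.8 µm² measured vs 53.0 elliptic for *C. mediterraneensis*) confirm
spores are not perfect ellipses, and no correction is applied.

## Statistical comparisons

`compareGroups()` reproduces the two-sample protocol: Shapiro–Wilk
normality on each group at α = 0.05 routes to a t-test when both pass and
to a Mann–Whitney test otherwise, two-sided throughout (the sidedness is
not stated in the protocol; two-sided is the conservative reading), with
stars at 0.05/0.01/0.001. Welch is the t default — "independent sample
t-tests" does not specify equal variances, and Welch is the safer choice —
with Student available. The Mann–Whitney p-value is computed by full
enumeration of all $\binom{n_1+n_2}{n_1}$ rank assignments when both
groups have ≤ 8 observations (ties included; identical constant groups
give p = 1) and by the normal approximation with tie correction otherwise.
No multiple-testing correction is applied by default, matching the
original analysis. The default unit of analysis is the collection mean
(the figure captions mark "each mark represents a measured collection");
pooled-spore comparisons are possible by passing per-spore rows.

The isoprobability ellipse is the bivariate-normal quantile region:
covariance eigen-axes scaled by $\sqrt{\chi^2_2(p)}$. The probability
level is not printed in the original figures; 0.95 is the package default
and always an explicit argument, never hard-coded into outputs. The 2-D
KDE uses a product Gaussian kernel with Scott's rule
($h_j = \hat\sigma_j n^{-1/6}$) on a grid covering the data ± 3
bandwidths; the grid density integrates to 1 within 1% by trapezoidal
quadrature.

## The identification key as a rule engine

`classifyMicroscopy()` traverses the printed microscopy key literally,
with strict inequalities: width exactly 5 µm, length exactly 12.5 µm and
depression in [2.5, 3]% are the key's own gaps and return indeterminate
with the candidate set of the unresolved couplet. Couplet 4's overlapping
length conditions ("< 12.5" vs "> 12.0") are disambiguated by the
categorical characters (shape, gloeocystidia) first and dimensions second;
conflicting or unknown characters are never guessed. The full decision
path is recorded (e.g. `1b→4b→5b`). The key thresholds ship in a
versioned YAML schema; the macromorphological field key is encoded there
as data only and is not an evaluated classifier. On populations simulated
from the presets the modal outcome per species is the species itself; a
small cross-label rate (≈ 3–4% for *C. mediterraneensis* collections whose
average width falls below 5 µm while length stays above 12.5 µm) is a
property of the key's printed thresholds under the published
between-collection variability, not of the implementation.

```{r key}
classifyMicroscopy(5.33, 12.67, "narrowly_subamygdaliform", 1.8, "sparse")
```

## Arsenic summaries

`summarizeArsenic()` computes per-species order-statistic medians (mean of
the central pair for even n) and ranges over the packaged 13-collection
table. Hyperaccumulation is flagged when the species median reaches a
configurable threshold; the default 50 mg/kg dry matter reflects the level
exceeded by the vast majority of collections of the one known
hyperaccumulator of the genus (*C. pulverulentus*, literature median
160 mg/kg), and the threshold used is always echoed in the output. The
boundary is inclusive. A QC hook checks a reference-material measurement
against its certified interval (NIST SRM 1566b, 7.65 ± 0.65 mg/kg).

## Alignment site tally

`tallySites()` classifies alignment columns with gaps and IUPAC ambiguity
codes treated as missing — the common tallying convention: constant
(exactly one distinct resolved base), variable (≥ 2), parsimony
informative (≥ 2 distinct bases each in ≥ 2 sequences), singleton
(variable, not informative); all-missing columns are tallied separately
and the informative percentage is over the full alignment length.
Published per-locus tallies produced by other tools can disagree by a
column or two at the edges of these definitions (one published ITS row
lists 365 variable sites against 284 + 80 = 364 informative + singleton);
such tool-specific edge rules are documented here, not reverse-engineered.

## Numerical choices and problem sizes

* Depression differences below 1e-12 of the hull area are snapped to zero,
  so convex polygons measure exactly 0 despite floating-point shoelace
  noise; similarity invariance is asserted at 1e-9 relative.
* Polygon simplicity is verified with a bounding-box sweep
  (near-linear for short-edged contours); marching-squares output is
  simple by construction and skips the check.
* Notch calibration: bisection to ±0.0005 absolute on the concavity
  fraction, at most 80 iterations, deterministic.
* Default raster scale is 0.02 µm/px for measurement-grade masks; the test
  suite uses 0.03–0.1 µm/px and population sizes of 4–17 collections to
  keep the default run around half a minute, and the acceptance script
  runs the two full 17×10×5 and 15×10×5 pipelines at 0.02 µm/px in under
  two minutes. Monte-Carlo assertions (type-I error at 10⁴ replicates,
  ellipse coverage at 10⁵ points) use fixed seeds.

## What passing tests do and do not show

The generator emulates silhouette geometry, the measurement chain and the
published hierarchy of variability. It does not emulate optical blur,
staining, DIC artefacts, touching or overlapping spores, or segmentation
ambiguity on real micrographs — binary masks are assumed clean, and the
selection protocol behind the original depression data (side-view spores
showing the most pronounced depression) is a max-selection the pipeline
does not apply by default (it measures all provided spores). Parameter
recovery on synthetic populations therefore validates the estimators and
conventions, not the field performance of segmentation on real images.
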