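---
title: "cleftQuant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cleftQuant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftQuant)
```

`cleftQuant` quantifies the position of extracellular-matrix molecules
(hyaluronan, HAS2, CD44) relative to excitatory synapses in two imaging
regimes: single-molecule localization microscopy (dSTORM) at the level of
individual synapses, and confocal microscopy at the level of tissue
sections. This vignette is the package's own account of the underlying
procedures: what is computed, under which assumptions, with which defaults,
and where the design was genuinely open.

## 1. The super-resolution measurement chain

A synapse arrives as a `SynapseROI`: either a three-channel localization
subset (one synapse per ROI; no drift correction, channel registration or
multi-synapse segmentation is attempted) or a per-channel image stack. The
chain implemented by `analyzeSynapse()` is:

1. **Rendering** (localization route): each channel's (x, y) coordinates are
   binned into a count grid at `pixelSize` nm/px. The package's coordinate
   convention is continuous nm with 0-based, half-open pixels: pixel *i*
   covers `[i·s, (i+1)·s)` and its center is `(i + 0.5)·s`. Reconstructed
   dSTORM synapse images are typically exported near 2 nm/px, which is the
   `SynapseROI` default; batch analyses in this package's tests use 5 nm/px,
   which changes distances by well under a nanometer while rendering is
   several times faster.
2. **Projection**: element-wise maximum across stack planes (a single plane
   is its own projection).
3. **Pre-blur**: Gaussian blur of radius 2.00 px. The "radius" is
   interpreted as the Gaussian standard deviation — the ImageJ Gaussian
   Blur convention — with the kernel truncated at 4 radii and renormalized,
   and zero padding at the borders. The blur exists to keep the centroid
   from being dominated by a single bright localization cluster; at 2 px on
   a 2–5 nm/px rendering it is a 4–10 nm smoothing, far below the
   classification bounds.
4. **Centroids**: intensity-weighted centroid of each blurred projection, in
   nm. Whether centroids should be computed on raw localizations or on
   blurred renderings is not uniquely determined by the procedure the
   package follows; `cleftQuant` uses the rendered route (it applies equally
   to image-only inputs) and the two agree to sub-pixel accuracy on
   synthetic data. A zero-intensity channel yields a distinct "no signal"
   outcome, not an error — it feeds the presence criterion.
5. **Geometry**: the cleft axis runs from the pre- toward the post-synaptic
   centroid; the midpoint operationalizes the cleft position; the
   separation is their Euclidean distance. Distances are computed in the 2-D
   projection plane (the analysis operates on projections); a 3-D mode using
   per-channel localization means is available via `use3d = TRUE`.
6. **Presence criterion**: the source material never quantifies what
   "lacking" matrix signal means, so the package makes it explicit: on the
   localization route, at least `presenceMin = 10` matrix localizations
   within `windowRadius = 300` nm of the cleft midpoint; on the image route,
   integrated blurred matrix intensity of at least `presenceMin` in the same
   window. Both defaults are deliberately permissive — 10 localizations is
   roughly 5% of a typical per-channel count — so that `ABSENT` captures
   genuinely empty channels rather than dim ones.
7. **Profiles**: mean intensity in a strip of `profileWidth = 5` px
   perpendicular to the cleft axis, sampled along the axis at 1-px steps
   with bilinear interpolation (border replication at the field edge).
   Profiles are retained for QC and plotting; classification uses only the
   centroid distances.

### 1.1 The five-way classification and its precedence

Three published distance rules govern the classification: both distances
strictly below 50 nm is "equidistantly in the synaptic cleft"; both between
50 and 100 nm is "near the synaptic cleft"; a distance *difference* strictly
greater than 100 nm is "preferential" to the nearer compartment. These rules
do not partition the plane of (d_pre, d_post) pairs — (30, 80) satisfies
none of them verbatim — so an implementation must fix a precedence.
`classifyCleftLocalization()` applies:

```
ABSENT  →  |d_pre − d_post| > θ_diff  →  both < θ_in  →  NEAR_CLEFT
```

i.e. gap cases that are neither preferential (by the only rule that
addresses asymmetry) nor in-cleft are assigned `NEAR_CLEFT`. The rationale
for sending the residual to `NEAR_CLEFT` rather than to a preferential
class: (a) all three printed rules remain honored verbatim — a synapse is
called preferential exactly when the difference rule fires, so a sweep of
the distance difference flips at exactly θ_diff = 100 nm, which is how the
package's acceptance checks recover the constant; (b) the residual region
with both distances moderate (e.g. 30 and 80 nm) is biologically "near the
cleft"; and (c) the rule order makes the classifier a total function with
no tie-breaking needed (a preferential call requires a nonzero difference,
so "equidistant residual" ties cannot arise). Bounds are applied with their
printed strictness, so boundary values (exactly 50 or exactly 100 nm) fall
through to the next rule. The applied precedence is recorded in the
`ruleOrder` attribute of every classification and in each
`SynapseMeasurement`.

The compartment assignment (`classifyCompartment()`) is a separate, coarser
view used for receptor-type molecules: a side counts when its distance is
≤ 100 nm (inclusive — "within 100 nm"), giving `BOTH`, `PRE_ONLY`,
`POST_ONLY` or `NEITHER`.

### 1.2 What the synapse simulator emulates

`simulateSynapse()` generates the statistical structure the analysis must
tolerate, with two noise scales:

- each marker is an isotropic Gaussian **emitter cloud** (`clusterSD`,
  default 50 nm — the physical extent of a synaptic marker cluster);
- each emitter produces `1 + Poisson(blinksPerEmitter − 1)` **blinks**
  (mean `blinksPerEmitter`, minimum one, default 2), so localization counts
  vary per emitter as in dSTORM;
- each blink is displaced by isotropic Gaussian **localization error**
  (`precisionSD`, default 15 nm, a typical dSTORM localization precision);
- the cleft axis orientation is uniformly random per synapse, so
  classification is exercised rotation-invariantly;
- the matrix channel sits at a signed axial offset with lateral jitter
  (`matrixLateralSD`, default 10 nm).

The default pre-to-post separation is 150 nm, a typical VGLUT1–PSD95
centroid distance for immunolabeled excitatory synapses; the source material
shows this quantity only graphically, so the default is a configuration
choice, not a reproduced value. `presetSimParams()` fixes per-class
geometries chosen to sit well inside each class region relative to the
centroid noise (≈ 3.7 nm per axis at the defaults): separation 70 nm with
the matrix at the midpoint for `IN_CLEFT` (both distances 35 nm), 150 nm for
`NEAR_CLEFT` (both 75 nm), and separation 300 nm with a ±120 nm offset for
the preferential classes (30 vs 270 nm). Ground-truth labels are computed
from the noiseless geometry by the classifier itself, so generator and
classifier cannot disagree by construction — which is precisely what makes
recovery rates interpretable.

What the simulator does **not** emulate: raw camera frames and PSF fitting,
drift, spectral crosstalk, repeated-blink correlations beyond the Poisson
count, non-Gaussian cluster shapes, and background localizations. Passing
recovery tests therefore demonstrate that the measurement chain is correct
and noise-tolerant under the stated noise model — not that any particular
biological distribution is reproducible from real data.

In the package's tests, 1000 simulated synapses (200 per class, 100 emitters
× mean 2 blinks ≈ 200 localizations/channel, 15 nm precision, fixed seeds,
rendered at 5 nm/px) recover their ground-truth class in ≈ 98% of cases,
against a ≥ 90% requirement; accuracy is checked to be non-increasing in
`precisionSD`.

## 2. The confocal quantification

All confocal analysis operates on 8-bit pixel counts at 0.1563257 µm/px
(the acquisition scale; both are parameters). `convert8bit()` maps a display
range linearly to 0–255 with half-up rounding (half-even would be equally
defensible; the choice is recorded in the output's `rounding` attribute).

- **Thresholds** are required inputs (`ColocParams`): the procedure fixes
  equal thresholds across all samples of an experiment but no published
  values exist. Tests in this package use 25/255, about 12% of the phantom's
  punctum amplitude.
- **Colocalization** (`colocMask()`): a pixel is colocalized when both
  channels reach their thresholds *and* `min(I_A, I_B) / max(I_A, I_B) ≥ ρ`
  with ρ = 0.10. The "at least 10% of their intensities" criterion names an
  ImageJ colocalization output without a formula; the min/max ratio is the
  classic plugin's symmetric semantics. Whether a directional ratio was
  intended cannot be determined from the text; the rule applied is recorded
  in the mask's `criterion` attribute and alternative interpretations can be
  swapped in behind the same mask interface. Raising ρ or either threshold
  can only shrink the mask (tested as a monotonicity property).
- **Edge sampling regions** (`sampleEdgeROIs()`): the procedure places ten
  100-µm-diameter circles along the section edge (the cortical plate)
  manually; the package formalizes this as centers inset from the DAPI-mask
  boundary by one ROI radius at equal boundary angles around the section
  centroid, with the angular start seed-controlled. ROIs failing the
  inside-the-section or pairwise non-overlap checks are dropped with an
  explicit warning and a reduced count — never silently.
- **Areas** (`normalizedArea()`): pixel counts × (pixel size)², restricted
  to an ROI, normalized to the DAPI area in the same ROI; a zero-DAPI ROI
  yields a flagged `NA`, not an error.
- **Particles** (`particleStats()`): connected components at 8-connectivity
  by default (4 available), with a minimum size of 1 px — the source
  procedure does not state a size filter, so none is applied by default.
  Labeling is computed as graph components of the pixel adjacency graph.
- **Ratiometric measurement** (`ratiometricParticles()`): the per-pixel
  ratio (e.g. GTP-Rac1 / total Rac1) is formed only where the denominator
  reaches `ratioFloor` (default 1 count, avoiding division blow-up at
  near-zero denominators); excluded pixels are counted and reported, and a
  particle with every pixel excluded gets a flagged `NA` rather than an
  infinite or silent value.

### 2.1 The confocal phantom

`simulateConfocalSection()` emulates a spheroid cryosection: a tissue disc
with faint DAPI background (so the section footprint is derivable from the
DAPI channel) and bright nucleus discs, plus two marker channels of
equal-amplitude 2-D Gaussian puncta confined to the rim annulus. A
per-punctum Bernoulli draw with probability `overlapFraction` co-centers
each marker-B punctum on its paired marker-A punctum; non-overlapped centers
keep a 6-SD minimum separation from every other punctum so that, with equal
thresholds, the colocalized area is exactly the thresholded area of the
overlapped puncta. The measured coloc/marker-B area ratio therefore
estimates `overlapFraction` — exactly 0 and 1 at the extremes, and within
binomial Monte-Carlo error in between (verified over 20 seeds at f = 0.5,
on 60-µm-radius phantoms with 80 puncta per channel; larger sections only
add computation, not information, to this check). Default phantom
dimensions (250 µm section radius, 50 µm rim) are sized so that the
standard ten 100-µm edge ROIs fit.

The phantom does not emulate optical blur of nuclei, intensity
inhomogeneity, autofluorescence gradients, or marker puncta outside the
rim; conclusions from phantom tests are about the measurement code, not
about biological image complexity.

## 3. The gated two-group comparison

`compareGroups()` screens both samples with Shapiro–Wilk at `alpha`
(default 0.05); if neither rejects, a two-sided Student t-test
(equal-variance — the procedure names only "t-tests"; Welch is available by
flag), otherwise a two-sided Mann–Whitney rank-sum test. When only one
group rejects normality the rank-sum branch is taken — the conservative
reading of a procedure that is silent on the mixed case. A constant sample
(Shapiro–Wilk undefined) is flagged and treated as non-normal. The
Mann–Whitney branch is exact for group sizes ≤ 20 without ties, otherwise
the tie-corrected normal approximation with continuity correction. Under
normal simulation (n = 30 per group, 1000 replicates) the gated procedure's
type-I error sits inside the 99% binomial interval of the nominal 0.05. No
multiple-testing correction is applied (none is part of the procedure), and
paired designs are out of scope.

## 4. Numerical choices and degenerate inputs

- Percentages in `aggregateDistribution()` are `100·count/n` from integer
  counts, so they sum to 100 exactly.
- Coincident pre/post centroids are an error (no cleft axis exists); an
  empty pre or post channel is an error (the synapse is not measurable),
  while an empty matrix channel is the regular `ABSENT` path.
- Rendering with explicit bounds treats points outside the field as
  out-of-bounds (half-open pixels); with data-derived bounds every
  localization is in bounds, so grid totals equal row counts.
- Rigid motions of the localizations leave distances and classes exactly
  invariant when measured on localization centroids; through the rendered
  route they are invariant to within pixel quantization (tested at twice the
  pixel size). Rotational bias is avoided in simulation by randomizing the
  cleft axis angle.
- All generators consume an explicit `seed` through an RNG scope that
  restores the caller's `.Random.seed`, so identical parameters give
  bit-identical outputs without side effects.

## 5. Problem sizes used by the test suite

Synthetic recovery runs 1000 synapses at ≈ 200 localizations per channel;
the phantom overlap check uses 60 sections of 60 µm radius; the type-I
simulation uses 1000 replicates of n = 30. These sizes were chosen to give
comfortable Monte-Carlo margins for the assertions they support while
keeping the default suite quick to run.

## 6. Known limitations

- The classification precedence for gap cases is a documented package
  choice; an authors'-side appendix resolving those cases was not available,
  so other implementations may assign residual cases differently.
- Threshold selection for confocal masks is left to the user (with equal
  thresholds across an experiment as the contract); an automatic Otsu-based
  mode was considered and deliberately not made default, as it would change
  the procedure being implemented.
- The 2-D analysis ignores the z coordinate by design; `use3d = TRUE` is
  provided but profiles and presence windows remain planar.
- No proprietary microscope formats are read; export TIFF/CSV first.
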