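---
title: "Compartmental densitometry of striosome and matrix: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental densitometry of striosome and matrix: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striodens)
```

## The measurement problem

The rodent dorsal striatum (caudoputamen) is organized into two neurochemical
compartments: labyrinthine, mu-opioid-receptor-rich *striosomes* embedded in
the larger, MOR1-poor *matrix*. In Huntington's-disease knock-in mice the
MOR1 signal in striosomes changes before the matrix does, so a quantitative
comparison of compartment intensities across genotype and age is the core
readout. `striodens` implements that measurement chain for immunostained
section images:

1. **Conditioning** — 16-bit grayscale conversion and inversion (dark DAB
   deposit becomes large values), rolling-ball background subtraction,
   median denoising.
2. **Sector geometry** — a ruler-and-compass construction from anatomical
   landmarks partitions each caudoputamen into dorsomedial (DM),
   dorsolateral (DL), ventromedial (VM) and ventrolateral (VL) sectors.
3. **Segmentation** — minimum cross-entropy (Li) thresholding splits each
   region independently into striosome (supra-threshold) and matrix
   compartments; non-neuronal fiber is excluded by a control-square
   threshold.
4. **Metrics** — striosome %area, compartment mean intensities, the index
   of striosome-to-matrix predominance (ISMP = striosome mean / matrix
   mean), and total striosome signal (intensity x %area).
5. **Statistics** — Kruskal-Wallis omnibus, pairwise two-sided Mann-Whitney
   U tests, Bonferroni correction with an explicit family size.

Because the original histology images are not public, the package ships a
synthetic-section generator with exact ground truth; every pipeline stage is
validated against it.

## Image conditioning

Inversion maps an 8- or 16-bit grayscale value $g$ to $65535 - g$ (8-bit
input is first rescaled by $65535/255$); RGB input is reduced with ITU-R 601
luminance weights (0.299, 0.587, 0.114) — the conversion used by common
raster tools. The pipeline fixes the order *invert, then subtract
background*, and records it in the image provenance.

**Rolling ball.** The background is the grayscale opening of the image by a
hemispherical structuring element of radius $r$ (default 500 px at
full scan resolution): the highest surface touched by a ball of radius $r$
rolled beneath the intensity landscape. We use the exact offset-loop
erosion/dilation for $r \le 16$ and, above that, the standard large-radius
approximation: block-minimum downsampling by a factor $s \in \{2, 4, 8\}$,
opening on the reduced grid, bilinear enlargement, and clipping to the
image. One subtlety matters for accuracy: the gray axis is *not* shrunk, so
the reduced-grid kernel is an ellipsoid with spatial radius $r/s$ but
intensity semi-axis $r$. With that correction the approximation stays within
1% mean absolute error of the exact opening on smooth 64x64 fixtures (the
tolerance we hold it to in the tests); with a spherical reduced kernel the
error is about four times larger.

**Median filter.** Euclidean disk of radius 5 px by default, borders by edge
replication. Boundary policy and kernel shape are stated contracts because
the upstream description names only the command.

**Scale correspondence.** The synthetic sections are rendered at 10 um/px
(versus roughly 0.3–0.7 um/px for slide scans), so parameters stated in
pixels must be rescaled to keep their physical meaning. The simulation
configs use a 48 px rolling ball — wider than the synthetic caudoputamen, as
the 500 px ball is wide relative to the structures it must not engulf — and
skip the median stage, since a 5 px median at scan resolution corresponds to
a sub-pixel kernel at 10 um/px (a 5 px median *at this scale* would be a
50 um filter that erases thin striosomes). The defaults in `run_config()`
remain the full-resolution values.

## Sector geometry

The construction, per hemisphere:

* **line 1** — the inter-hemispheric tangent between the two caudoputamen
  outlines. We fix the interpretation as the line perpendicular to the
  centroid axis of the two outlines, anchored at the midpoint of their
  medial extreme points (tying vertices averaged). For symmetric anatomy
  this is the limiting inner common tangent; unlike a literal bitangent it
  is stable under small outline jitter and exactly mirror-equivariant.
* **line 2** — parallel to line 1 through the lateral tip of the anterior
  commissure.
* **line 3** — from the upper tip of the nucleus accumbens shell to the
  crossing of line 2 with the caudoputamen margin. Line 2 crosses the
  outline twice; we take the dorsal crossing, which makes line 3 the
  diagonal of the published figure. This choice is documented rather than
  derived: the source text says only "the lateral margin".
* **line 4** — perpendicular to line 1 from the NAcc-shell tip, extended
  laterally to the outline; "divide evenly" is read as bisection.
* **line 5** — parallel to line 3 through the midpoint of line 4. This is
  the dorsal/ventral divider.
* **line 6** — through the midpoints of the striatal chords of lines 3 and
  5, extended to the outline boundary (the source does not state the
  extent). This is the medial/lateral divider.

Pixels (by center, even-odd rule) inside the outline are classified by side
of lines 5 and 6. The dorsal side of line 5 is the side holding the
dorsal-most outline points; the medial side of line 6 is the side holding
the line-1 anchor (fallbacks: the NAcc tip, then the medial extreme).
Pixels exactly on a divider are assigned to the sector with the nearest
centroid, ties resolved in the order DM, DL, VM, VL. By construction
$|DM| + |DL| + |VM| + |VL| = |whole|$ exactly; the tests assert the
partition on random landmark sets, mirror symmetry to 0.5% of pixels, and
agreement with analytically clipped polygon areas to 1% on a rectangular
fixture.

The geometry and segmentation stages never see genotype labels; metadata is
joined to the metrics table afterwards. This mirrors the blinded manual
demarcation of the original protocol and is enforced structurally (the
blinded functions have no genotype argument).

## Segmentation

**Li threshold.** For a candidate split $t$ of the histogram, with $A_i$
the summed gray mass and $\mu_i$ the mean on each side, the minimum
cross-entropy criterion is
$$\eta(t) = -A_1(t)\log\mu_1(t) - A_2(t)\log\mu_2(t),$$
equivalent (up to a constant) to the cross entropy between the image and its
two-level approximation. The 16-bit values are binned to 256 levels over
their observed range; we minimize $\eta$ *globally* over all splits by
cumulative sums rather than iterating Li & Tam's mean-ratio fixed point:
the contract is the global minimizer, the fixed point is only one route to
it and can stall in local minima on irregular histograms. When several
splits attain the minimum — e.g. every split between the two levels of a
two-level histogram — the median candidate is returned, so the threshold
sits midway between the modes. Equal-valued splits give bitwise-equal
criterion values (they share the same cumulative sums), so the tie set is
well defined. Pixels strictly above the threshold are striosome; ties go to
matrix, making results bit-reproducible. A constant region raises a
degenerate-input error and is reported as unsegmentable.

Each region (whole, DM, DL, VM, VL) is thresholded independently; the
whole-caudoputamen threshold is never reused for its sectors.

**Fiber exclusion.** Two 50 um control squares on the corpus callosum and
anterior commissure are averaged; the mean is truncated after the decimal
point and used as a threshold: pixels at or below it are moved to the
excluded mask *after* compartment segmentation (the published order is
unstated; segment-then-exclude is fixed here and recorded in provenance,
since excluding first would change the Li thresholds). The three masks
always partition the sector, and raising the threshold never shrinks the
excluded mask.

**Separability regime.** On three-level histograms (fiber, matrix,
striosome) the Li criterion can prefer cutting below the fiber cluster
rather than at the striosome gap when the fiber mass in a region is large
or the striosome mass is small; we mapped this numerically and the correct
split is preferred when per-region fiber mass stays around 1% and the
striosome fraction is above roughly 5%. The generator's defaults respect
that regime (sparse fascicles, see below); the measured-ISMP monotonicity
test sweeps striosome brightness within it. For a region with *no* true
striosome contrast the threshold necessarily falls inside the noise
distribution and the striosome fraction is a thresholding artifact — the
forced-null caudal wildtype sections exercise exactly this case (see
"Known limitations").

## Metrics

Per region and hemisphere: striosome %area
$= |strio| / (|region| - |excluded|)$; mean striosome and matrix intensity
over the processed image; ISMP $=$ striosome mean / matrix mean (striosome
in the numerator so predominance reads $> 1$; a non-positive matrix mean
invalidates the record rather than producing infinity); total intensity
$=$ striosome mean $\times$ %area. Records with an empty compartment are
flagged invalid and dropped from statistics. Hemispheres are separate
analysis units (16 caudoputamen samples from 8 animals), matching the
source design; `summarize_metrics()` reports group means with SEM.

All metrics are scale-equivariant: multiplying the image by $c$ scales the
intensities and total intensity by $c$ and leaves %area and ISMP unchanged
(asserted in the tests, including through re-segmentation).

## Statistics

`kruskal_wallis()`, `mann_whitney_u()` and `bonferroni_adjust()` wrap the
standard `stats` implementations and fix the usage: two-sided tests
throughout (the direction of change was a finding, not a prior), midrank
tie handling, exact Mann-Whitney p-values (complete enumeration) whenever
both groups have at most 8 tie-free observations, otherwise the
tie-corrected normal approximation with continuity correction; requesting
the exact mode on tied data falls back to the approximation with a logged
notice. The independent test oracles (full permutation enumeration,
hand rank computation) are implemented separately in the test suite.

The Bonferroni family size is explicit because the source states only the
resulting threshold: significance is declared below 0.005 raw, i.e.
$\alpha = 0.05$ with $m = 10$ (five regions by a two-comparison structure
per metric panel). `comparison_plan()` defaults to $m = 10$ and every
output row records $m$, the group sizes, tie counts and test mode.
A raw p of exactly 0.005 is *not* significant (strict inequality).
`run_cascade()` reports pairwise tests regardless of the omnibus outcome
but flags rows whose omnibus is non-significant.

## The synthetic-section generator

Each section is a 140 x 200 px, 10 um/px image holding both hemispheres.

* **Anatomy.** Jittered elliptical caudoputamen outlines (36 vertices,
  smooth radial Fourier jitter), AC lateral tips ventrolateral to each
  outline, NAcc-shell tips at the ventromedial margin, a dorsal corpus
  callosum band and a ventral AC bundle outside the outlines carrying the
  two control squares (placement retried until a square sits fully inside
  the fiber mask, then a geometry error).
* **Striosome pattern.** Gaussian-smoothed white noise (SD 3 px, i.e.
  ~30 um blob cores) thresholded at the quantile matching the target area
  fraction, after adding a linear dorsoventral gradient (0.25 SD units) so
  placement probability rises toward the dorsal rim. The quantile rule
  realizes the requested density almost exactly and deterministically per
  seed. Inside the cohort generator the quantile is applied per sector
  with a dorsal density tilt (x1.15 dorsal, x0.85 ventral): this
  guarantees striosome presence in every sector — as in real anatomy,
  where all four sectors carry striosomes — while keeping the dorsal rim
  enriched. A single global quantile leaves the small ventral sectors
  striosome-free in a few percent of draws, which is an artifact of the
  smoothed-field model, not of striatal biology. Wildtype rostral density
  defaults to 0.15 (the general striosome literature puts rostral
  striosome fraction around 10–15%; the value is a config knob, not a
  claim).
* **Fibers.** Six small fascicles (radius ~1 px) scattered through each
  rostral caudoputamen at intensity 50, versus 60 for the large commissural
  bundles. The bundle/fascicle margin is what makes the truncated-mean
  control threshold sit above the fascicle distribution, so exclusion
  captures essentially all fascicle pixels under noise; with equal
  intensities only half the noisy fascicle pixels would fall below the
  threshold. Caudal sections carry no intra-striatal fascicles.
* **Intensities.** Base striosome/matrix values 180/120 (a 60-gray-level
  gap). Mutant effects follow the programmed progression: striosome +40 in
  DL at 3 and 6 months, spreading to most sectors by 12 and all by 19
  months; matrix +25 from 12 months (DL, VL) and in all sectors at 19
  months; rostral mutant striosome density rises to 0.19 at 19 months.
  Caudal sections multiply the striosome-matrix contrast by a gain: 0 in
  wildtype (no visible striosomes), 1 in mutants. Effect sizes are set
  large relative to replicate variance to emulate the near-saturated
  significance levels (p < 0.001 at n = 16) reported for these contrasts.
* **Replicate variance.** Gaussian intercepts per compartment: one per
  animal (SD 1.5) shared by its sections, one per hemisphere-section
  (SD 4). Section-to-section staining variability dominating animal-level
  variability is what justifies treating hemispheres as replicates; with
  animal-only intercepts the two hemispheres of an animal would be
  near-duplicates and the rank tests would be badly anticonservative under
  clustering.
* **Noise.** Multiplicative low-frequency shading (blurred noise field,
  amplitude 5%) times the expected intensity, plus additive Gaussian noise
  (SD 5), rounded and clipped to 16 bits. Ground-truth metrics store the
  rounded programmed intensities so that noise-free renders reproduce them
  exactly.

What the generator does **not** model: optical point-spread (compartment
borders are hard edges, which makes noise-free segmentation exactly
recoverable — real boundaries are graded), DAB chromogen chemistry and
antibody specificity, anisotropic section deformation, and 3-D structure.
Passing tests therefore demonstrate the correctness of the measurement
chain, not robustness to every real-world artifact.

## Simulation harness and problem sizes

The detection harness runs the full image pipeline on replicate cohorts
with ages {3, 19 months}, 4 animals per genotype-age cell (8 hemisphere
samples per group — the smallest size at which an exact Mann-Whitney test
can cross the 0.005 per-test threshold; the separation required is then
U <= 6 of 64), both levels. The full study design (8 animals per cell,
four ages) remains the generator default. The detection criterion is the
three-element qualitative pattern: DL striosome intensity flagged at the
earliest age with no rostral matrix flag; a rostral matrix flag at the
latest age only; caudal whole-region %area and total intensity flagged at
both ages. Type-I calibration simulates null metric tables directly from
the cohort variance structure (500 replicates), which is what the cascade
consumes; rendering images for the null adds cost but no information about
the cascade's calibration.

## Known limitations

* Under a true null compartment (caudal wildtype, gain 0), Li thresholding
  of a unimodal distribution yields an arbitrary split: the measured %area
  (~0.5) is a thresholding artifact and the measured ISMP is slightly
  above 1 by construction (the "striosome" side is the upper part of the
  noise). Two-sided comparisons against the strongly labeled mutant still
  flag, but the wildtype point estimates should not be read as biology.
  The noise-free forced null is constant-valued and is reported as
  unsegmentable instead. Consequently the caudal mean-intensity trajectory
  (mutant difference emerging only at the oldest age) is not reproducible
  under a strict forced-null wildtype and is not part of the harness
  pattern.
* The generator's null-fidelity checks measure compartment means over
  ground-truth masks; measured-mask ISMP under the null is biased upward
  for the reason above.
* Sector shapes depend on the documented line interpretations; alternative
  readings of the tangent and crossing choices would shift sector
  boundaries, though all contracts (partition, determinism, equivariance)
  would be preserved.
* Rolling-ball background subtraction preserves compartment contrasts here
  because the ball is wider than the synthetic caudoputamen, so the
  background under it is pinned by the surrounding floor. At scales where
  the ball fits inside broad flat regions, plateau signal is removed by
  construction and matrix intensities would be compressed toward zero.
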