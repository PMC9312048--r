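---
title: "Methods: ray-profile comparison of frontal sinus outlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ray-profile comparison of frontal sinus outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinustdm)
```

## The measurement model

A frontal sinus outline on a posterior-anterior radiograph is reduced to a
*ray profile*. Three anatomical references define the frame:

* the **baseline** — the supraorbital line demarcating the inferior sinus
  border, with left and right termini and length $B$ (mm);
* the **origin** — the intersection of the facial midline with the baseline;
  its position is summarized by the midline ratio $r = RB/B$, where $RB$ is
  the distance from the origin to the image-right terminus;
* the **outline** — an open vertex arc tracing the lateral and superior
  sinus border from the left terminus to the right one.

From the origin, 59 rays are cast at $\theta = 3°, 6°, \dots, 177°$,
measured counter-clockwise from the origin$\to$right-terminus direction.
The length $L_\theta$ of each ray to the outline is recorded; when a ray
crosses the outline more than once, the **outermost** crossing (maximal
distance from the origin) is kept. Profiles are made dimensionless by
$s_\theta = L_\theta / B$, and two outlines are compared by the Total
Difference $TD = \sum_\theta |s^A_\theta - s^B_\theta|$, an L1 distance: in
an array of antemortem candidates, the lowest TD against a postmortem
profile proposes the identification.

**Assumptions.** The sinus must be *eligible*: it rises above the baseline,
spans the midline (origin strictly between the termini), and its lobes touch
(a single connected arc anchored on both termini). Because the arc and the
baseline jointly bound a closed region with the origin on its lower edge,
eligibility guarantees that every ray in $(0°, 180°)$ meets the arc, so all
59 lengths exist. We read "rises above the baseline" strictly: all vertices
on or above the baseline line (anchoring tolerance $10^{-6}$ mm) with at
least one strictly above. A laxer reading (some vertex above, others
below) would void the intersection guarantee, so the package treats an arc
dipping below the baseline as ineligible.

**Geometric conventions.** Coordinates are calibrated millimetres, $x$
toward the image-right terminus and $y$ superior (y-up); raster input is
converted from its native y-down indexing only at the I/O boundary. Angles
are measured from the baseline direction, not from the image axes, so
profiles are invariant to rigid motion of the radiograph and equivariant
under scaling; $r$ and $s_\theta$ are dimensionless and fully
scale-invariant. Leveling a tilted image (`rotate_to_level()`) is therefore
cosmetic for measurement and matters only for overlay placement and
rasterization.

**Numerical choices.** Ray/segment crossings closer than $10^{-9}$ mm are
merged before the outermost rule is applied, so a ray passing exactly
through a vertex (shared by two segments) counts as one crossing; the
outermost rule itself takes the maximal Euclidean distance among merged
crossings. The outline is modeled as a zero-width polyline — the traced
contour itself — so the distinction between the inner and outer border of a
drawn stroke does not arise; stroke width is an I/O concern. Line lengths
can also be reconstructed from angle-tool exports as perimeter minus right
baseline (`line_length_from_perimeter()`), which is exact by construction.

## Comparison and ranking

`standardize_profile()` divides by the *total* baseline length $B$; this is
the divisor used throughout. A `standardize = FALSE` escape hatch keeps raw
millimetre lengths for workflows where all images share one calibration and
a raw-length comparison is wanted. `rank_candidates()` sorts ascending by
TD with ties broken by input order (stable sort), so results are
deterministic; rank 1 is the proposed match. No match/non-match TD
threshold is provided: calibrating one requires reference populations
outside this package's scope.

## Raster and ROI interoperability

Scale is set by `calibrate_scale()` from a dacryon–ectoconchion landmark
pair; the default target of 39.49 mm is the grand mean orbital breadth of
the Howells craniometric dataset, making the landmark segment measure the
target exactly after calibration.

`extract_outer_contour()` requires a single 8-connected foreground
component (disjoint components mean discontinuous lobes, which are
ineligible), takes area as foreground pixel count $\times$ mm/px$^2$, and
perimeter as the length of the crack-boundary polygon — the unit edges
separating foreground from background, the convention matching wand-style
selection of a filled region. Holes and internal septa are ignored; only
the outer boundary is traced. The above-baseline portion of the boundary
becomes the outline arc, anchored at its baseline crossings.

The raw crack boundary is a staircase. A ray running nearly parallel to the
local boundary can snag on staircase corners: a boundary displacement $d$
produces a ray-length error of about $d/\sin\gamma$, where $\gamma$ is the
incidence angle between ray and boundary. The extractor therefore smooths
the arc with a short moving average over the dense crack corners (default
window 5 px, endpoints pinned so baseline anchoring is exact; window 1
keeps the raw polygon). With smoothing, the extracted boundary sits within
one pixel of the true contour; per-line agreement with vector ground truth
is sub-pixel at transversal incidence, while near-tangential rays remain
subject to the $1/\sin\gamma$ amplification — an intrinsic property of the
outermost rule, not of the extractor. The test suite checks exactly this
displacement bound on a rasterization with 600 px outline height.

ImageJ `.roi` files (big-endian, magic `Iout`; polygon, freehand and line
types) and `RoiSet.zip` archives are read and written natively so traced
outlines can move between this package and ImageJ's ROI Manager; archives
are written store-only (uncompressed), which ImageJ accepts. The overlay
measurement aid (`render_overlay()`) reproduces the 59-ray fan on a level
baseline as vector segments, SVG, or a rasterized PNG.

## Error statistics

For every measured line the *bias* is observed $-$ expected and the
*inaccuracy* is its absolute value; the two together characterize accuracy
and precision of a collection technique. Because bias is signed and its
distribution skewed, a signed cube root
$\mathrm{sign}(x)\,|x|^{1/3}$ is used as the variance-stabilizing transform
— monotone and defined for negatives, unlike a log. Extreme outliers are
values outside $[Q_1 - 3\,\mathrm{IQR},\ Q_3 + 3\,\mathrm{IQR}]$; quartiles
use linear interpolation between order statistics (`quantile()` type 7),
the convention stated explicitly because fence positions depend on it.

`rm_anova()` fits fully within-subject designs (subject = image) with one
or two within factors, testing each effect against its own
effect-by-subject stratum; no sphericity correction is applied. The design
must be complete and balanced — anything else is rejected rather than
silently approximated. When an effect has exactly zero sum of squares the
$F$ statistic is reported as 0 with $p = 1$ (the 0/0 case cannot reject).
Post hoc pairwise tests use the Holm step-down adjustment
(`p.adjust(method = "holm")` behind `pairwise_holm()`).

## The synthetic-data design

The generator exists so the full measurement and validation workflow runs
without radiographs; its defaults describe one fixed study condition and
are not tuned per analysis.

**Shapes.** `generate_outline()` builds a height profile over a 60 mm
baseline: two Gaussian lobe envelopes (peaks near 22 and 26 mm, windowed to
vanish at the termini, overlapping at the midline so the lobes touch) with
2–3 raised-cosine arcades per lobe of ~3 mm amplitude superimposed. Heights,
arcade centres, widths and amplitudes are jittered reproducibly from the
seed, so one seed is one individual. The origin sits at midline ratio 0.52,
matching the near-centred placement seen in adult material. Baseline
width, lobe heights and arcade counts are of adult frontal-sinus scale on
an orbital-breadth-calibrated radiograph. All generated outlines pass the
eligibility check by construction (generation fails loudly otherwise).

**Observer noise.** `simulate_observer()` perturbs the three manual steps:
origin placement along the baseline (sd in mm), each ray's angle (sd in
degrees), and the final line length (sd as a fraction of $B$). Gaussian
noise is used for all three — measurement error of trained observers with
no systematic bias component. "Expected" values are the noiseless ground
truth: the nominal angle, and the true ray length at the nominal angle from
the true origin. Per-mode defaults encode the design intent that a tracing
overlay, and a guided macro on top of it, successively reduce placement
error relative to freehand work: angle sds 0.8°/0.3°/0.2°, length sds
1.5%/0.8%/0.5% of $B$, origin sds 0.5/0.3/0.2 mm for freehand, overlay and
semi-automated modes. These magnitudes are package conventions (no
published per-mode sds in physical units exist to anchor them) and are
configurable per study.

**Study design.** `simulate_study()` reproduces the technical-error layout:
$n$ images $\times$ modes $\times$ observation events, each event
contributing 59 line records; events are tagged observer 1 round 1,
observer 1 round 2 (intraobserver), observer 2 round 1 (interobserver).
The default 10 images $\times$ 3 modes $\times$ 3 events gives 5310
records, and one mode with one event gives 590 — the per-mode sample a
10-image study collects. A master seed fans out to per-image and per-event
streams, so the whole dataset is bit-reproducible.

**What passing tests show — and what they do not.** The simulator
demonstrates that the geometry, scoring and statistics are implemented
correctly: injected noise sds are recovered from the records, zero noise
collapses every error summary to exactly zero, the per-mode noise ordering
survives into mean-inaccuracy summaries, and low-noise identification
recovers every true source. It does not emulate real radiographs: no
film/sensor texture, no tracing ambiguity at low-contrast borders, no
anatomical covariation between neighbouring angles' errors, no
observer-specific systematic bias, and inter-individual shape variation is
parametric rather than empirical. Identification rates on synthetic
populations therefore validate the machinery, not the real-world
discriminating power of the method, which requires radiographic samples.

## Problem sizes and runtime choices

The test suite runs property checks at sizes chosen to keep the full suite
in minutes on one CPU while leaving the statistics meaningful: 1000 random
outlines (101 vertices each) for the outermost-rule oracle with three
spot-checked angles per outline plus full-fan measurement; 5001-vertex
half-ellipses for the $10^{-6}$ closed-form comparison; $10^4$ simulated
lines for noise-sd recovery within 10%; 1000 null repeated-measures designs
for the $\alpha = 0.05$ calibration check ($\pm 2$ SE band); and one
600-px-height rasterization for contour fidelity. The acceptance script
uses 20 individuals with shape seeds 1–20 and noise driven by its `--seed`
argument.

## Known limitations

* The outermost rule makes near-tangential rays sensitive to any boundary
  perturbation (the $1/\sin\gamma$ amplification above); this affects raster
  extraction and real tracing alike, and is inherent to the method.
* No match/non-match decision threshold is provided, only rankings.
* `rm_anova()` handles complete balanced within-subject designs only;
  unbalanced data (e.g. missing timing observations) need mixed models,
  which are out of scope.
* The ROI codec covers polygon, freehand and line types — the types the
  workflow produces — and rejects others explicitly.
* DICOM input and automatic segmentation of grayscale radiographs are out
  of scope: outlines enter as traced vertex lists, masks, or ROI files.
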