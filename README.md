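# sinustdm

Automated Total Difference Method (TDM) for frontal sinus radiographic
comparison.

The frontal sinus outline seen in posterior-anterior skull radiographs is
individually distinctive — stable in adults and unique even between
monozygotic twins — which makes it usable for corroborating the
identification of unknown skeletal remains when antemortem radiographs
exist. The TDM quantifies the traced sinus outline with a fan of **59 rays
at 3° intervals** (3°–177°, counter-clockwise) cast from an *origin*: the
point where the facial midline meets the supraorbital *baseline*. Each ray
length *L<sub>θ</sub>* is standardized by the baseline length *B*,

&nbsp;&nbsp;&nbsp;&nbsp;*s<sub>θ</sub> = L<sub>θ</sub> / B*,

and two outlines A (antemortem) and B (postmortem) are compared by the
**Total Difference**

&nbsp;&nbsp;&nbsp;&nbsp;TD(A, B) = Σ<sub>θ</sub> | s<sub>θ</sub><sup>A</sup> − s<sub>θ</sub><sup>B</sup> | ,&nbsp;&nbsp; θ = 3°, 6°, …, 177°.

TD is an L1 distance on standardized ray profiles: it is zero for identical
outlines, and in an array of candidates the lowest TD proposes the match.
When a ray crosses the outline more than once (scalloped "arcade" borders),
the **outermost** intersection is used.

The package is for forensic anthropologists and researchers validating
sinus-based identification. It provides:

- exact ray–outline geometry (origin placement, midline ratio, ray casting
  with the outermost rule, leveling rotation, eligibility checks);
- TD scoring and candidate ranking;
- raster interoperability: orbital-breadth scale calibration (39.49 mm
  Howells reference), binary-mask outer-contour extraction with area and
  perimeter, ImageJ `.roi`/`RoiSet.zip` read/write, and the 59-ray overlay
  measurement aid as PNG/SVG;
- the validation statistics used in technical-error studies: bias
  (observed − expected), inaccuracy (|bias|), signed cube-root transform,
  3×IQR extreme-outlier filtering, grouped summaries, fully within-subject
  repeated-measures ANOVA, and Holm-corrected pairwise p-values;
- a synthetic generator of eligible bilobed, scalloped outlines plus a
  Gaussian observer-noise model, so the complete workflow — including a
  10-image × 3-mode × 3-event error study (5310 line records) and
  antemortem/postmortem identification trials — runs with no radiographs.

## Worked example

```r
library(sinustdm)

# two synthetic individuals as the antemortem array
am1 <- generate_outline(seed = 1)
am2 <- generate_outline(seed = 2)
prof1 <- measure_profile(am1$outline, am1$baseline, am1$origin)
prof1
#> Sinus profile 'synthetic_1': 59 rays, L in [8.011, 28.924] mm, B = 60.000 mm, r = 0.520

s1 <- standardize_profile(prof1)
s2 <- standardize_profile(measure_profile(am2$outline, am2$baseline, am2$origin))

# a noisy postmortem re-measurement of individual 1
pm <- simulate_observer(am1, noise_model(0.2, 0.01, 0, "postmortem"),
                        seed = 99)$profile
total_difference(pm, s1)
#> Total Difference synthetic_1 vs synthetic_1: TD = 0.420487 over 59 angles (max per-angle 0.030510)

rank_candidates(pm, list(s1, s2))
#>   candidate_id        TD rank
#> 1  synthetic_1 0.4204874    1
#> 2  synthetic_2 2.8256058    2
```

The postmortem profile's TD to its true source (0.42) is far below its TD to
the other individual (2.83), so the true source ranks first. At study scale:

```r
simulate_identification(20, noise_model(0.2, 0.01, 0, "pm"), seed = 1)
#> Identification trial: 20 individuals, true source ranked first in 100.0%
```

A command-line front end is installed at `exec/tdm` (subcommands
`measure`, `compare`, `rank`, `validate`, `simulate-study`, `simulate-id`,
`overlay`, `roi2csv`); run it without arguments for usage.

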