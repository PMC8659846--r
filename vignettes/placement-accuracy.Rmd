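---
title: "Assessing patient-specific guide placement: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing patient-specific guide placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiplace)
```

## The problem

Patient-specific instruments (PSIs) are 3D-printed guides that nest on
a unique bone region and constrain an osteotomy saw to a planned
cutting plane. In pelvic tumour resection the target regions of the
ilium differ sharply in how well they constrain a guide: the
supra-acetabular zone (S) is narrow with a characteristic shape, while
the iliac crest (C) is broad and locally homogeneous, so a guide can
sit plausibly in many poses. Bench studies assess placement accuracy
by tracking where a guide actually ended up and measuring how far the
achieved bone cut deviates from the planned one. `psiplace` implements
that assessment pipeline end to end, and replaces the physical bench —
printed phantom, optical tracker, human users — with a parametric
phantom and a stochastic placement simulator, so every stage can be
exercised, tested and rerun from a single seed.

## Geometric model

**Rigid transforms.** All geometry lives in a right-handed millimetre
frame (the clinical CT convention). A placement or registration is a
proper rigid motion `p -> R p + t` with `det R = +1`; reflections are
rejected at construction. Composition is right-to-left
(`compose_transform(second, first)`), a convention that is documented
and tested rather than assumed.

**Paired-point registration.** Given corresponding point sets, the
least-squares rigid transform is the Horn/Kabsch closed form: SVD of
the centred cross-covariance with a determinant correction that
forbids reflective solutions. Its RMS residual is the fiducial
registration error. Degenerate configurations (fewer than three pairs,
collinear points) are rejected because the rotation is not then
identifiable.

**ICP refinement.** The bone registration is initialised from
landmarks and refined with iterative closest point against the mesh,
using true point-to-triangle projection (not nearest-vertex, which
biases correspondences on coarse meshes). Each iteration refits the
original points to their current surface foot points, which guarantees
the RMS point-to-surface residual is non-increasing; the iteration
stops when the RMS change falls below `tol` (default `1e-6` mm) or at
`max_iter` (default 50). No outlier trimming is applied: the tracked
registration step of this protocol is low-noise, and trimming would
only add a tuning knob. Both defaults are exposed. The reported
"registration error" is the RMS point-to-surface residual (the
maximum is also reported), a choice the user should be aware of when
comparing against bounds stated without a norm.

**planToReal.** Every guide carries four pinhole fiducials. The
achieved pose is estimated by measuring the pinholes with a tracked
pointer, mapping them from the tracker frame through the (inverse)
bone registration, and solving the paired-point problem against the
planned pinhole positions — exactly four, matched by label; any other
arity is an error because the physical protocol is four pinholes.

**Cross-sections and the MOD.** The planned cutting plane is
intersected with the bone mesh: every triangle-edge/plane crossing
segment is computed, segments are chained into polylines (all
connected components are kept, none silently dropped), and each
polyline is resampled at uniform arc length (default `spacing = 0.1`
mm) so the point-cloud density does not depend on mesh resolution. The
achieved cut is the intersection of the *fixed* bone with the
transformed plane (origin `R o + t`, normal `R n`); the bone does not
move when a guide is misplaced, the cut does. The maximum osteotomy
deviation is the directed distance

MOD = max over planned points of the distance to the nearest achieved
point,

unsigned Euclidean in 3-D. The metric is deliberately asymmetric
(planned to actual) and a test documents a case where the two
directions differ. Distances are point-to-nearest-sampled-point rather
than point-to-segment: with 0.1 mm resampling the discretisation error
is negligible against deviations in the 0.3–50 mm range this
assessment cares about, and the implementation then matches the
point-cloud wording of the bench protocol exactly. If a transformed
plane no longer meets the bone, the trial is reported as `off_bone`
with an infinite sentinel and tallied separately — gross misplacements
must never be masked by clamping.

## The synthetic phantom

No bone mesh is deposited with the bench protocol this package
emulates, and the assessed pipeline is shape-agnostic, so the phantom
is a parametric stand-in rather than a pelvis reconstruction. Realism
is limited to the features the analysis hinges on:

- a flattened superellipsoid *blade* (tips left open; watertightness
  is not required by any stage) roughly 190 × 110 × 34 mm at the
  default `size_mm = 200`, the scale of a hemipelvis ilium;
- a broad, flat crest band along the top ridge — the C region — whose
  surface texture amplitude scales with `1 - crest_homogeneity`
  (default 0.7), with bumps confined to one half so the band has a
  smooth and a featured side;
- a narrow, deep notch on the lower face — the S region — giving the
  high local curvature that makes S guides self-locating.

Cutting planes pass through the footprint centre with normal along the
local blade tangent, so each cut is a closed local cross-section ring
of the bone, as an osteotomy is; every generated plane intersects the
phantom by construction. The six C footprints vary in size (30–60 mm)
and position: cases 1 and 4 are small guides on the smooth half,
cases 3 and 5 large guides on the featured half, reproducing the
size/location contrast that drives region differences; S footprints
(20–24 mm) are always the smallest. Pinholes are footprint corners
projected onto the surface and offset 2.5 mm along the local normal —
surface curvature makes them non-coplanar, which keeps the planToReal
rotation well conditioned.

The phantom mesh, cases and every stochastic draw are deterministic
functions of their seeds; per-trial streams are derived by counter
from the master seed, never shared.

## Placement noise model

A placed guide differs from its plan by a small rotation about the
footprint centroid (half-normal angle, uniformly random axis) plus an
isotropic Gaussian translation. Defaults per method:

| method     | rotation sigma | translation sigma | slip |
|------------|----------------|-------------------|------|
| freehand   | 2.0 deg        | 1.5 mm            | p = 0.15, scale 8 mm |
| smartphone | 1.0 deg        | 0.5 mm            | —    |
| hololens   | 1.1 deg        | 0.55 mm           | —    |

With probability `slip_prob` a freehand placement on the C region
additionally slides `slip_scale * (1 + Exp(1))` mm along the crest's
homogeneous direction — the direction in which a featureless band
gives no tactile feedback — producing the heavy upper tail
characteristic of unguided placement. On the soft-tissue-coated
("realistic") phantom the translation sigma is inflated additively by
`tissue_extra_sigma_mm` (default 0.8 mm) and the rotation sigma
multiplied by `1 + tissue_extra_sigma_mm`: the silicone layer hides
the surface detail a guide would register against. These values are
loose calibrations chosen so the simulated medians land in the same
order of magnitude as bench measurements (AR methods around 1 mm on
the bare phantom, freehand a factor 2 higher plus outliers); they are
configuration values, not fitted quantities, and none of them is an
acceptance target. The HoloLens model is set marginally above the
smartphone one so the two AR arms are realistic yet statistically
indistinguishable, as bench comparisons of the two devices find.

Pointer measurements of the pinholes add isotropic Gaussian noise
(`pointer_sigma_mm`, default 0.2 mm). Registration landmarks and
surface points are recorded noiselessly by default
(`registration_sigma_mm = 0`): the navigation-side registration is the
low-noise step of the physical protocol (performed once, on the bare
bone, with error below 0.1 mm) and simulating it noiselessly keeps the
placement-error models as the only stochastic influence on the MOD.

## The simulated experiment

`run_experiment()` reproduces the full bench design: 4 users x 6 cases
x 2 regions x 3 methods x 2 phantom variants = 288 trials per
experiment (one placement per cell; repetition counts beyond one per
user are not part of the emulated design). The bone registration is
performed once per phantom variant and reused for all its trials, as
the physical protocol does. Per trial the pipeline draws the true
placement, simulates the pointer measurement, estimates planToReal,
and scores the achieved cut; planned cross-sections are computed once
per case since they are trial-invariant. Summaries are the
min/Q25/median/Q75/max table per phantom x method x (C, S, Total), and
the inferential layer runs Kruskal–Wallis over methods with Dunn's
post hoc, Kruskal–Wallis over cases within each region, and per-method
Kruskal–Wallis between phantom variants.

## Statistical choices

- Quantiles use linear interpolation between order statistics (R type
  7, the common statistical-software default); bench tables do not
  disambiguate the rule, and the choice only matters at small n.
- The Kruskal–Wallis statistic is tie-corrected with a chi-square
  reference on k − 1 degrees of freedom; the computation delegates to
  `stats::kruskal.test` and the tests verify it against the textbook
  rank-sum closed form and a null calibration.
- Dunn's z uses the tie-corrected pooled variance
  `N(N+1)/12 − Σ(t³−t)/(12(N−1))`. The default multiplicity adjustment
  is *none*, because bench reports of this protocol quote single
  pairwise p-values without naming an adjustment; Bonferroni and Holm
  are available and a one-line option.
- p-values are stored at full precision; `format_pvalue()` renders the
  conventional "p < 0.001" strings only at the display layer.

## Numerical choices

- Mesh loading merges duplicate vertices within 1e-6 mm and drops
  faces below 1e-9 mm² — STL stores triangles vertex-by-vertex, and
  closest-point queries need sane topology.
- Chaining of intersection segments snaps endpoints to a 1e-7 mm grid;
  open polylines are walked from degree-1 nodes first, then remaining
  cycles, so both open and closed cuts are handled.
- Vertices exactly on a cutting plane are classed with the positive
  side, which keeps every crossing triangle contributing exactly one
  segment and avoids double-counted degenerate hits.
- The closest-point (point-to-triangle) and directed nearest-neighbour
  kernels are compiled (Rcpp); the nearest-neighbour search sorts one
  cloud on an axis and prunes by the axis gap, which makes the 288 x 2
  cross-section queries of an experiment run in seconds.

## What the tests do and do not show

The suite checks the pipeline against closed forms (cylinder and cube
sections, pure translations and rotations), independent oracles (a
generic numerical minimiser for the registration, an exhaustive
all-pairs scan for the MOD, an independently coded Dunn
implementation), parameter-recovery loops (zero pointer noise must
reproduce the ground-truth MOD of the known placement), and the
qualitative orderings of the simulated experiment — freehand worse
than AR, coated worse than bare, method effect detected at
alpha = 0.001 — across 20 replicate experiments with distinct seeds.
Problem sizes used by the suite: phantom resolution 96 (about 18k
faces; 64 for unit-level fixtures), 288 trials per experiment,
0.1–0.25 mm section spacing, 10,000-replicate null calibration for the
rank test.

Passing these tests shows the *computation* is right and the simulator
has the designed behaviour. It does not validate the bench findings
themselves: the synthetic phantom has no printing or segmentation
error, users do not learn or fatigue, the silicone layer is a noise
inflation rather than a contact model, and the placement noise laws
are the package's own constructions. Conclusions about real guides
require real bench data — which this pipeline can ingest unchanged
through its STL/PLY, CSV and JSON interfaces.

## Known limitations

- Distances are unsigned 3-D Euclidean; a deviation within the cutting
  plane and one perpendicular to it contribute identically, and no
  resection-margin (safe/unsafe side) classification is attempted.
- The MOD is sensitive to the extent of the cross-section: geometry
  that lets a plane graze distant bone inflates deviations for every
  method. The synthetic cases are constructed as local transverse
  cuts; with real meshes, off-target intersection components belong to
  the deviation by definition of the whole-mesh metric.
- Timing of placements, AR rendering and tracking hardware are out of
  scope; only their geometric consequences are modelled.
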