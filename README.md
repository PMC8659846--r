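# psiplace

Accuracy assessment of patient-specific instrument (PSI) placement for
pelvic tumour resection.

PSIs are 3D-printed surgical guides designed to nest on a unique bone
region and steer an osteotomy saw along a planned cutting plane. When a
guide is placed slightly off its planned pose, the achieved cut deviates
from the plan. `psiplace` implements the full geometric and statistical
pipeline used to quantify that deviation on bench phantoms, together
with a synthetic phantom and placement-error simulator so the whole
experiment is reproducible in software:

- **Rigid registration.** Paired-point least squares (Horn/Kabsch via
  SVD with determinant correction, so reflections are excluded) solving
  `argmin_{R,t} Σᵢ ‖R mᵢ + t − fᵢ‖²`, refined against the bone surface
  with iterative closest point (ICP) using true point-to-triangle
  projection. The RMS residual at the fiducials is the fiducial
  registration error (FRE).
- **planToReal.** The rigid transform carrying a guide from its planned
  pose to the pose actually achieved, estimated from the four pinhole
  fiducials present in every PSI, measured with a tracked pointer and
  mapped through the bone registration.
- **Maximum osteotomy deviation (MOD).** The planned cutting plane is
  intersected with the bone mesh; planToReal is applied to the plane
  (origin `R o + t`, normal `R n`) and the fixed bone is re-intersected.
  For every point `p` of the planned cross-section the distance to the
  closest point of the achieved cross-section is computed, and
  `MOD = max_p min_q ‖p − q‖` — a directed (planned → actual), unsigned
  Euclidean point-cloud distance.
- **Synthetic experiment.** A parametric hemipelvis stand-in with a
  broad homogeneous iliac-crest band (C region) and a narrow
  characteristic supra-acetabular notch (S region), six paired guide
  cases, and stochastic placement models for freehand versus
  AR-guided (smartphone, HoloLens 2) placement on a bare ("conventional")
  or soft-tissue-coated ("realistic") phantom, including a heavy-tailed
  tangential slip term for freehand placements on the featureless crest.
- **Statistics.** Five-number summaries per phantom/method/region,
  tie-corrected Kruskal–Wallis omnibus tests and Dunn's post-hoc
  pairwise comparisons.

## Worked example

```r
library(psiplace)
ex <- run_experiment(experiment_config(master_seed = 42))
print(ex)
```

```
Simulated PSI placement experiment: 288 trials (4 users x 6 cases x 2 regions x 3 methods x 2 phantoms)
  conventional phantom registration: ICP rms 1.00e-14 mm (1 iterations)
  realistic phantom registration: ICP rms 1.06e-14 mm (1 iterations)
Maximum osteotomy deviation (mm) by phantom, method and region
      phantom     method column  n  min  q25 median  q75   max
 conventional   freehand      C 24 0.21 1.48   2.50 5.28 20.08
 conventional   freehand      S 24 0.51 1.31   2.07 3.79  9.37
 conventional   freehand  Total 48 0.21 1.31   2.18 4.30 20.08
 conventional smartphone  Total 48 0.36 0.78   1.08 2.23  3.85
 conventional   hololens  Total 48 0.24 0.66   1.07 2.18  4.99
    realistic   freehand  Total 48 0.35 2.41   4.03 6.18 27.09
    realistic smartphone  Total 48 0.35 1.11   2.01 2.98  7.87
    realistic   hololens  Total 48 0.69 1.44   2.42 3.53  5.67
Method effect: Kruskal-Wallis: H(2) = 32.37, p = < 0.001
```

(abridged: the full table also lists the C and S splits of each
phantom/method cell). Reading the output: each row is the five-number
summary of the MOD across the 24 (or pooled 48) placements of one cell.
Freehand placement roughly doubles the median deviation relative to
AR guidance and produces the long upper tail (20–27 mm slips along the
homogeneous crest), and the soft-tissue-coated phantom inflates every
method's deviations — while the two AR devices are statistically
indistinguishable:

```r
print(ex$stats$dunn_methods)
#> Dunn's post-hoc test (adjustment: none)
#>    group1     group2        z       p
#>  freehand   hololens 4.387355 < 0.001
#>  freehand smartphone 5.330164 < 0.001
#>  hololens smartphone 0.942809   0.346
```

Individual stages are exposed directly, e.g.

```r
ph    <- make_phantom_mesh(phantom_spec(seed = 1))
cases <- make_cases(ph, seed = 1)
cs    <- cases[[1]]$C
tr    <- simulate_placement(cs, default_placement_models()$freehand)
assess_placement(ph, cs$plane, tr, spacing = 0.1)
#> Osteotomy deviation (region C): MOD = ... mm, ...
```

and `read_mesh()`/`write_mesh()` handle STL (ASCII + binary) and ASCII
PLY, so the same pipeline ingests real bone meshes and plans.

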