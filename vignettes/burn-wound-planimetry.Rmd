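---
title: "Area-based monitoring of burn wound healing from 3D surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-based monitoring of burn wound healing from 3D surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnplanimetry)
```

## The measurement problem

Clinical burn assessment has traditionally relied on visual inspection and
2D estimation (Rule of Nines, Lund–Browder charts, flat photography), all
of which struggle on curved anatomy and show substantial inter-observer
variability. Structured-light surface scanning replaces the estimate with a
measurement: each scanning session yields a textured triangulated mesh of
the affected skin in millimetre units, the wound region is delineated on
the mesh, and the wound's true curved surface area follows by summing
triangle areas. Repeating the measurement at successive dressing changes
turns wound area into a longitudinal signal from which healing dynamics can
be quantified objectively.

`burnplanimetry` implements that pipeline end to end: mesh input/output and
validation, wound region-of-interest (ROI) extraction, curved-surface
planimetry, the standard area-based healing metrics, and cohort-level
aggregation — plus a synthetic scene generator that stands in for the
scanner so every stage can be validated against closed-form geometry.

## Planimetry on a triangulated surface

A mesh is a set of vertices $v_i \in \mathbb{R}^3$ (mm) and triangles
$(i, j, k)$. Each triangle contributes
$\tfrac{1}{2}\,\lVert (v_j - v_i) \times (v_k - v_i) \rVert$
and a region's area is the sum over its triangles, converted to cm² only at
the reporting boundary (`surface_area()`); everything upstream stays in
scanner millimetres. This estimator is exact for the polyhedral surface and
converges quadratically to the smooth surface area as the mesh refines; no
smoothing, hole filling, or watertightness is assumed or imposed, because
clinical wound meshes are open sheets. `validate_mesh()` performs only
hygiene: it removes numerically collapsed triangles (area below
`area_epsilon`, default $10^{-8}$ mm², far below any scanner's resolution)
and unreferenced vertices.

## From delineation to ROI

A human segmenter traces the wound perimeter on the textured mesh. The
package represents the result of any such delineation as a per-vertex
labelling and derives the face-level ROI from it:

* **`roi_from_labels()`** — a face is wound if all three vertices carry the
  wound label (`all_vertices`, the default) or at least two (`majority`).
  The default is conservative: a boundary-straddling triangle is never
  counted as wound, so measured areas err low by at most one triangle ring.
  How boundary triangles "should" be apportioned is not prescribed
  clinically, which is why the rule is configurable.
* **`roi_from_color()`** — a linear classifier on vertex colour,
  $s = w \cdot (r, g, b)$ thresholded, standing in for texture-guided
  selection. It returns the induced labelling, so the colour pathway and
  the label pathway are mutually consistent by construction.
* **`roi_from_boundary_loop()`** — a seed fill bounded by a closed vertex
  polyline, mirroring the manual perimeter trace. It is an alias onto the
  label pathway and off by default.

Multi-wound scans are handled by `mesh_components()`, which partitions a
selection into edge-connected components. Adjacency is by shared *edge*,
not shared vertex — vertex adjacency would fuse two patches that touch at a
single point. Components are ordered by descending area with ties broken by
smallest face index, so downstream output is deterministic.
`filter_components()` removes speckle below a configurable area.

## The healing metrics

All metrics derive from the per-scan wound areas $A_t$ (cm²), with the
baseline scan at day 1 and elapsed time measured from it:

* absolute reduction $\Delta A = A_0 - A_t$;
* percent reduction $(A_0 - A_t) / A_0 \times 100$;
* early-phase reduction — the percent reduction at the *first* follow-up
  scan;
* daily healing rate $(A_0 - A_t) / t$ in cm²/day. The rate is a plain
  area change per elapsed day; the package deliberately applies no
  additional scale factor, keeping the stated unit dimensionally
  consistent with reported clinical magnitudes (small partial-thickness
  burns commonly heal at 5–20 cm²/day);
* Du Bois body surface area
  $\mathrm{BSA}\,(\mathrm{m}^2) = 0.007184\, W^{0.425} H^{0.725}$
  ($W$ kg, $H$ cm), the classical anthropometric whole-body skin area;
* TBSA-scale burden $A / (\mathrm{BSA} \cdot 10^4) \times 100$ and its
  longitudinal change
  $\Delta\mathrm{TBSA}\% = \sum_{\text{wounds}} (A_0 - A_\mathrm{last}) /
  (\mathrm{BSA} \cdot 10^4) \times 100$,
  which by linearity equals the sum of per-wound contributions.

Two conventions are worth calling out. Reductions are *signed*: a wound
that grew between scans yields a negative reduction and is flagged, never
clamped — real series are not always monotone and clamping would hide it.
And $A_\mathrm{last}$ is each wound's own final scan; wounds are never
truncated to a common day, because follow-up intervals in pragmatic
clinical schedules vary.

```{r metrics-example}
obs <- tibble::tibble(patient_id = "P12", location = "RLL",
                      day = c(1, 3, 8, 16, 23),
                      area_cm2 = c(1502.51, 1175.52, 941.05, 507.83, 402.60))
wound_metrics(obs)
```

## The bundled pilot cohort

`burn_pilot_cohort()` ships a pilot dataset of 18 patients and 43 acute
thermal burns with serial scans (125 area observations), patient
anthropometrics, and per-wound clinical annotations (mechanism, depth
class, surgery). BSA is always recomputed from height and weight — never
read from a recorded column — and the cohort table carries each patient's
$\Delta\mathrm{TBSA}\%$ on every wound row.

The original clinical records contain a handful of internal
inconsistencies, which the fixtures document rather than hide:

* three recorded BSA values (P05, P07, P17) disagree with the Du Bois
  formula on the recorded heights and weights; P07's own recorded
  $\Delta$TBSA is consistent only with the *recomputed* BSA, confirming
  transcription typos. They are flagged `bsa_typo`/`inconsistent` in
  `reported_patients.csv`.
* two wound rows (P06-LUL, P07-LUL) carry derived values that belong to
  neighbouring rows (a one-row shift), and one (P04-LUL) a dropped-digit
  percent; they are flagged `excluded` in the annotations — visibly, not
  silently — and skipped by consistency assertions.
* four recorded percent-reduction values differ from recomputation by
  0.013–0.023 because they were evidently derived from full-precision
  areas rather than the recorded 2-decimal ones (`percent_rounding`).
* the per-patient record block of P05 is corrupted in the source; its
  mechanism annotation follows the cohort's summary counts (7 scald,
  6 explosion, 5 fire), the only single-patient assignment consistent
  with them.

Comparisons against recorded values therefore use absolute tolerance
0.01 m² for BSA (the records mix rounding and truncation) and 0.01 of a
unit for percent and $\Delta$TBSA quantities (0.03 for the four
`percent_rounding` rows).

```{r cohort}
co <- burn_pilot_cohort()
tab <- build_cohort_table(co$patients, co$observations, co$annotations)
glance(tab)
group_summary(tab, "mechanism")
```

Group summaries use the midpoint median; mixed depth classes
(`"IIb and III"`, …) stay as their own categories because annotations apply
to whole patients, not wounds. No hypothesis testing is provided anywhere:
with 18 heterogeneous patients the honest output is description, and
adding p-values would invite over-reading.

## The synthetic scene generator

Real validation data with known wound area does not exist — a scanner
measures, it does not prescribe. The generator therefore builds scenes
whose wound area is known *in closed form before any mesh exists*:

| anatomy | wound patch | analytic area (mm²) |
|---|---|---|
| plane (flat skin patch) | disc, radius $r$ | $\pi r^2$ |
| cylinder (limb), radius $R$ | angular span $\Delta\varphi$ × axial length $\ell$ | $R\,\Delta\varphi\,\ell$ |
| sphere (torso segment), radius $R$ | cap, angular radius $\theta$ | $2\pi R^2 (1 - \cos\theta)$ |

The triangulation *inserts the patch boundary into its knot set*: the cap
ring, the patch edges and the disc circle are mesh polylines. With the
conservative `all_vertices` face rule, the labelled region is then the full
polyhedral patch, and its area differs from the closed form only by the
quadratic chordal deficit ($\sim 10^{-5}$ relative at the default 1 mm
resolution) instead of a linear boundary band (which would be several
percent at clinically relevant patch sizes). The flat anatomy is meshed as
a polar fan whose boundary polygon contains the rectangle corners, so its
total area is exact.

Longitudinal series (`generate_series()`) shrink the patch *parameter* so
the analytic area equals the prescribed trajectory value
$A(d) = A_0 e^{-k (d - d_1)}$ (or linear) at every scan day — morphing a
mesh would forfeit the oracle. A day whose target area is zero yields an
unlabelled mesh; a positive area smaller than the meshing resolution can
represent raises an error rather than silently degrading.

Scanner noise (`apply_scan_noise()`) displaces vertices along the analytic
surface normal by a *smooth correlated* Gaussian field (sum of random
cosine waves, 10 mm correlation length, marginal sd `sigma_mm`, seeded and
deterministic). Registered structured-light output exhibits smooth residual
undulations, not per-vertex speckle; independent vertex noise at sub-edge
correlation roughens the surface and biases area upward by
$\mathcal{O}((\sigma/h)^2)$ — about 2% at $\sigma = 0.1$ mm on a 1 mm mesh
— which misrepresents the instrument. The uncorrelated model remains
available (`correlation_mm = 0`) for studying exactly that bias. Noise is
applied after labelling and only along normals, so the labelled boundary
never moves.

Defaults: resolution 1 mm (a few times the native resolution of clinical
structured-light scanners, keeping a full torso segment around $4 \times
10^5$ triangles), skin tone (0.9, 0.75, 0.6) vs wound tone (0.8, 0.2, 0.2)
— linearly separable by the default colour rule `w = (1, -1, -1)` at
threshold 0.

What the generator deliberately does **not** emulate: photographic texture
realism, occlusion and registration artifacts of multi-view capture, and
biomechanical skin deformation between sessions. Passing the synthetic
checks therefore demonstrates that segmentation and planimetry are
geometrically correct — it does not certify robustness to registration
failure or to posture change, which are acquisition-time problems.

```{r synthetic}
scene <- synthetic_scene("sphere_torso")
mesh <- paint_wound(make_anatomy(scene), scene)
roi <- roi_from_labels(mesh)
c(measured = roi$area_cm2, truth = ground_truth_area_cm2(scene))
```

## Numerical choices and degenerate inputs

* Unit boundary: mm² internally, cm² only in `surface_area()` output, so
  `surface_area() * 100` equals the face-area sum on the same float path.
* Degenerate faces: threshold $10^{-8}$ mm²; removal is the only mutation
  `validate_mesh()` performs.
* Empty face subsets measure 0 with a warning; empty *selections* are
  errors — silently measuring nothing would masquerade as a healed wound.
* Component ordering and all file outputs are deterministic; re-running
  any front-end on identical inputs produces byte-identical tables.
* Mesh I/O reads ASCII and binary PLY/STL and ASCII OBJ, writes ASCII
  only (diffable); STL corner vertices are merged exactly; integer labels
  travel in a sidecar CSV because none of the three formats standardises
  them.
* Errors are classed conditions (`bp_error_*`), and the command-line
  front-end maps them to exit codes (2 input/config, 3 empty selection).

## Problem sizes used in the test suite

Unit tests run on coarse scenes (2–4 mm resolution limbs, $10^3$–$10^4$
faces); the oracle-agreement and trajectory-recovery checks run at the
default 1 mm resolution (the sphere scene has $\approx 4 \times 10^5$
faces, the four-scan cylinder series $\approx 10^5$ faces per scan) —
sizes chosen to match the geometry a clinical scan produces while keeping
the whole suite in the tens of seconds.

## Known limitations

* Planimetry measures *open wound area* only; depth, volume and scar
  quality are out of scope, as is whole-body TBSA charting for acute
  resuscitation decisions.
* The colour rule is a linear threshold on painted tones; it is a testing
  device and a baseline, not a segmentation model for clinical
  photographs.
* Multi-scan registration is assumed done upstream; the package never
  aligns meshes.
* Inter-operator segmentation variability is not modelled — the pilot data
  stem from a single segmenter, and no reproducibility statistic is
  defined for it.
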