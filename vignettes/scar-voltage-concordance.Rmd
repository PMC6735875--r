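---
title: "Methods: MRI scar vs electroanatomic substrate concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI scar vs electroanatomic substrate concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarconcord)
```

## The problem

Ventricular tachycardia ablation is guided by two independent pictures of
the arrhythmogenic substrate: structural scar seen on late gadolinium
enhancement (LGE) MRI, and electrical abnormality measured by catheter
mapping — low bipolar voltage (< 1.5 mV is the conventional cut) and slow
conduction (stimulus-to-QRS delay > 40 ms during pace mapping). The two
modalities live in different coordinate frames and on different supports
(a voxel grid versus scattered catheter points), so quantifying their
agreement requires a pipeline: segment scar on the image, register the
image frame to the mapping frame, project scar onto the endocardial
surface mesh, interpolate the sparse electrical samples over the same
mesh, and compare the two per-vertex binary maps.

`scarconcord` implements that pipeline as composable, individually tested
operations, and ships a fully ground-truthed synthetic left-ventricular
phantom so every stage can be validated against known answers.

## The phantom

The phantom is deliberately *analytic* rather than anatomical: the LV wall
is an ellipsoidal half-shell (triaxial semi-axes, default 22 × 18 × 28 mm,
wall thickness 6 mm) truncated at a basal plane, with a transmural
antero-septal scar patch defined by an azimuthal band (default 90°) and an
axial band (default 40% of the long-axis extent). Because membership of
any point in wall or scar is a closed-form test, brute-force per-voxel and
per-vertex oracles exist for every geometric operation, and the test suite
uses them.

Two deliberate geometry choices:

* **Transmural scar.** In the ischaemia–reperfusion setting this package
  models, scar typically spans the full wall thickness, and the scar patch
  is transmural by construction. This matters downstream: the epicardial
  side of a transmural scar produces image points far from the endocardial
  mesh, which is why the point-to-node mapping has a discard radius.
* **Triaxial cross-section.** With equal short-axis radii the shell is a
  surface of revolution, and azimuthal rotation becomes unobservable to
  any surface-distance criterion — iterative closest point alignment is
  then ill-posed by symmetry, not by any algorithmic defect. A triaxial
  cross-section (which is also the more realistic LV shape) makes the
  registration problem well-conditioned.

Electrical measurements are simulated per tissue class. Bipolar voltage is
log-normal — strictly positive and right-skewed, as peak-to-peak
amplitudes are — with class medians 0.8 mV (scar) and 3.8 mV (normal) and
a common log-SD of 0.5. Stimulus-to-QRS delay is Gaussian truncated at
zero (normal 25 ± 8 ms, scar 60 ± 10 ms), and pacing in scar fails to
capture with probability 0.3. Activation time is a smooth affine function
of distance from an apical origin plus a fixed conduction delay inside
scar and 3 ms noise; it is carried as a secondary output and no statistic
in the package depends on its exact form. Sampling positions are mesh
vertices jittered uniformly inside a 1 mm ball (catheter localisation
error), with scar vertices oversampled by a weight of 4, reflecting
mapping that is deliberately focused on the imaged scar. With the default
counts (445 electrograms, 113 pace sites) this reproduces the composition
of the animal study the defaults emulate: roughly 31% of electrograms in
scar and about ten non-capturing scar sites. A known rigid transform (10°
about z, translation (5, −3, 2) mm) separates the image frame from the
mapping frame; landmark pairs carry 0.5 mm Gaussian localisation noise.

One root integer seed drives everything; each generator operation draws
from its own deterministically derived sub-stream, so regenerating any
single table is reproducible without regenerating the rest.

What the phantom does **not** emulate: electrophysiological wave
propagation (voltages are conditionally independent given class), MRI
physics (intensities are Gaussian per class with no partial-volume or bias
field), respiratory/cardiac motion, and border-zone tissue with
intermediate voltage. Passing tests therefore demonstrate correctness of
the pipeline's arithmetic and geometry under a controlled model, not
clinical performance on real data.

## Scar segmentation

`fwhm_segment()` implements the full-width-half-maximum rule: compute the
maximum signal intensity over the wall mask and label as scar every wall
voxel whose intensity is *strictly above* half that maximum. The fraction
is exposed (`fwhm_frac`, default 0.5) for sensitivity analyses, the
boundary is strict because the rule says "above", and no smoothing is
applied before the maximum. Two properties are worth knowing:

* The rule is invariant to positive rescaling of intensities, and raising
  the fraction can only shrink the scar set (both are property-tested).
* The rule is *relative*: on a scar-free homogeneous wall it labels
  essentially the entire wall, because almost every voxel exceeds half of
  the maximum of its own noise distribution. A scar-free input therefore
  does not produce an empty scar map — this is a limitation of FWHM
  itself, not of the implementation. An optional percentile clip
  (`clip_quantile`) blunts hyper-intense outliers; it is off by default
  because the plain maximum is the canonical rule.

## Registration

`fit_rigid_landmarks()` solves the least-squares rigid alignment of
corresponding landmark pairs by the SVD (Kabsch) construction with the
standard determinant sign correction, refusing fewer than three or
collinear source points. `icp_refine()` then alternates nearest-vertex
correspondence with a Kabsch update until the mean correspondence distance
changes by less than `tol` (default 1e-4 mm, `max_iter` 100); each update
refits from the original points so numerical error does not accumulate,
and the mean-distance objective is non-increasing by construction.
Correspondence is point-to-vertex rather than point-to-triangle because
every downstream statistic is per-vertex. Non-convergence returns the
current transform with a flag rather than an error.

`map_points_to_nodes()` projects the registered scar point cloud onto the
mesh: a vertex is scar if it is the nearest vertex of at least one
retained point, ties broken deterministically toward the lowest vertex
index, and points farther than `max_dist_mm` (default 5 mm) from every
vertex are discarded and counted — this is what drops the epicardial-side
voxels of a transmural scar. The defaults keep the endocardial and
mid-wall voxels; whether epicardial voxels should be excluded before
mapping is genuinely undecided in the field, which is why it is a
parameter rather than an assumption.

A discretisation consequence worth stating: nearest-node rasterization
dilates a scar patch by roughly half a vertex spacing at its boundary
(with the default mesh, ~190 labelled vertices for ~120 truly inside the
patch). Diagnostics that use the LGE node map as gold standard inherit
that boundary band as label noise; the package therefore reports both
LGE-referenced diagnostics (as the study design dictates) and, on the
phantom, truth-referenced recovery (which is what closed-form expectations
describe).

## Map interpolation

`assign_egm_to_nodes()` attaches each electrogram to its nearest vertex,
averaging multiple samples on one vertex (unbiased and order-independent).
`relax_interpolate()` fills the remaining vertices by solving the discrete
Laplace equation on the vertex–edge graph with measured vertices as fixed
Dirichlet boundary conditions — each unknown vertex equals the mean of its
neighbours, which is exactly the steady state of the relaxation that
clinical mapping platforms run for colour interpolation. Uniform
(combinatorial) weights are the default as the minimal faithful reading of
"linear interpolation between mapping points"; cotangent weights are
available behind a flag for geometry-aware smoothing. The system is solved
directly as a sparse linear solve; an independent Gauss–Seidel relaxation
serves as a cross-check oracle in the tests. The solution inherits the
discrete maximum principle (interpolated values stay inside the measured
range), is linear in the boundary data, and is idempotent — all three are
tested, along with the exact closed-form ramp on a path graph.

Disconnected graph components without any measured vertex are a hard
error naming the component, since their values would be unconstrained.

## Concordance and diagnostics

`binarize_map()` labels a vertex abnormal when voltage is strictly below
the threshold (default 1.5 mV). `dice_binary()` computes, per class,

$$\mathrm{DSC}_{scar} = \frac{2|A \cap B|}{|A| + |B|}, \qquad
  \mathrm{DSC}_{normal} = \frac{2|A^c \cap B^c|}{|A^c| + |B^c|},$$

with A the voltage-abnormal set and B the LGE-scar set over vertices. The
*total* DSC is the micro-averaged two-class Dice, which is algebraically
identical to the fraction of vertices on which the maps agree; this is the
only reading under which a scar DSC near 35%, a normal DSC near 90% and a
total near 79% can coexist on a majority-normal surface, so it is the
default, with the macro average (mean of the two class coefficients)
behind a flag. A class empty in both maps scores 1 (a scar-free surface
agreeing with a scar-free map is perfect concordance); empty in exactly
one scores 0. `dice_threshold_sweep()` repeats this over ascending
cut-offs, default 0.5–3.5 mV in steps of 0.5.

Diagnostic accuracy takes the LGE-derived node map as gold standard.
The analysis unit is the individual electrogram (each sample classified by
its own measured voltage, truth taken from its vertex), matching how the
study counted its 445 electrograms; a per-vertex mode is a one-line
variation. Non-capturing pace sites are excluded from stimulus-to-QRS
proportions and diagnostics and reported separately. The S-QRS boundary
follows the strict "> 40 ms" reading; a site at exactly 40 ms is normal.
`roc_from_scores()` builds the empirical ROC over all unique thresholds
(ties grouped at one operating point) and integrates by the trapezoidal
rule, which equals the Mann–Whitney concordance probability with ties
counted one half — the equivalence is asserted to 1e-12 against an O(n²)
oracle. The orientation argument declares whether low scores (voltage) or
high scores (S-QRS) indicate scar. `reconstruct_confusion()` bridges
printed prevalence and sensitivity/specificity pairs to expected
real-valued confusion counts, from which predictive values follow.

## Numerical and design choices

| Parameter | Default | Why |
|---|---|---|
| `fwhm_frac` | 0.5 | the canonical half-maximum rule; strict `>` |
| voltage threshold | 1.5 mV | conventional abnormal-myocardium cut; strict `<` |
| sweep | 0.5–3.5 mV, step 0.5 | the threshold-sensitivity range of interest |
| `slow_ms` / `very_slow_ms` | 40 / 80 ms | slow-conduction cuts; strict `>` / `>=` flag |
| ICP `tol`, `max_iter` | 1e-4 mm, 100 | sub-discretisation convergence at bounded cost |
| `max_dist_mm` | 5 mm | keeps endo/mid-wall scar voxels, drops epicardial |
| rotation validation | 1e-9 | orthonormality and det +1 at construction |

Tie-breaks are deterministic everywhere (lowest vertex index); all
generator operations are reproducible from one seed; positions are in
millimetres throughout, with image and mapping frames related only by the
rigid `frame_transform`.

The test suite exercises phantoms at reduced size (40³ voxels at 2 mm,
~500-vertex meshes, 200 electrograms) chosen so that brute-force oracles —
per-voxel membership loops, exhaustive nearest-neighbour searches, the
2¹⁶-case exhaustive Dice enumeration, O(n²) Mann–Whitney — remain
practical; the pipeline defaults (64³ at 1.2 mm, 1153 vertices, 445
electrograms) match the imaging resolution and sampling density the
defaults emulate.

## Known limitations

* FWHM cannot return an empty scar map on scar-free input (see above).
* Nearest-node projection dilates scar patches by ~half a vertex spacing;
  finer meshes reduce the dilated fraction but increase the chance that
  the 1 mm position jitter reassigns a sample to a neighbouring vertex.
* Uniform Laplacian interpolation ignores triangle shape; on strongly
  anisotropic meshes the cotangent option is preferable.
* The phantom's class-conditional independence makes detection easier
  than real border-zone electrophysiology; recovery results are upper
  bounds, not forecasts of clinical accuracy.
* Confidence intervals for AUC are out of scope.

## A minimal run

```{r example, eval = FALSE}
report <- run_pipeline(list(seed = 1))
report
autoplot(report$dice_sweep)
```
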