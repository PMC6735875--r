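# scarconcord

Quantifying the concordance between MRI-derived ventricular scar and
catheter-measured electroanatomic substrate.

In ventricular tachycardia ablation, structural scar is imaged by late
gadolinium enhancement (LGE) MRI while the electrical substrate is mapped
with a catheter: bipolar voltage (abnormal myocardium < 1.5 mV) and
stimulus-to-QRS delay during pace mapping (slow conduction > 40 ms). The
two pictures live in different coordinate frames on different supports — a
voxel grid versus scattered points on the endocardium. `scarconcord` is an
R package for electrophysiologists and imaging researchers who want to
measure how well the two agree, stage by reproducible stage:

1. **FWHM scar segmentation** — label as scar every LV-wall voxel with
   intensity strictly above 50% of the maximal wall intensity.
2. **Rigid registration** — least-squares (Kabsch/SVD) landmark alignment
   of the image frame to the mapping frame, refined by iterative closest
   point against the endocardial mesh.
3. **Scar-to-mesh projection** — nearest-vertex mapping of scar voxel
   centres onto mesh nodes, with an off-surface discard radius.
4. **Map interpolation** — sparse voltage/activation samples become full
   per-vertex maps by solving the discrete Laplace equation with measured
   vertices as Dirichlet constraints (the "relaxation" colour
   interpolation of clinical mapping platforms).
5. **Nodal Dice concordance** — per-class Sørensen–Dice between the
   binarized voltage map A and the LGE scar map B over vertices,

   DSC_scar = 2|A∩B| / (|A|+|B|),  DSC_normal = 2|Aᶜ∩Bᶜ| / (|Aᶜ|+|Bᶜ|),

   with the total DSC the micro-average (= the nodal agreement fraction),
   swept across voltage thresholds 0.5–3.5 mV.
6. **Diagnostic accuracy** — sensitivity/specificity/PPV/NPV and
   trapezoidal-AUC ROC curves for voltage- and S-QRS-based detection of
   LGE scar, plus reconstruction of expected confusion counts from
   prevalence and printed rates.

A seeded synthetic left-ventricular phantom (analytic ellipsoidal
half-shell with a transmural antero-septal scar patch, class-conditional
log-normal voltages, truncated-Gaussian S-QRS, a known inter-frame rigid
transform) provides ground truth for every stage; real data in the same
formats (NIfTI volumes, PLY meshes, CSV point tables) drop straight in.

## Worked example

```r
library(scarconcord)

report <- run_pipeline(list(seed = 1))
report
#> <concordance_report>
#>   registration: landmark RMS 0.626 mm, ICP mean distance 1.726 mm (7 iterations)
#>   dice @ 1.5 mV: total 0.920, scar 0.720, normal 0.953
#>   voltage diagnostics: sens 0.81, spec 0.97, ppv 0.94, npv 0.89
#>   voltage ROC AUC: 0.928
#>   S-QRS ROC AUC: 0.985
```

The phantom's voltage and LGE maps agree on 92% of mesh vertices at the
1.5 mV threshold; agreement within the scar class alone (Dice 0.72) is
lower than within normal myocardium (0.95), as expected for a small patch
whose boundary is blurred by registration, rasterization and the overlap
of the two voltage distributions. The threshold sweep shows scar Dice
peaking near the class boundary:

```r
report$dice_sweep[, 1:4]
#>   threshold_mV dsc_total dsc_scar dsc_normal
#>            0.5     0.832    0.093      0.907
#>            1.0     0.893    0.571      0.939
#>            1.5     0.920    0.720      0.953
#>            2.0     0.911    0.713      0.947
#>            2.5     0.898    0.711      0.938
#>            3.0     0.827    0.608      0.889
#>            3.5     0.700    0.488      0.788
autoplot(report$dice_sweep)   # ggplot of the three curves
```

Worked example on printed summary statistics: predictive values implied by
a prevalence of 138 scar electrograms out of 445 with sensitivity 0.57 and
specificity 0.96 —

```r
diagnostic_summary(reconstruct_confusion(138, 307, 0.57, 0.96))
#>   sensitivity specificity   ppv   npv    tp    fp     tn    fn
#>          0.57        0.96 0.865 0.832 78.66 12.28 294.72 59.34
```

i.e. PPV 86% and NPV 83% after rounding.

A thin command-line front-end over the same functions is installed at
`system.file("scripts/scarconcord.R", package = "scarconcord")` with
subcommands `phantom`, `segment`, `register`, `map`, `dice`, `roc`, `run`.

## Package layout

* `phantom_config()`, `make_lv_phantom()`, `simulate_egm_samples()`,
  `simulate_pace_sites()`, `make_landmarks()` — synthetic data with ground
  truth.
* `fwhm_segment()`, `scar_point_cloud()` — segmentation.
* `fit_rigid_landmarks()`, `icp_refine()`, `map_points_to_nodes()`,
  `transform_points()` — registration.
* `assign_egm_to_nodes()`, `relax_interpolate()`, `binarize_map()`,
  `classify_sqrs()`, `egm_snr()` — electroanatomic maps.
* `dice_binary()`, `dice_threshold_sweep()` — concordance.
* `confusion_counts()`, `diagnostic_summary()`, `reconstruct_confusion()`,
  `roc_from_scores()` — diagnostic accuracy.
* `run_pipeline()` — the whole sequence from one (YAML-able) config.
* `tidy()`/`glance()`/`autoplot()` methods for result objects; NIfTI, PLY,
  CSV and JSON readers/writers for every artifact.

See the methods vignette (`vignettes/scar-voltage-concordance.Rmd`) for
the model, parameter rationale, numerical choices and known limitations.
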