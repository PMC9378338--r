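# torsotopo

Automated surface-topographic measurement of trunk shape for spinal
deformity assessment, in R.

Adolescent idiopathic scoliosis deforms the torso surface: lateral trunk
deviation, axial rotation with rib prominence, and waist asymmetry.
Surface topography quantifies these without ionizing radiation.
`torsotopo` implements a fully automated pipeline for 3D torso scans:

* **Registration.** A symmetric torso template atlas is deformed onto a
  raw scan (OBJ/PLY/STL) by stiffness-regularized nonrigid ICP after a
  markerless PCA + rigid-ICP initialization. The output is a clean,
  watertight torso in full per-vertex anatomical correspondence with the
  atlas; nine landmarks (bilateral PSIS/ASIS, xiphoid process, jugular
  notch, L2/T8/C7 spinous processes) transfer through the correspondence.
* **Measurements**, in a landmark-derived body frame. Intrinsic
  (rigid-motion invariant): spine length (cm), dorsal back surface area
  (dm²), cross-sectional areas at L2/T8/JN (dm²), section volumes L2–T8,
  XP–JN and PSIS–JN (L). Pose-dependent: back surface rotation
  BSR (the angle of the posterior supporting line of a cross-section — the
  scoliometer analogue — at 25/50/75% and the signed maximum, °), lateral
  centroid deviation (mm), trunk axial rotation (principal axis of the
  cross-section, °), and the Qangle, a Cobb-style angle computed from the
  fourth-order harmonic fit of the back symmetry line
  x(t) = a₀ + Σₖ₌₁⁴ (aₖ cos 2πkt + bₖ sin 2πkt). Sign convention:
  positive = the patient's left side posterior / deviation toward the left.
* **Synthetic cohort.** A parametric generator of watertight scoliotic
  torsos (stacked sections with a flattened back, spinal groove and
  paraspinal prominences; injectable lateral bow A·sin πt, axial rotation
  Θ·sin πt, one-sided hump) with analytic/quadrature ground truth, plus
  test–retest / remove–replace / rater noise models for reliability
  studies.
* **Reliability statistics.** ICC(2,1) (two-way random, absolute
  agreement, single rater) with F-based 95% CI, RMS (quadratic-mean)
  error, Spearman consistency-vs-BMI screening with Bonferroni–Holm
  correction, paired comparison of ICC sets, and a clinical-style
  per-parameter reliability report.

## Worked example

Generate a scoliotic torso (10° axial rotation, 15 mm lateral bow, 8 mm
left dorsal hump) and measure it:

```r
library(torsotopo)

spec <- torsoSpec(rot = 10, bow = 15, hump = 8)
tor  <- generateTorso(spec)
reg  <- asRegisteredTorso(tor)   # generator shares the atlas grid
measureAll(reg, landmarks = tor$landmarks)
#> MeasurementSuite (EOS pose):
#>   spine_length_cm          47.682
#>   back_area_dm2            20.655
#>   back_area_left_dm2       10.472
#>   back_area_right_dm2      10.183
#>   xsa_L2_dm2                4.983
#>   xsa_T8_dm2                4.978
#>   xsa_JN_dm2                4.118
#>   xsv_L2_T8_L               6.790
#>   xsv_XP_JN_L               5.499
#>   xsv_PSIS_JN_L            22.685
#>   bsr_25_deg                8.513
#>   bsr_50_deg               12.044
#>   bsr_75_deg                8.558
#>   bsr_max_deg              12.047
#>   centroid_dev_mm          15.207
#>   axis_max_deg             12.485
#>   qangle_deg               -1.359
```

Spine length (47.7 cm) and the areas/volumes are the intrinsic torso
dimensions. The injected 10° rotation appears in the trunk-axis and BSR
maxima (the 8 mm hump adds ~2° on top of the rotation at the apex, which
is why both exceed 10°); the 15 mm bow is recovered by the centroid
deviation (15.2 mm, positive = toward the patient's left). Without the
hump and with pure rotation, `bsr_max_deg` recovers Θ essentially exactly.

For a raw scan file the full pipeline is one call (registration included):

```r
runMeasure("scan.obj", poses = "EOS", outDir = "out")   # writes JSON + CSV
```

ICC(2,1) with its 95% CI on an n subjects × k raters table:

```r
icc21(matrix(c(9,6,8,7,10,6, 2,1,4,1,5,2, 5,3,6,2,6,4, 8,2,8,6,9,7), 6, 4))
#> ICC(2,1) = 0.290 [0.019, 0.761] (n = 6 subjects, k = 4 raters)
```

A thin command-line interface over the same functions lives at
`inst/cli/torsotopo.R` (verbs: `measure`, `simulate`, `reliability`,
`atlas-build`).

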