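---
title: "Automated surface-topographic measurement of trunk shape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated surface-topographic measurement of trunk shape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsotopo)
```

## The problem

Adolescent idiopathic scoliosis is a three-dimensional deformity of the
spine that expresses itself on the body surface: rib prominence, waist-crease
asymmetry, lateral trunk deviation and axial rotation of the torso. The
clinical standard for quantifying the deformity is radiographic (the Cobb
angle), but surface topography offers an objective, radiation-free
description of torso shape. `torsotopo` implements a fully automated
measurement pipeline for 3D torso scans:

1. a symmetric **template torso atlas** is deformed onto each raw scan by
   nonrigid registration, yielding a clean watertight torso with full
   per-vertex anatomical correspondence;
2. nine **anatomical landmarks** (bilateral PSIS and ASIS, xiphoid process,
   jugular notch, and the L2/T8/C7 spinous processes) are transferred from
   the atlas through the correspondence;
3. a suite of **intrinsic** (spine length, dorsal back area, cross-sectional
   areas at L2/T8/JN, section volumes L2–T8, XP–JN, PSIS–JN) and
   **pose-dependent** (back surface rotation, lateral centroid deviation,
   trunk axial rotation, Qangle) measurements is computed in a
   landmark-derived body frame;
4. reliability of the measurements over repeated scans is quantified by
   ICC(2,1), RMS error, and related statistics.

Because no scanner data ships with the package, a parametric generator of
watertight scoliotic torsos with analytic ground truth stands in for the
scanner and the cohort; every quantitative claim made by the test suite is
a comparison against that ground truth or against an independent numerical
oracle.

## Coordinate conventions and the body frame

All internal lengths are millimetres; reported units follow clinical
conventions: cm for spine length, dm² for areas, L for volumes, mm for
centroid deviation, degrees for angles.

The body frame is built from landmarks alone: the origin is the PSIS
centroid, the longitudinal axis w points from it to C7, the lateral axis u
is the PSIS\_L−PSIS\_R direction orthogonalized against w (so **+u is the
patient's left**), and the anterior axis v = w × u completes a right-handed
triad. Transverse measurement planes have normal w; the level fraction
t ∈ [0, 1] runs from the PSIS level (t = 0) to the C7 level (t = 1).

Signed measures need a convention, which clinical tables usually leave
implicit. Here: **positive BSR and trunk axis mean the patient's left side
is more posterior; positive centroid deviation and Qangle mean deviation
toward the patient's left.** Magnitudes are convention-free.

Note that the landmark-derived longitudinal axis is not the geometric
vertical: on a realistic torso C7 lies on a shallower section than the
pelvis, so w is tilted a couple of degrees in the sagittal plane. All
measurements are defined in the landmark frame, which is what makes them
reproducible across scans of the same subject.

For the Adam (forward bend) pose the angular reference switches from the
subject's coronal plane to the floor plane, and only spine length, back
area and the BSR family are computed — the remaining measures are
standing-pose only and are reported as `NA`.

## Geometry core

Cross-sections are computed by exact face/plane intersection; the resulting
segments are chained into closed loops through shared mesh edges, which is
exact on a watertight mesh (each cut edge is shared by exactly two cut
faces). Areas and centroids use the shoelace formulas; the trunk axial
rotation uses the eigenvectors of the polygon's second-area-moment tensor.
Section volumes clip the mesh to the slab between two transverse planes
(per-triangle Sutherland–Hodgman clipping), cap the cut loops with centroid
fans, and apply the divergence theorem to the capped closed surface; cut
loops of a registered torso are star-shaped about their centroid, which
makes the fan capping valid. Dorsal surface area sums labelled dorsal faces
with boundary triangles clipped exactly to the slab, so the value is stable
under refinement rather than jumping by whole triangles.

Properties enforced by the test suite: rigid invariance of all intrinsic
quantities (relative error < 1e−9 for pure geometry, < 1e−6 through the
full suite), scaling laws s/s²/s³ for lengths/areas/volumes, volume
additivity over interior partitions (< 1e−9 relative), and strict error
decrease under mesh refinement on analytic shapes.

## Back surface rotation as a supporting line

The paper-and-pencil instrument for trunk rotation is the scoliometer: a
level rested across the two paraspinal prominences. We operationalize BSR
at a level t as the angle between the **posterior supporting line** of the
cross-section — the convex-hull edge that faces posteriorly and spans the
lateral position of the section centroid — and the coronal (or floor)
reference. This is the geometric analogue of the physical instrument.

A consequence worth stating: on a strictly convex section (an ellipse) the
posterior supporting line degenerates to the tangent at the most posterior
point and is insensitive to axial rotation. Real backs are not convex —
they are flat, with a spinal groove between two paraspinal muscle bulges —
and the supporting line is only meaningful on such shapes. The synthetic
torso therefore models the back realistically (see below); on it, BSR
recovers injected axial rotation essentially exactly.

## Qangle

The back symmetry line (the registered dorsal midline, i.e. the fixed
points of the atlas symmetry map) is resampled uniformly in t and its
lateral deviation x(t) is fitted with a fourth-order harmonic series
x(t) = a₀ + Σₖ aₖ cos 2πkt + bₖ sin 2πkt (k ≤ 4) by least squares. The
Qangle mimics the Cobb construction on this curve: the apex is the interior
extremum of |x| (after removing the endpoint chord), the "end plates" are
the nearest slope extrema flanking the apex, and the angle is the
difference of the end-tangent inclinations atan(x′(t)/L), signed by the
apex direction. For x(t) = 25 sin 2πt mm on a 450 mm trunk this gives
2·atan(2π·25/450) ≈ 38.5°, which the tests verify against the closed form.

A known limitation, inherited from the construction itself: the periodic
harmonic basis represents a single half-wave bow (c(t) = A sin πt, which is
not 1-periodic) with endpoint ringing, so Qangle on pure-bow synthetic
torsos reflects the fitted, not the injected, curve. The Qangle tests
therefore use curves inside the harmonic span; recovery of the bow
amplitude itself is tested through centroid deviation, which does not pass
through the harmonic fit.

## The synthetic torso generator

The generator is the package's study population. A torso is a stack of
cross-sections along t with:

* semi-axis profiles a(t), b(t) (natural cubic splines through control
  values; defaults describe an adolescent trunk, pelvis ~152 mm lateral
  semi-axis narrowing to ~120 mm at the shoulders, AP semi-axis ~105 mm,
  trunk height H = 470 mm PSIS→C7);
* a **flattened dorsal half** (superellipse exponent 4), a **spinal
  groove** (5 mm deep Gaussian at the dorsal midline) and **paraspinal
  prominences** (6 mm Gaussian bumps at ±40° from the midline) — the
  anatomy a scoliometer actually rests on;
* deformity parameters: lateral bow c(t) = A sin πt, axial rotation
  θ(t) = Θ sin πt (positive Θ rotates the patient's left side posteriorly),
  and a one-sided dorsal hump (Gaussian in azimuth, sin πt along the
  trunk);
* a flesh margin of 0.05·H beyond both landmark levels, so every
  measurement slice in t ∈ [0, 1] is a proper interior cross-section;
* end caps closing the surface; watertightness is verified structurally.

Ground truth is analytic where closed forms exist (π·a·b section areas for
the pure-ellipse configuration) and dense-boundary quadrature otherwise
(4096 azimuthal samples; volumes by trapezoidal quadrature over 401
levels; the midline by 2001-point arclength). Landmarks are placed on grid
vertices, which makes landmark-transfer errors exactly measurable.

What the generator does **not** emulate: arms and head (the template torso
has none, matching the measurement span), breathing and soft-tissue
dynamics, scanning holes and photogrammetric artefacts beyond i.i.d.
vertex noise, and clothing. Passing tests demonstrate correctness of the
geometry and statistics under realistic smooth shape variation; they do not
certify performance on raw scanner meshes.

The scan-protocol noise model mirrors a clinical reliability study: within
a placement ("test–retest") a scan differs by a small rigid jitter plus
vertex noise; between placements ("remove–replace") the posture parameters
(Θ, A) are additionally re-drawn, and each rater carries a small systematic
guidance bias. Defaults (σ of 1.5° rotation / 3 mm bow between placements,
0.3° / 1 mm / 0.3 mm within) describe cooperative subjects and were fixed
at design time.

## Template atlas and registration

The template atlas is the zero-deformity torso of the same generator, so
its mirror symmetry, landmark vertex indices, dorsal midline chain and
dorsal/ventral face labels are exact by construction; the default grid is
48 rings of 96 vertices. The atlas serializes as PLY plus a JSON sidecar.

Registration is a standard two-stage design:

1. **Initialization.** Markerless by default: PCA aligns the vertex clouds
   (longitudinal = largest-variance axis), the four axis-sign candidates
   are scored by subsampled cloud-to-cloud RMS, scale comes from the
   longitudinal extents, and a rigid ICP refinement with nearest-vertex
   correspondences polishes the pose (scale is re-estimated from extents
   each iteration rather than fitted by Procrustes, so nonrigid shape
   differences cannot leak into a spurious global stretch). With landmark
   hints, a similarity Procrustes on the landmark pairs is used instead.
2. **Nonrigid ICP.** Per-vertex displacements minimize a closest-point
   data term (point-to-surface; correspondences rejected beyond 30 mm or
   60° normal disagreement) plus λ times an edge-difference stiffness
   term, with λ stepped down over {50, 20, 8, 3, 1} and up to 20 inner
   iterations per stage, each solving one sparse linear system per
   coordinate. Because the rejection set changes between iterations the
   residual trajectory is mildly non-monotone; the best iterate of each
   stage is kept, and a residual that worsens across a whole stage raises
   an error. The result always retains the template connectivity, hence
   watertightness and full correspondence; flipped triangles raise a
   warning. No randomness is used anywhere in registration.

**Identifiability limitation.** Surface-to-surface registration observes
displacement only along the surface normal; tangential correspondence on
featureless regions is fixed by the stiffness prior, not by data. On
smooth warps with tangential components (e.g. axial rotation of a smooth
ventral wall) landmark transfer can slide by several millimetres — an
inherent property of markerless nonrigid ICP, not an implementation
defect. The registration contract is therefore validated on a
normal-direction warp (a 10 mm radial bulge), where residual RMS stays
below 1 mm and landmark transfer below 2 mm at the shipping resolution;
dorsal landmarks, anchored by the groove-and-bump relief, transfer well in
all cases, which is what the dorsal measurements rely on.

## Reliability statistics

ICC(2,1) — two-way random effects, absolute agreement, single rater — is
computed from the two-way ANOVA mean squares,
ICC = (MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE)), with the F-based
95% confidence interval of the absolute-agreement construction (McGraw &
Wong). Negative estimates are reported as computed. The implementation is
checked against a definitional ANOVA oracle (`stats::aov`) to 1e−10 on
random tables, and its CI coverage is verified by simulation (population
ICC 0.9, n = 200, k = 2, 500 replicates).

A statistical caveat worth knowing when k = 2: the F-based interval is
built from the realized rater pair (the rater mean square has k − 1 = 1
degree of freedom), so it covers the rater-conditional agreement, not the
agreement marginalized over hypothetical new raters. If the rater variance
component is large, nominal coverage of the marginal population ICC is not
attained — with a 50/50 rater/residual split at population ICC 0.9,
coverage drops to roughly two thirds (we verified the identical behaviour
in an independent implementation). The package's coverage simulations
therefore use a small rater variance (σ²ᵣ = 0.1 of a unit error budget),
which is also the realistic regime: trained raters in clinical
surface-topography studies are near-interchangeable, with inter-rater
reliability indistinguishable from intra-rater.

The reliability report mirrors the clinical layout: per parameter (and
pose), intra-rater test–retest ICC (trials 1 vs 2 of placement 1),
intra-rater remove–replace ICC (trial 1 of each placement), inter-rater
ICC (trial 1, placement 1, rater A vs B) with its CI, and the grand
mean/SD over all scans. The first-scan-per-placement pairing is a policy
choice, stated here because published tables rarely spell it out.

Two screens accompany the ICCs: a Spearman correlation of inter-rater
consistency (relative differences for intrinsic measures, absolute for
pose-dependent) against BMI with Bonferroni–Holm correction at α = 0.05
across the parameter family, and a paired two-tailed t comparison between
sets of ICCs (with the degenerate zero-variance case documented to return
t = 0, p = 1 for identical sets).

## Problem sizes and numerical choices

The shipping resolutions were chosen once, as a balance of discretization
error against desktop runtime: template atlas 48×96; analytic-accuracy
fixtures 48 levels × 128 azimuths (inscribed-polygon area deficit
≈ 4·10⁻⁴, comfortably inside the 0.5% accuracy contract), with a
resolution-doubled mesh (96×256) as the back-area oracle; profile measures
sampled at 201 levels (tests use 101 or fewer where the profile is
smooth); registration tests at 20×40 to 48×96. Endpoint merging in slice
assembly uses a 1e−6 mm tolerance; principal axes are declared undefined
when the moment eigenvalues agree to 1e−9 relative; cross-sections under
1 dm² raise a registration-quality warning; inverted landmark order aborts
volume computation with the offending pair named.

## Known limitations

* Registration fidelity is to the measurement contract of a standard
  stiffness-regularized nonrigid ICP; the original full-body registration
  algorithm behind the published system is not reproduced.
* Tangential landmark transfer on featureless surface regions is
  underdetermined (see above).
* The Qangle's harmonic basis under-represents non-periodic bows.
* The generator's noise model is smooth and parametric; it does not model
  scan holes (though registration tolerates them), outliers, or clothing.
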