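---
title: "Measuring the airway response to jaw displacement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the airway response to jaw displacement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uamorph)
```

## The model

The package quantifies how surgical repositioning of the maxilla and the
mandible reshapes the pharyngeal airway. Its working hypothesis is a
*neutral-impact interval*: for antero-posterior (AP) displacements inside
roughly ±5 mm the airway remodels unpredictably, with no consistent
relation to the bony movement, while beyond that interval the
cross-sectional area gain grows linearly with the excess displacement. The
analysis therefore aims at one number per bone segment, area cutoff and
pharyngeal subregion: the AP displacement threshold above which a given
relative area gain becomes expected rather than incidental.

All geometry lives in a patient-centred frame: +x lateral (patient right),
+y anterior, +z cranial, millimetre units throughout. A bone displacement
is a six-degree-of-freedom rigid transform reported as intrinsic z–y–x
Euler angles (yaw about z, then roll about y, then pitch about x) plus
translations; the AP component is `ty`, positive for advancement and
negative for setback. The Euler order is a convention the data do not pin
down; the package fixes it once and the decompose/compose round-trip test
makes the choice self-consistent. At gimbal lock (|roll| = 90°) the
decomposition sets yaw to 0 and flags the record.

## Registration chain

Displacement extraction mirrors manual practice in mesh-processing tools,
made reproducible:

1. fit the post-operative cranial base onto the pre-operative one
   (least-squares rigid Kabsch fit on labelled landmark pairs:
   frontozygomatic sutures, zygomatic arches — structures surgery does not
   touch);
2. carry the post-operative segment landmarks into that frame;
3. fit the pre-operative segment landmarks onto them (molar and canine
   cusps, four per segment), optionally refined by ICP when segment meshes
   are available;
4. decompose the result. Translations are reported as the motion of the
   segment-landmark centroid, so a pure advancement reads as `ty` exactly
   regardless of any small rotation component.

Airway models are aligned separately through three airway landmarks
(pharyngeal recess left/right, interarytenoid notch) plus ICP. Because the
anterior airway wall deforms with surgery, ICP is restricted by default to
the posterior pharyngeal wall — identified per cranio-caudal band as
vertices behind the local section median — which is essentially inert to
jaw repositioning. ICP is point-to-surface with deterministic seeded
sampling, a 10 mm correspondence rejection distance, and a monotonicity
guard: an update that increases the RMS is rejected and iteration stops,
so the RMS trace is non-increasing by construction. Module defaults are 50
iterations, 1e-6 mm RMS tolerance and 5000 samples; the cohort pipeline
uses a lighter profile (25 iterations, 1e-4 mm, 1200 samples) because a
landmark initialisation leaves only sub-millimetre refinement to do.

## Slab morphometry

The cropped airway is divided along z into 25 equal-height slabs, labelled
superior→inferior as 5 nasopharynx / 9 oropharynx / 11 hypopharynx.
Dividing *each model's own extent* is what normalises the vertical
dimension: slab *i* of the pre- and post-operative models spans the same
fractional interval of its airway, so indices remain comparable when the
airway lengthens or shortens after surgery. Slab intervals are half-open
(`[z_lo, z_hi)`), with the topmost slab closed.

Each slab's cross-section is measured as the area of the axial silhouette
of the solid airway portion inside the slab — the standard cross-sectional
airway measure. The silhouette is rasterised at 0.1 mm (configurable); a
pixel counts when the vertical line through its centre intersects the
solid inside the slab's z interval, decided by the winding number of
oriented surface crossings. This avoids explicitly clipping and capping
each slab and is exact up to raster resolution; halving the pixel changes
areas by well under 0.5% on the synthetic fixtures, and a 720-gon cylinder
reproduces the exact inscribed-polygon area to ~0.04%. The projection axis
is axial by assumption (the natural choice for a cranio-caudal airway) and
configurable in principle via a prior rigid transform of both models.
Slabs with zero pre-operative area cannot carry a percentage change; they
are flagged invalid and excluded from statistics, never silently dropped.

Volumes come from the signed-tetrahedron (divergence theorem) sum over the
watertight surface; cropping planes cap the cut cross-sections by fan
triangulation about the loop centroid, which is exact for the convex or
star-shaped sections of tubular airway models (a documented limitation for
strongly non-convex sections).

## Threshold statistics

The unit of analysis is the slice (slab), labelled positive when its
ΔArea% meets the cutoff (+30, +50 or +100%) and scored by its patient's
segment AP displacement — the patient-level score repeats across that
patient's slices, a deliberate pseudo-replication that matches the
original design; a patient-averaged sensitivity mode exists but is off by
default. Candidate thresholds are midpoints of consecutive sorted unique
scores; AUC is trapezoidal and equals the Mann–Whitney identity
`U/(n₊·n₋)` on every dataset (asserted as an invariant). The primary
threshold maximises Youden's J, ties resolving to the smaller displacement
(the clinically conservative call); secondary local maxima within 0.05 of
the peak are reported alongside, reproducing the dual-peak presentation
used for the mandible at the lower cutoffs.

Subgroup comparisons follow the published scheme: the surgical groups
(maxillo-mandibular advancement, MMA; maxillary advancement + mandibular
setback, MAMS) are compared per region with MMA split at 5 mm AP
(boundary inclusive in the "at or above" arm) by one-way ANOVA and
Games–Howell post hoc tests on ΔArea%, and by Mann–Whitney on ΔVolume%.
ANOVA and Mann–Whitney delegate to the classical base-R routines (the
one-way F is computed from the textbook sum-of-squares decomposition and
cross-checked against `lm()`); Games–Howell is implemented directly —
pairwise Welch-type statistics referred to the studentized-range
distribution with `q = t√2` — because no installed package provides it,
and it is verified against an independent reference implementation and
against Tukey HSD in the equal-variance limit. No multiple-testing
correction is applied beyond Games–Howell's family-wise control; α = 0.05
two-tailed. The combined effect of both segments is summarised by a
binomial logistic model on (maxilla AP, mandible AP) whose fitted
probabilities feed a multivariate ROC, run by default at the +30% cutoff
where the positive-to-negative slice balance is closest to one; complete
separation is flagged and the ROC still computed on the separating score.

## The synthetic cohort

No imaging data accompany the method, so every pipeline stage is exercised
on synthetic cases with exact ground truth.

**Meshes.** The pharynx is a watertight capped tube along z (~70 mm,
96 points per ring by default) with spline-interpolated elliptical
sections, lateral semi-axis wider than the antero-posterior one and a
narrower oropharyngeal waist; per-station log-normal jitter (4% SD)
varies anatomy across patients. A constant-profile tube reproduces the
capped-prism volume to 1e-9, which anchors the volume code analytically.

**Landmarks.** Cranial-base, dental and airway landmark bundles sit at
plausible skull offsets, mirror-symmetric up to jitter. The zygomatic-arch
points are placed well posterior to the frontozygomatic pair; the
resulting spread matters, because pitch uncertainty in the cranial-base
fit is amplified by the ~70 mm lever arm to the dental landmarks and
dominates the AP error budget. With 0.3 mm per-coordinate picking noise
the median AP recovery error is ~0.23 mm.

**Response.** Per region, an effective displacement mixes the two segments
through a maxilla-share weight, `d_eff = w·AP_mx + (1−w)·AP_md` with
w = 0.8 / 0.5 / 0.2 for naso/oro/hypopharynx — the nasopharynx sits behind
the maxilla, the hypopharynx behind the mandible. Per-slab ΔArea% is
Gaussian noise (σ = 15 percentage points) around 0 inside the neutral
interval (θ = 5.5 mm) and around β·(d_eff − θ) beyond it (β = 25 %/mm);
draws at or below −100% are truncated at −95% with a warning. The
post-operative mesh is the pre-operative one with each cross-section
scaled about its posterior-wall point by √(1 + ΔArea%/100), interpolated
between slab centres — so the per-slab area change is exact by
construction away from interpolation boundaries, and the posterior wall
stays (approximately) fixed, as assumed by the alignment. A random scan
pose (≤1° rotations, ≤3 mm translations) moves all post-operative data
into a different frame so registration has real work to do. Cohort AP
distributions are log-normal, calibrated so the group medians match the
published descriptive statistics (MMA maxilla +3.8 / mandible +4.6 mm;
MAMS maxilla +3.9 / mandible −2.5 mm, setbacks capped at −5.8 mm), with
29 + 16 patients by default. All randomness flows from one master seed
through a fixed splitting scheme (`seed·48271 + 7919·k mod 2³¹−19`).

**What the generator does not emulate:** soft-tissue mechanics, airway
wall thickness, segmentation noise, non-rigid anatomical variation between
time points, and curved airway centrelines. Passing tests therefore
demonstrate the correctness of the measurement chain, not clinical
validity on real CBCT anatomy.

## Estimator behaviour worth knowing

Under a linear-above-threshold response, the ROC threshold for a +c%
cutoff is *not* an unbiased estimate of θ: a slice only becomes positive
once the mean response actually reaches the cutoff, i.e. near
`θ + (c − σ·z)/β`, and scoring by a single segment's AP while the response
mixes both segments shifts it further. With the default β = 25 and σ = 15
the pooled 50%-cutoff threshold mean sits 1–2 mm above θ across cohort
seeds. On real data the same caveat applies whenever the supra-threshold
response is shallow relative to the cutoff; the three cutoffs are analysed
jointly precisely to expose this dependence.

## Problem sizes and numerical choices

Default analyses use 96-ring × 56-level meshes (~11k faces), a 0.1 mm
raster, and the lighter ICP profile above; a 45-patient cohort generates
in under a second and analyses in well under a minute on one core. The
nearest-point kernel prunes by centroid-z ordering (exact: it equals
exhaustive search, asserted on small meshes); silhouette rasterisation
bins triangles on a 16-pixel grid and jitters pixel centres by 1e-4 pixel
to avoid edge-degenerate ray crossings. Landmark fits reject configurations
with fewer than three pairs or collinear points; ICP errors out when no
correspondence survives the rejection distance, reporting the nearest
miss.
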