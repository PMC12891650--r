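---
title: "Measuring the iliococcygeus angle: geometry, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the iliococcygeus angle: geometry, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icangle)
```

## The measurement model

The iliococcygeus muscle (ICM) forms two sheets that rise from their
lateral attachments toward the midline. In a coronal section the sheets and
the transverse pelvic plane form a triangle; the apex angle of that
triangle, the **total iliococcygeus angle (ICA)**, summarizes pelvic floor
support in a single number:

$$\text{total ICA} = 180^\circ - \text{left ICA} - \text{right ICA},$$

where the side angles are the inclinations of the left and right sheets
relative to the transverse plane. Flat sheets (side angles near zero) give
a total near 180° and indicate good support; steep sheets a sharp total.

`icangle` computes this per subject from two inputs: a binary 3D
segmentation of the levator ani (a `volume_mask`, NIfTI-1 on disk) and four
bony landmarks (`landmark_set`): pubic symphysis (PS), sacrococcygeal joint
(SCJ) and the two ischial spines. The chain is:

1. **PICS frame** (`pics_frame`). Origin at PS; the PICS axis is the unit
   vector PS → SCJ; the lateral axis is the inter-spine vector (left minus
   right) Gram–Schmidt-orthogonalized against the PICS axis, so positive
   lateral is the subject's left; the vertical axis is lateral × PICS,
   which makes the (lateral, axial, vertical) triple right-handed
   (determinant +1). This is the minimal frame determined by exactly the
   four named landmarks: the external references that define the 3D pelvic
   inclination correction system do not fix a further rotation offset, so
   none is applied. The construction is deterministic and rigid-motion
   equivariant, which the tests verify directly.
2. **Plane placement** (`define_planes`). With $D$ the axial projection of
   the *right* ischial spine onto the PICS axis, plane $k$ sits at
   $kD/5$, $k = 1\ldots5$, each perpendicular to the PICS line. The source
   description ("five equidistant planes from the pubic symphysis to the
   ischial spine") leaves open whether the endpoints carry planes; the
   chosen scheme puts plane 5 at the spine level and plane 1 one fifth of
   the way from the pubis — consistent with anterior avulsion gaps
   disturbing *plane 1*, which is how the scheme behaves on avulsion
   phantoms. An `"inclusive"` scheme ($ (k-1)D/4 $) is available via
   `ica_control(plane_scheme=)` for sensitivity analyses.
3. **Slab extraction and side split** (`extract_slab`, `split_sides`). A
   mathematical plane intersects no voxel centers, so each plane gathers
   the foreground voxel centers whose axial coordinate falls in a slab
   $[x_k - h, x_k + h)$ (half-open, so adjacent slabs never share a
   voxel). Points with positive lateral coordinate are the left side,
   negative the right; exact-midline points (lateral = 0) belong to
   neither and are discarded.
4. **Side fits** (`fit_side_line`). The side angle is obtained from a
   first-degree polynomial fit of the vertical on the lateral coordinate —
   ordinary least squares, the literal reading of the published method —
   and reported as $\arctan|b|$ in degrees, clamped to $[0, 90)$. Side
   angles are magnitudes by construction, which the triangle formula
   presumes. An orthogonal (major principal axis) estimator is provided
   (`fit_estimator = "principal_axis"`) but off by default: it is not what
   the reference method describes, though it is the better-behaved choice
   for very steep sheets where regression attenuation matters.
5. **Aggregation** (`compute_plane_ica`, `measure_ica`). A plane is
   *measurable* only if both sides could be fit; the triangle identity is
   then applied exactly. Unmeasurable planes (avulsion gaps, sparse
   segmentations) are flagged, never fatal.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `slab_halfwidth_mm` | 1.5 × in-plane voxel size (0.735 mm at 0.49 mm) | mm | ≈3 voxel layers per slab: enough points for a stable fit; thin against the 12 mm inter-plane spacing of a typical $D \approx 60$ mm pelvis, so planes never mix |
| `min_points` | 10 | voxels/side | below ~10 centers a slope estimate is dominated by voxelization; also the guard that turns an avulsion gap into "unmeasurable" rather than a garbage angle |
| `plane_scheme` | `"fifths"` | — | see above |
| `fit_estimator` | `"ols"` | — | fidelity to the described first-degree polynomial fit |
| `alpha` | 0.05 | — | conventional significance level |
| `exclusion_threshold` | 0 subjects | — | strict reading of "a plane where the angle could not be measured is omitted from statistical analysis": any unmeasurable subject drops the plane |

## Coordinate and I/O conventions

Everything downstream of I/O works in world millimetres; voxel centers are
the geometric carriers, with 0-based index $(i,j,k)$ mapping to world via
`affine %*% c(i, j, k, 1)` (the NIfTI convention). Landmarks must be in the
same world space as the mask affine. 3D Slicer fiducial files declare their
convention in the header; LPS files are sign-flipped in x and y to the
NIfTI RAS world on read, and `read_landmarks(convention=)` can override a
wrong or missing declaration — a silent RAS/LPS mismatch would corrupt
every angle, which is why the switch is explicit. Masks are binarized as
nonzero → foreground, since segmentation tools disagree on label values.

Because no NIfTI reader is assumed on the system, the package carries a
minimal, self-contained NIfTI-1 reader/writer (sform preferred, qform
quaternion fallback, then pixdim; both endiannesses; uint8/int8/int16/
uint16/int32/float32/float64). The test suite cross-checks it against
nibabel in both directions.

## Defect-score aggregation

Per muscle (PCM, ICM) the two expert side scores 0–3 are summed: 0 = none,
1–3 = minor, 4–6 = major, and **any** side score of 3 forces *major* (for
the ICM a side score of 3 denotes a hernia, which `categorize_defect`
flags). All sixteen score pairs are pinned against a hand-written table in
the tests. Prevalence percentages are `100·count/n` rounded half away from
zero to one decimal; published reports occasionally print neighbouring
values for the same fraction (e.g. 18.7 for 3/16 = 18.75), and the package
prefers deterministic conventional rounding over mimicking any one such
choice. PCM scores are conventionally assigned on supine images and ICM
scores upright; the aggregation itself is posture-agnostic.

## Cohort inference

Per eligible plane (after the exclusion rule) the package reports
Shapiro–Wilk W and p per group (reported, never used as a gate), a
classical one-way fixed-effects ANOVA, and pairwise comparisons between
all six group pairs with the Bonferroni adjustment $p_{adj} = \min(1, 6p)$.
The pairwise statistic behind a "Bonferroni post hoc" is not fixed by the
name; the package uses pooled-variance two-sample t tests, the textbook
choice after a one-way ANOVA, with Welch's t as an option. The family is
the six pairs *within* one plane; no correction is applied across planes,
matching how per-plane p-values are conventionally reported for this
measurement. Complete-case analysis is used throughout: only measurable
values enter summaries and tests.

Degenerate inputs are defined rather than left to chance: an all-identical
response gives F = 0, p = 1; a group of one gets SD 0 with a
`single_subject` flag; constant samples are "untestable" for Shapiro–Wilk.

A note on printed tables of this measurement: integer-rounded side angles
and totals need not satisfy the triangle identity exactly (each of the
three numbers rounds independently, so the printed total can differ by 1°
from 180 minus the printed sides). The acceptance tests therefore pin only
rounding-consistent cells; `summarize_groups` keeps full precision in the
stored layer and confines integer rounding to a separate presentation
layer.

## What the phantom generator emulates — and what it does not

`generate_phantom` builds two *planar* sheets attached at lateral
$\pm W$ (default 40 mm) descending toward the midline at prescribed
per-plane angles (linearly interpolated between plane positions), with a
thickness of 3 mm — a typical iliococcygeus — voxelized at the stated
0.49 mm isotropic resolution. Landmarks are placed analytically in the
construction frame, so the derived PICS frame is exact and the ground
truth per plane is `180 − left − right` of the prescription. Options add
an anterior avulsion gap (one side removed below a given axial extent) and
boundary noise (each surface-adjacent voxel flipped independently with a
given probability, seed-deterministic).

The phantom validates the *estimator*: angle recovery within 2° across a
5×5 grid of side angles in [5°, 70°], rigid-motion invariance within 0.5°,
exact mirror symmetry, avulsion locality, robustness to 20% boundary-voxel
noise. It does **not** emulate anatomy: real ICM sheets are curved, have
varying thickness, and neighbouring structures make segmentation itself
uncertain. A green phantom test therefore establishes that the geometry
pipeline is correct and stable — not that the measurement is accurate on
any particular clinical segmentation protocol.

`simulate_cohort` draws per-subject plane totals from normal distributions
at the published group means and SDs (truncated to the valid (0, 180)
interval — negligible at those parameters), synthesizes side angles
satisfying the triangle identity with a small N(0, 2°) left/right
asymmetry, marks the published number of avulsion subjects per group
unmeasurable at plane 1, and draws defect categories from the published
prevalence fractions (side scores uniform over the pairs compatible with
the drawn category, so aggregation can be round-trip tested). No plane-1
group summary was ever published (the plane was excluded for avulsions),
so the simulator reuses the plane-2 parameters there as an explicitly
synthetic stand-in.

## Known limitations

- Angles are fit on the full slab point cloud, not a skeletonized midline;
  for very thick or strongly curved segmentations the OLS slope can
  underestimate steep sheets (attenuation). The principal-axis option
  mitigates this but departs from the reference method.
- $D$ is measured as the axial *projection* of the right ischial spine
  (the planes are perpendicular to the PICS axis); a Euclidean-distance
  reading would shift plane positions by a few percent for oblique spines.
- Masks are measured at native resolution; no resampling or smoothing is
  applied.
- Static geometry only: no straining/dynamic sequences, no puborectalis
  geometry, no automatic landmark detection.
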