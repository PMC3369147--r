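---
title: "Measuring femoral-head coverage: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral-head coverage: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hipcov)
```

`hipcov` measures acetabular coverage of the femoral head from 3D
surface models, computes the standard 2D radiographic measures of
acetabular morphology, and relates the two statistically. This vignette
documents the underlying models, every convention the implementation
had to fix where the underlying geometry is ambiguous, the synthetic
data generator that supplies ground truth, and what the validation
suite does and does not establish.

## Anatomical frame

All 3D geometry uses one fixed right-hip convention: **+x lateral, +y
anterior, +z superior**, lengths in mm, angles in degrees. Version and
inclination signs, the region labels (AL/AM/PL/PM) and the default
covered-side witness (below) are all defined in this frame. Left hips
should be mirrored into it before analysis.

## The 3D coverage chain

`head_coverage()` runs six stages, each available separately.

**Principal curvatures** (`estimate_curvature()`). Per vertex, a
quadric height field $z = ax^2 + bxy + cy^2 + dx + ey$ is fit over the
neighbours within a radius (default 2.5× the mean edge length, minimum
2×) in the tangent frame of the area-weighted vertex normal; the
principal curvatures are the eigenvalues of the shape operator built
from the first and second fundamental forms of the fit. Signs follow
the convex-positive convention: a sphere of radius $R$ has
$k_1 = k_2 = 1/R$. Vertices with fewer than six neighbours are flagged
and interpolated from their neighbours. The default radius trades bias
(a larger window blurs the junction) against noise; the junction
stability checks in the test suite guard it.

**Head sphere.** Spherical (umbilic) vertices — $k_1 \approx k_2 > 0$ —
are selected from the curvature field, and a sphere is fit to them by a
linear algebraic fit refined with Gauss–Newton iterations on the
geometric residuals, with one MAD-based trim pass. This avoids any
prior knowledge of where the head is.

**Head–neck junction** (`detect_head_neck_junction()`). On the convex
head $k_2 > 0$; at the saddle-shaped head–neck transition $k_2 < 0$.
Marching down meridians from the head apex (the antipode of the neck
direction), the first zero-crossing of $k_2$ per azimuthal sector
(default 72 sectors) is located by linear interpolation; only the first
crossing is taken so that distal shaft inflections cannot capture the
ring. A least-squares plane is fit to the crossing points with one
MAD-trim pass (no RANSAC — the single trim pass handles cam-bump
outliers and keeps the estimator deterministic), and the mesh is cut
along the plane, keeping the head side. Fewer than eight crossings is a
hard failure ("no inflection ring"), which is also what an isolated
sphere produces.

**Neck and shaft centers** (`narrowest_neck_center()`). Planes
perpendicular to the head-to-shaft axis are sampled at 0.5 mm steps;
each planar cross-section's area and centroid come from Green's theorem
over the oriented mesh–plane intersection segments, which requires no
contour assembly but does require consistent outward winding. Sections
whose oriented segments do not close (e.g. when a face filter broke the
loop) are discarded. The minimum-area section's centroid is the neck
center; `head_coverage()` runs the scan twice, re-aiming the axis at
the first pass's result, because the head-to-shaft line is oblique to
the true neck axis. The shaft center is the centroid of the distal
quarter of the mesh (by distance from the head center) — the source
data place no marker on the shaft, so this is a documented convention.

**Region planes** (`region_planes()`, `partition_head()`). Plane 1
passes through the head, neck and shaft centers (normal oriented
anteriorly); plane 2 passes through the head center perpendicular to
plane 1, its normal the medially-oriented component of the head–neck
axis orthogonal to plane 1's normal. Faces straddling either plane are
split geometrically, never majority-voted, so region areas sum to the
head area to machine precision — the conservation checks in the test
suite assert a relative error below $10^{-9}$.

**Rim projection and covered classification** (`project_rim()`,
`covered_region()`). The rim spline (a closed periodic cubic spline
through the ordered rim points, chord-length parameterised) is sampled
densely (default 512; 256 changes total coverage by under 0.005
percentage points on validation hips) and each sample is mapped to its
Euclidean nearest point on the head mesh by exact point-to-triangle
distance. Face vertices and the projected curve are then mapped to the
unit sphere about the head center and classified by an even/odd
geodesic-crossing test against the closed spherical polygon. Faces
straddling the curve receive a fractional covered area by recursive
spherical subdivision (default depth 3, i.e. 64 sub-triangles).

### The covered-side ambiguity

A closed curve divides the sphere into two regions, and the rim curve
alone cannot say which one the acetabulum covers: a cap of half-angle
$\theta$ about one pole has exactly the same rim as a cap of
$180-\theta$ about the antipode. Any rule that derives the covered side
from the rim (for instance, from the rim centroid direction) silently
inverts for cups deeper than a hemisphere — and normal hips *are*
deeper than hemispheric in effective cap angle. `covered_region()`
therefore takes an explicit `interior` witness direction, defaulting to
the medial direction of the anatomical frame, since the acetabulum lies
medial to the femoral head in any orientation this package supports.
Passing `interior = NULL` restores the rim-centroid fallback, valid
only for shallow cups.

## The 2D measures

All six measures are defined relative to the horizontal reference
direction supplied with the landmarks (in synthetic data, the
inter-teardrop direction). The lateral and superior unit directions are
derived from the landmarks themselves — medial points from the
ipsilateral toward the contralateral teardrop, superior is the
perpendicular on the sourcil side of the teardrop — which makes every
measure invariant under rigid in-plane transforms and left/right
mirroring without relying on sign conventions of the reference vector.

* **Extrusion index**: uncovered horizontal head width lateral to the
  sourcil over the head diameter, clamped at 0 when the sourcil
  overhangs the head edge (a physical uncovered distance cannot be
  negative).
* **LCEA**: angle at the head center between the vertical and the ray
  to the lateral sourcil, lateral positive.
* **Acetabular index / acetabular angle**: inclination of the
  medial-sourcil-to-lateral-sourcil and teardrop-to-lateral-sourcil
  segments, up-sloping positive.
* **Posterior wall distance**: signed horizontal distance from the head
  center to the posterior wall where it crosses the horizontal through
  the center, lateral positive; with several crossings the most lateral
  is used (a documented convention).
* **Crossover ratio**: the walls are swept from the lateral rim and the
  first *transversal* crossing — a sign change of the anterior wall's
  signed distance to the posterior wall exceeding 0.5% of the
  acetabular diameter — is located; the ratio is the distance from the
  lateral rim to that point over the acetabular diameter. Samples
  projecting onto the posterior wall's free endpoints, and the first
  4% / last 10% of the anterior wall's course where the two walls
  anatomically merge, are excluded: separations there reflect the
  shared wall origin, not a crossover. A tangential graze is not a
  crossover; symmetric cups whose walls project onto the same curve
  correctly return "no crossover".
* **Obturator index**: ipsilateral/contralateral foramen width ratio,
  adequate in the inclusive band [0.8, 1.2].

## The synthetic hip generator

The generator supplies what the measurement chain cannot get from real
data here: geometry with known ground truth.

**Femur.** A sphere (head) blends into a cylinder (neck) through a
meridian fillet arc tangent to both, then a bent cylinder (shaft); the
mesh is watertight and consistently wound. The fillet is what makes the
junction detectable *and* analytically known: the minimum principal
curvature jumps from $+1/R$ (head) to $-1/\rho_f$ (fillet) exactly at
the sphere–fillet tangency circle, so `true_junction_plane()` is exact
and junction recovery can be scored in mm. Defaults (head 25 mm, neck
15 mm, fillet 4 mm, neck-shaft angle 130°) follow typical adult
proportions.

**Cup and rim.** The cup is a sphere concentric with the head
(congruent joint), so radial rim projection is the identity on
directions and closed-form coverage is available. At zero version and
inclination the cup pole is the reversed neck axis (the neck aims into
the socket); version rotates the pole about the superior axis (positive
= anteverted), inclination about the anterior axis. The rim is the
spherical circle at polar half-angle `cup_depth_angle` around the pole,
modulated by two elevation terms anchored to the *body* azimuth rather
than the cup: a period-2 saddle (amplitude 8°, phase 120°) and a
period-1 anterior recess (10°) — the real rim is saddle-shaped and its
anterior segment sits lower than the posterior. These two terms are
what make a radiographic crossover geometrically possible at all: a
planar circular rim projects to an ellipse whose two wall arcs can
never cross. With the default amplitudes, retroverted cups (version
< 0) produce a crossover whose ratio grows with severity and anteverted
cups do not, which is the defining contrast between the patient and
control groups. The amplitudes were fixed once, from that qualitative
requirement, and are not tuned per analysis.

**Ground truth.** Total coverage over the full head sphere has the
closed form $100\,(1 - \overline{\cos\theta(t)})/2$ with the mean taken
over rim azimuth (evaluated by quadrature to $10^{-12}$; for an
unperturbed rim this is the spherical-cap fraction
$100\,(1-\cos\theta_c)/2$ exactly). Regional ground truth comes from
`mc_region_coverage()`, a Monte-Carlo spherical integrator that
classifies uniform random directions by cup membership and region
planes — independent of every mesh-based code path, which is what makes
it usable as an oracle. It can be restricted to the head side of a
junction plane so oracle and pipeline integrate the same domain.
Note the two conventions: *ground-truth totals* refer to the full head
sphere (closed forms exact, area-weighted means consistent), while the
*pipeline's percentages* refer to the head cut at the junction;
domain-matched comparisons pass the detected junction plane to the
oracle.

**Version-0 symmetry.** With the pole on the neck axis, a version-0 cup
is mirror-symmetric across the neck/shaft plane, so the ground-truth
equalities are AL = PL and AM = PM (anterior/posterior twins) — tested
with the rim undulations off, which are the only symmetry-breaking
terms.

**Cohorts** (`cohort_spec()`, `generate_cohort()`, `run_cohort()`).
Controls draw anteverted cups (version 15° ± 3°) with deeper sockets
(depth 98° ± 3°); patients draw retroverted (−12° ± 4°), shallower
(89° ± 4°) cups; head radius 25 ± 1.5 mm; per-subject pelvic tilt and
rotation 0 ± 2°. These distributions reproduce the *direction* of the
group effects (negative posterior wall distance, reduced posterior and
total coverage, universal crossover in patients; none in controls) —
published group magnitudes cannot be reproduced because the underlying
subject-level geometry is not available, and no attempt is made.
Reader noise is applied to landmark coordinates, never to final
measures, so one perturbation propagates coherently into all six; each
named landmark gets its own Gaussian offset (default SD 0.5 mm), and
the two wall traces share a common film-level offset plus a quarter-SD
independent component, reflecting that a reader mislocates the wall
pair far more than the walls relative to each other. Two readers × two
reads is the default; measures are averaged over reader and read before
descriptives and regression, and the crossover ratio is reported as not
quantifiable for a group without any crossover sign.

## Statistical layer

Group comparison uses the pooled-variance two-sample t-test (Welch
available behind a flag but not the default, matching the classical
reporting convention). Reliability uses ICC(2,1) — two-way random
effects, absolute agreement, single measures — computed from the
two-way ANOVA mean squares; the model choice matters (other ICC forms
give different values) and is fixed and documented rather than
configurable. Intra-observer ICCs compare the two reads within each
reader; inter-observer ICCs compare the two readers within each read.
Landis–Koch labels use the bands slight (≤ 0.20), fair (≤ 0.40),
moderate (≤ 0.60), substantial (≤ 0.80), almost perfect (> 0.80).
Regression is ordinary least squares of each coverage outcome on each
averaged 2D measure with pooled groups, reporting Pearson r and the
two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$; significance is read at
0.05 with no multiplicity correction, deliberately mirroring the
single-dataset reporting style the package emulates.

## Numerical choices and degenerate inputs

* Plane splits snap vertices within $10^{-9}$ of a plane onto it;
  face-split conservation is exact by construction.
* The spherical point-in-polygon test nudges the witness by $10^{-9}$
  to avoid exact-degeneracy ties; arcs are assumed minor, which the
  dense rim sampling guarantees.
* Sphere/circle fits reject coplanar/collinear input; constant ratings
  make the ICC undefined (error), and constant x rejects a regression.
* A rim entirely farther than twice the head radius from the mesh fails
  loudly ("wrong bone"), as does a projected rim that self-intersects
  beyond cleanup, a posterior wall that never crosses the head-center
  horizontal, and a cohort with an empty group (warning; comparisons
  skipped).
* Problem sizes used in the validation suite: 11k-vertex spheres for
  the analytic cap checks, 3.5k-vertex femora for the 20-hip
  conservation/oracle sweeps (the oracle uses $10^6$ samples per hip),
  5k/20k for junction stability, and the full 18 + 16 cohort at 5k
  vertices per femur — sizes at which the measured quantities are
  well inside their tolerances while the whole suite stays fast.

## What the validation does and does not show

The synthetic generator produces ideal geometry: exactly spherical
heads (unless a cam bump is requested), noise-free meshes, a congruent
cup, and landmark noise that is Gaussian and entity-coherent. Passing
the validation suite therefore establishes the *correctness of the
algorithms* against analytic and Monte-Carlo ground truth — not
robustness to segmentation artifacts, osteophytes, aspherical heads,
partial rims, or reader error structure in real radiographs. The
measured magnitudes of the synthetic cohort's group differences and
reliability coefficients depend on the generator's parameter
distributions and are not calibrated to any patient series; only their
directions and sign patterns are designed to match the clinical
phenomenon. Pelvis-side coverage angles, CT segmentation, perspective
magnification and cartilage surfaces are out of scope.
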