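---
title: "Measuring articular cartilage thickness from paired surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring articular cartilage thickness from paired surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartscan)
```

## The measurement problem

Articular cartilage thickness on the distal femur can be measured with
very high accuracy from 3D surface models if the same bone is scanned
twice — once with its cartilage layer and once after the cartilage has
been removed — and the two models are brought into a common coordinate
frame. Thickness at a point on the articular (cartilage) surface is then
the *closest-point distance* to the bone surface:

$$ t(p) \;=\; \min_{q \,\in\, S_\text{bone}} \lVert p - q \rVert . $$

Two error sources matter. The *random* error follows from the scanner's
per-scan precision $\sigma$: because the thickness is a difference of two
independent surface measurements,

$$ \sigma_t \;=\; \sqrt{\sigma^2 + \sigma^2} \;=\; \sqrt{2}\,\sigma , $$

so a scanner with $\sigma = 0.087$ mm yields $\sigma_t \approx 0.123$ mm —
about 6% of a typical 2 mm cartilage layer. The *systematic* error (bias)
comes from the cartilage-removal process changing the underlying bone; it
is assessed by comparing before/after models of the bone itself with the
root-mean-square deviation (RMSD) and average deviation (AD) of
point-to-surface distances, judged against the repeatability floor from
repeated segmentations of a single scan. `cartscan` implements the desk
side of this workflow end to end, plus a phantom generator with analytic
ground truth so that every stage can be verified without specimens.

## Pipeline stages and their assumptions

**Fiducial registration.** Spherical fiducial markers rigidly attached to
the bone are visible in both scans. Each marker cloud is fit by least
squares; the geometric (orthogonal-distance) objective
$\sum_i (\lVert p_i - c\rVert - r)^2$ is minimised by Gauss-Newton from an
algebraic (Coope) initialisation. The geometric fit matters because
markers are typically seen from one side only, and the algebraic fit is
biased under partial coverage with noise; on noiseless data both are
exact, which the tests exploit. Marker correspondence uses labels when
present and otherwise an exhaustive match of inter-centre distance
matrices (at 6-8 markers the search is trivial); a near-tie between two
assignments (within 0.05 mm) signals a symmetric layout and is reported
as an error rather than guessed. The rigid transform between scans is the
Kabsch/SVD solution with determinant correction, so reflections can never
be returned. Fiducial-based registration is preferred over shape matching
(e.g. ICP) because the with- and without-cartilage surfaces genuinely
differ — shape matching would absorb part of the cartilage layer into the
alignment. The transform estimated from the marker centres is then
*propagated* to the with-cartilage surface model.

**Anatomical frame.** The standard planes are built from three landmark
regions supplied as inputs (automatic landmark detection is out of
scope): the two posterior condylar patches, the medial tibial plateau
patch, and an anterior (trochlea-side) reference. Spheres are fit to the
posterior condylar patches and the medial-lateral (ML) axis is the line
through their centres — the usual operationalisation of "superimposing
the posterior condyles"; a cylinder fit to the combined patches would be
an alternative, but the sphere route reuses the marker machinery and is
equally resampling-stable, since both rely on least-squares centres. The
axial plane normal is the plateau normal orthogonalised against ML; the
AP axis completes it, oriented anteriorly by the trochlear reference; PD
closes the right-handed triad. Degenerate configurations (condylar patch
residual above 1 mm; plateau normal within 10 degrees of ML) raise
errors instead of producing a silently skewed frame. For a left knee the
ML axis is negated so that the frame stays right-handed with AP anterior
and PD proximal on mirrored anatomy.

**Condylar subregions.** In frame coordinates (x = ML, y = AP, z = PD)
the distal (0&deg; flexion) subregion of each condyle is constructed in
three stages: the weight-bearing strip between the AP level of the
trochlear lowest point and 60% of the distance to the condyle's most
posterior point; the central third of that strip in AP; and a
medio-lateral trim to 15% of the total cartilage width W, centred on the
retained vertices' ML centroid. The posterior (90&deg;) subregion is the
band of the same length centred on the most posterior point in the
proximal-distal direction, restricted to the posterior aspect (AP below
the condylar sphere-centre level), with the same ML trim. Choices the
construction fixes: "lowest point" means the most distal vertex of the
user-supplied trochlear region; distances are straight-line coordinate
distances, not arc lengths; ties at extrema go to the lowest vertex
index; all bounds are closed intervals; the medial/lateral split defaults
to the ML coordinate of the trochlear lowest point. Membership is
evaluated on the cartilage (outer) surface, since the thickness
statistics are taken over cartilage-surface points.

**Thickness and summaries.** Distances are true point-to-surface minima
(faces, edges, vertices), computed by an exact per-triangle scan with a
bounding-sphere rejection test in compiled code — not vertex-to-vertex
distances, which overestimate on coarse meshes. Direction is cartilage
vertex to bone surface; points farther than `max_valid` (default 10 mm)
are flagged invalid and excluded, which guards against cartilage regions
facing unscanned bone. Subregion statistics use the arithmetic mean and
sample (n-1) SD; study tables are reported to 0.1 mm. `summarize_study`
reproduces study-table summaries (column means over specimens, the
overall mean of column means, extreme cells) from per-specimen inputs.
Deviation metrics default to the asymmetric convention (query mesh
vertices against reference surface), with a symmetric pooled variant
available; AD is unsigned by default, with signed deviations available
via face-normal orientation.

## The phantom generator

`make_bicondylar_phantom()` emulates the distal femoral articular
surface: two spherical condylar patches (radius 25 mm, centres 44 mm
apart, swept from 55&deg; anterior of the distal pole to 25&deg; past the
posterior pole, ±40&deg; in ML) joined by a trochlear groove — a
sagittally convex cylinder-like patch whose lowest line carries a slight
ML waist so the trochlear lowest point is unique at the midline. The
cartilage surface is the bone surface offset along the outward normal by
a smooth field $t(\theta) = t_0 + a\cos\theta$; the default $t_0 = 2$ mm
matches the typical distal-femur thickness, with $a = 0$ (constant) as
the baseline condition and $t_0 + |a| \le 4$ mm enforced as a
physiological and curvature-validity bound. On the spherical and
cylindrical patches the offset construction makes the analytic field
equal the closest-point distance exactly, which is what the end-to-end
recovery tests rely on.

Two deliberate idealisation limits are worth knowing. First, in the
trochleo-condylar blend zone the patches interpenetrate (as the real
surfaces merge there); the thickness-equals-distance identity therefore
holds on the condylar regions away from the blend, and all defined
subregions lie in those regions. Second, scan noise is modelled as an
independent Gaussian displacement of each vertex along its outward
normal (per-vertex RMS displacement equal to $\sigma$, default 0.087
mm), which mimics a triangulation scanner's depth error; real scanners
also have spatially correlated error and resolution limits that the
phantom does not emulate, so passing tests demonstrate correctness of
the algorithms, not field performance of a particular scanner.

A consequence of measuring against a *triangulated* noisy surface is
that the foot point usually lands inside a triangle, where the
interpolated vertex noise has less than unit variance, and the minimum
over a rough surface snaps slightly inward. The Monte-Carlo check of the
error model therefore recovers a per-point thickness-error SD a little
below $\sqrt{2}\sigma$ (typically 92-94% of it at the default mesh
resolution), comfortably inside the 15% acceptance band — a useful
reminder that $\sigma_t = \sqrt{2}\sigma$ is an upper-bound model for
surface-interpolated measurements.

**Markers and scans.** `add_markers()` places 3-8 spherical markers
(default 7) on an irregular ring — deliberately asymmetric so
distance-matrix matching has a unique answer — each sampled as a
deterministic Fibonacci lattice. `simulate_two_scans()` produces the
with-cartilage scan in the phantom frame and the without-cartilage scan
in a second frame related by a caller-chosen rigid transform, with
independent noise per scan, fully reproducible from its seed.

## Numerical choices

* Vertex merge tolerance on load: 1e-9 mm; zero-area faces dropped.
* Sphere fits: Gauss-Newton with step halving, step tolerance 1e-10 mm,
  at most 100 iterations; non-convergence is an error, not a warning.
* Rotation angles are extracted with the atan2 form, which is stable
  near zero where the acos form loses half the significant digits.
* FRE above 0.2 mm (about twice a good scanner's per-scan precision)
  emits a configuration-quality warning; it is a tool threshold, not a
  property of the method.
* Problem sizes in the tests and the acceptance script: phantoms at
  2.5 degree (default) or 5 degree (unit-test) angular resolution, 30
  Monte-Carlo replicates for the error-model check, 100 random motions
  for registration exactness, and 1000 queries against a 320-face mesh
  for the closest-point oracle — sizes at which every check is
  comfortably stable and the whole suite runs in seconds.

## Worked example

```{r example}
phantom <- add_markers(make_bicondylar_phantom(t0 = 2, a = 0), n_markers = 7)
move <- rigid_transform(
  rbind(c(cos(0.6), -sin(0.6), 0), c(sin(0.6), cos(0.6), 0), c(0, 0, 1)),
  c(8, -4, 11))
scans <- simulate_two_scans(phantom, sigma = 0.087,
                            inter_scan_transform = move, seed = 1)
aligned <- align_scans(scans$scan_with, scans$scan_without)
aligned$registration$fre_rms

study <- measure_condyle_thickness(aligned$cartilage, aligned$bone,
                                   phantom$patches)
study
```

The four subregion means recover the 2 mm truth; with per-scan noise of
0.087 mm the per-point scatter follows the $\sqrt{2}\sigma$ model
discussed above.

```{r precision}
propagate_precision(0.087, reference_thickness = 2)
```

## Known limitations

* Landmark patches (posterior condyles, trochlea, medial plateau) are
  inputs; no automatic detection is attempted.
* The trochlear and tibial articular surfaces get no subregions of their
  own; the tibial side enters only through the plateau plane.
* Mesh repair (hole filling, decimation, smoothing) is out of scope; the
  loaders only merge duplicate vertices and drop degenerate faces.
* ICP/shape-matching registration is intentionally absent from the core
  pipeline (see above); only fiducial registration is provided.
* The phantom's noise model is uncorrelated between vertices; it
  reproduces the precision arithmetic but not scanner-specific artefacts
  such as speckle, edge flare, or registration-free multi-sweep fusion.
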