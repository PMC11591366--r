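# cartscan

Articular cartilage thickness from paired 3D surface scans of a bone —
one scan **with** the cartilage layer and one **without** it.

Measuring cartilage thickness from surface scans offers very high
accuracy, but only if the two models are aligned without borrowing
information from the surfaces being compared, and only if the removal
process left the bone unchanged. `cartscan` implements the desk side of
that workflow for the distal femur:

* **Fiducial registration** — least-squares sphere fits to marker
  clouds (algebraic initialisation, geometric Gauss–Newton refinement),
  exhaustive distance-matrix marker matching, and the Kabsch/SVD rigid
  transform with determinant correction (reflections are impossible).
  The transform estimated on the marker centres is propagated to the
  with-cartilage model.
* **Anatomical frame** — the standard sagittal/axial/coronal planes
  from landmark patches: the medial–lateral axis joins the centres of
  spheres fit to the posterior condyles; the axial normal is the medial
  tibial plateau normal orthogonalised against it.
* **Condylar subregions** — the distal (0° flexion) and posterior
  (90° flexion) subregions of each condyle from the 60% weight-bearing
  rule, the central AP third, and the 15%-of-width medio-lateral trim.
* **Closest-point thickness** — per-point cartilage thickness as the
  exact point-to-surface distance (faces, edges, vertices — not vertex
  to vertex), with per-subregion mean and SD:

  $$t(p) = \min_{q \in S_\text{bone}} \lVert p - q\rVert,\qquad
    \sigma_t = \sqrt{\sigma^2 + \sigma^2} = \sqrt2\,\sigma$$

  where σ is the per-scan precision (σ = 0.087 mm gives
  σ_t ≈ 0.123 mm, about 6% of a 2 mm cartilage layer).
* **Bias assessment** — RMSD / average-deviation comparison of repeated
  bone models, including the n·(n−1)/2 pairwise repeatability design.
* **Ground-truth phantoms** — a bicondylar distal-femur phantom with
  analytic thickness field, spherical fiducials, and seeded per-scan
  surface noise, so every stage is testable without specimens.

Mesh I/O covers PLY (ASCII + binary little-endian), STL (ASCII +
binary), and OBJ, all in millimetres. A thin command-line driver lives
at `inst/cli/cartscan.R` (`phantom`, `register`, `thickness`,
`summarize`, `deviation`).

## Worked example

A constant 2 mm cartilage layer on a bicondylar phantom, scanned twice
with 0.087 mm noise and an unknown repositioning between scans:

```r
library(cartscan)

phantom <- add_markers(make_bicondylar_phantom(t0 = 2, a = 0), n_markers = 7)
move <- rigid_transform(
  rbind(c(cos(0.6), -sin(0.6), 0), c(sin(0.6), cos(0.6), 0), c(0, 0, 1)),
  c(8, -4, 11))
scans <- simulate_two_scans(phantom, sigma = 0.087,
                            inter_scan_transform = move, seed = 1)

aligned <- align_scans(scans$scan_with, scans$scan_without)
aligned$registration
#> registration over 7 fiducials: FRE 0.02091 mm
#> rigid_transform: rotation 34.372 deg, translation (7.997, -4.005, 11.009) mm

measure_condyle_thickness(aligned$cartilage, aligned$bone, phantom$patches)
#> thickness_study (mm):
#>   medial  0deg   2.0 (0.1)  n = 77
#>   medial  90deg  2.0 (0.1)  n = 77
#>   lateral 0deg   2.0 (0.1)  n = 77
#>   lateral 90deg  2.0 (0.1)  n = 77
```

The registration recovers the 34.4° repositioning with a fiducial
registration error of 0.02 mm, and all four subregion means recover the
2 mm truth; the per-point SD of 0.1 mm reflects the √2 · 0.087 mm
two-scan error model:

```r
propagate_precision(0.087, reference_thickness = 2)
#> precision_model: sigma_scan 0.087 mm -> sigma_thickness 0.123 mm
#>   relative error vs 2.00 mm reference: 6.2%
```

Study-level summaries aggregate per-specimen subregion means; a
three-specimen example table ships with the package:

```r
tab <- read.csv(system.file("extdata", "example_study_thickness.csv",
                            package = "cartscan"))
summarize_study(tab)
#> study summary (mm, rounded to 0.1):
#>   column means: medial 0deg 1.9 | lateral 0deg 2.1 | medial 90deg 1.6 | lateral 90deg 2.1
#>   overall mean of column means: 1.9
#>   thinnest cell: 1.2 (Specimen 3, medial, 90deg)
#>   thickest cell: 2.8 (Specimen 3, lateral, 0deg)
```

See `vignettes/cartilage-thickness-methods.Rmd` for the model, the
phantom's assumptions, and the numerical choices.

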