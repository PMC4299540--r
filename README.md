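# tumorloc

Automated estimation of lung tumor locations in megavoltage cone-beam CT
(MV-CBCT) verification images, for tumor-based patient positioning in
stereotactic body radiotherapy (SBRT).

Clinics typically position SBRT patients in two steps: bone-based alignment,
then a manual, subjective shift that brings the tumor in the verification
image onto its planned position. `tumorloc` automates the second step: it
locates the tumor in the MV-CBCT by matching a tumor template taken from the
planning CT, and reports the tumor centroid so the couch correction can be
computed directly.

## Method

For each treatment fraction:

1. CT and MV-CBCT are resampled to 1 mm isotropic grids (Keys tricubic), and
   to 5 mm (trilinear) for a coarse step; the MV-CBCT is median-filtered
   (3×3×3) and edge-enhanced (unsharp masking with a Laplacian-of-Gaussian,
   σ = 0.7 px).
2. A translation-only rigid registration aligns CT and CBCT at 5 mm by
   exhaustively maximizing the normalized cross-correlation

   `C(x,y,z) = (1/LMN) Σᵢⱼₖ (t(i,j,k) − t̄)(f(x+i, y+j, z+k) − f̄) / (σ_t σ_f)`

   over all integer offsets with ranges `R_x = X − L`, `R_y = Y − M`,
   `R_z = Z − N`.
3. The planning gross tumor volume (GTV) is mapped into the CBCT and its
   circumscribing cuboid, dilated by 20 voxels, becomes the search region.
4. A tumor template — the GTV cuboid cropped from the raw 1 mm planning
   CT — is optionally enhanced with a 3×3×3 Sobel gradient magnitude or a
   blob-structure-enhancement (BSE) filter built on the eigenvalues
   λ₁ ≥ λ₂ ≥ λ₃ of the Gaussian-scale Hessian:

   `F = |λ₃| (λ₂/λ₃)^γ (λ₁/λ₂)^γ  if λ₃ ≤ λ₂ ≤ λ₁ < 0, else 0`

   with σ = d/4 (d the GTV effective diameter, `d = 2 (3V/4π)^{1/3}`) and
   γ = 1. The filter enhances bright spheres and suppresses plates (vessel
   walls, chest wall) and tubes (vessels).
5. The template is matched exhaustively by NCC inside the search region (the
   region is enhanced the same way), the GTV is placed at the argmax,
   binarized by Otsu's threshold computed inside the placed GTV, and the
   binarized region's centroid is the estimated tumor location.

Because no imaging data can ship with the package, a digital thorax phantom
(`make_phantom_ct`) and an MV-CBCT degradation model (`degrade_to_cbct`:
contrast scaling, known rigid shift, blur, seeded noise) provide fully
ground-truthed test data, including a ten-case clinical-like series whose
tumor diameters (5.38–14.35 mm, mean 10.43 mm) follow the published patient
table.

## Worked example

```r
library(tumorloc)

ph <- make_phantom_ct(phantom_spec())     # 3 tumors: apex/bifurcation/base
g  <- ph$gtvs$apex
dg <- degrade_to_cbct(ph$ct, degradation_spec(
        isocenter_mm = g$isocenter_mm, seed = 11))   # shift (4,-3,6) mm

ct5   <- resample_isotropic(ph$ct,    5, method = "trilinear")
cbct5 <- resample_isotropic(dg$cbct, 5, method = "trilinear")
tr <- register_translation(ct5, cbct5)
tr
#> <translation_result> offset (3, 8, 19) vox = (15, 40, 95) mm, NCC 0.9400

loc <- localize(ph$ct, dg$cbct, g, tr, default_config())  # mode = "bse"
loc
#> <localization_result> mode bse: centroid (84.28, 96.62, 171.20) mm, NCC 0.9665

truth <- ph$truth["apex", ] + dg$applied_shift_mm    # (84.3, 96.6, 171.2)
sqrt(sum((loc$centroid_mm - truth)^2))
#> [1] 0.0277947
```

The estimated centroid lands 0.03 mm from the ground-truth tumor position.
`run_all(list(dataset = "phantom"))` repeats this for all three stations and
all template modes and returns the location-error records and per-mode
summaries; `run_all(list(dataset = "clinical"))` runs the ten-case × four-
fraction series.

A command-line interface wrapping these functions (subcommands `simulate`,
`register`, `localize`, `evaluate`, `run-all`) is installed at
`system.file("cli", "tumorloc.R", package = "tumorloc")`.

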