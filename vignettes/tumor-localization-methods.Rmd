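---
title: "Automated lung tumor localization in MV-CBCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lung tumor localization in MV-CBCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In stereotactic body radiotherapy (SBRT) of lung tumors, the patient is
positioned on the treatment couch using a verification image — here a
megavoltage cone-beam CT (MV-CBCT) — acquired just before each fraction.
Bone-based alignment leaves residual tumor misalignment, so clinics refine
the setup by manually aligning the tumor itself, which is subjective and
slow. `tumorloc` implements an automated alternative: estimate the tumor
location in the MV-CBCT by matching a tumor template extracted from the
planning CT, and report its centroid for couch correction.

## The pipeline

For one fraction the pipeline runs these stages, each an exported function:

1. **Isotropic resampling** (`resample_isotropic`). CT and CBCT are brought
   to 1.0 mm isotropic grids with Keys tricubic convolution (a = -0.5), and
   additionally to 5.0 mm with trilinear interpolation for the coarse
   registration. Edge handling is clamping; the output grid keeps the input
   origin and covers its extent to within one output voxel.
2. **Preprocessing** (`preprocess_cbct`). The MV-CBCT is median-filtered
   (3×3×3) and edge-enhanced. See "Edge enhancement" below.
3. **Coarse rigid registration** (`register_translation`). Exhaustive
   translation-only search on the 5 mm grids: the normalized
   cross-correlation (NCC)

   C = (1/LMN) Σ (t - t̄)(f - f̄) / (σ_t σ_f)

   is evaluated at every integer offset with nonnegative search ranges
   X-L, Y-M, Z-N (the CBCT is smaller than the CT on every axis, enforced as
   a precondition), and the argmax taken. Intensities are not harmonized
   between HU and MV-CBCT units: NCC's normalization absorbs any affine
   mismatch. Ties are broken by the smallest offset in lexicographic
   (z, y, x) order — the choice is arbitrary but fixed, making results
   reproducible.
4. **Search region** (`map_gtv_to_cbct`, `build_search_region`). The
   planning GTV is translated into CBCT index space by the registration
   offset, and its circumscribing cuboid dilated by 20 voxels per face
   (equivalent to 20 iterations of 26-neighbor dilation for a cuboid),
   clipped to the image. The dilation absorbs the 5 mm quantization of the
   coarse offset plus residual motion.
5. **Template extraction and enhancement** (`extract_template`, `sobel3d`,
   `bse_filter`). The GTV cuboid is cropped from the *raw 1 mm planning CT*
   and, depending on the mode, left as raw intensities (`none`), replaced by
   the 3×3×3 Sobel gradient magnitude (`sobel`), or by the
   blob-structure-enhancement response (`bse`). Filters run on a crop padded
   by the filter support and are trimmed back, so template voxels equal
   whole-image filtering.
6. **Template matching** (`match_template`). Exhaustive NCC of the template
   over every 1 mm placement inside the search region of the preprocessed
   (and, for `sobel`/`bse`, identically enhancement-filtered) CBCT.
7. **Binarization and centroid** (`binarize_gtv`, `centroid`). The GTV mask
   is placed at the matched location; an Otsu threshold computed from the
   CBCT intensities *inside the placed mask* (256 bins over that set's
   min–max) selects the tumor voxels, and their mean world coordinate is
   the reported location.

`localize()` composes stages 4–7; `run_all()` drives whole experiments.

## The blob-structure-enhancement filter

The BSE filter responds to bright sphere-like structures. At each voxel the
Hessian of the Gaussian-smoothed image at scale σ is assembled from the six
distinct second Gaussian-derivative responses (separable convolutions with
analytically differentiated kernels, truncated at 4σ, with discrete moment
corrections making them exact on quadratics) and its eigenvalues are sorted
λ1 ≥ λ2 ≥ λ3. The response is

F = |λ3| (λ2/λ3)^γ (λ1/λ2)^γ  if λ3 ≤ λ2 ≤ λ1 < 0, else 0.

For a bright blob all eigenvalues are negative and of similar magnitude, so
F is large; for plates and tubes the leading eigenvalue is near zero and the
ratio weights suppress the response. At γ = 1 the product telescopes to
|λ1|, which the tests assert voxelwise. Two printed-form ambiguities were
resolved as follows: the Hessian is implemented as the full symmetric matrix
(a repeated entry in the source's matrix layout is a typographical slip, as
a Hessian is symmetric), and the weight function is ψ(λs, λt) = (λs/λt)^γ
for λt ≤ λs < 0, the ratio-in-[0,1] form of the blob-enhancement literature
(the printed inequality would zero the weight almost everywhere, which
contradicts its stated purpose). We emit the absolute value so the map is a
bright-blob enhancement; NCC is invariant to a consistent sign.

The scale is σ = d/4 where d = 2 (3 V_GTV / 4π)^(1/3) is the effective
diameter of the planning GTV, and γ = 1; both template and search region are
filtered with the same parameters.

## Edge enhancement: a deliberate deviation

The preprocessing chain is described in the source material as a median
filter followed by a Laplacian-of-Gaussian (LoG, σ = 0.7 voxels) "edge
enhancement", and its illustrations show an enhanced image that still looks
like a CT. A raw LoG response map cannot be that image: in a raw Laplacian
map a bright tumor becomes a dark-cored ring, raw-intensity template
matching flips sign, and the bright-blob condition of the BSE filter fails
at the tumor. All downstream stages require the tumor to remain a bright
blob. `preprocess_cbct` therefore interprets the edge enhancement as
unsharp masking, `m − LoG(m)`, which sharpens edges while preserving the
intensity scale — consistent with every downstream stage and with the
appearance of the published figures. `log_filter()` itself returns the raw
LoG response (negative in bright cores, zero on constants and ramps), and
`edge_mode = "log"` restores the literal reading for sensitivity checks;
`edge_mode = "none"` stops after the median filter.

Whether the BSE filter should see the sharpened image or only the
median-filtered one was genuinely open; a sensitivity run on the two
smallest-tumor clinical-like cases (4 fractions each, both inputs) favored
the sharpened input — partial deconvolution of the CBCT blur restores the
small tumors' blob response relative to noise — so the sharpened volume is
the single matching input for all modes.

## The digital phantom and degradation model

No imaging data ships with the package; `make_phantom_ct()` builds a digital
stand-in for a thorax phantom: an elliptical soft-tissue body (+40 HU) in
air, two ellipsoidal lung fields at −900 HU, and anti-aliased spherical
tumors at −630 HU (+270 HU contrast), rasterized with 3³ voxel-center
supersampling to reduce quantization bias. The default layout places three
10 mm spheres at the apex, tracheal-bifurcation level and base stations.
The grid is 220×200×240 voxels at 1 mm — sized so that a 128 mm cubic CBCT
field of view centered on any station stays inside the CT; 128 mm (rather
than a clinical 274 mm) is the package's desk-scale working size, and the
field of view is a config value.

`degrade_to_cbct()` emulates MV-CBCT character: contrast scaling about the
lung baseline (default 0.6), a known rigid translation of the anatomy
(tricubic), Gaussian blur (default FWHM 3 mm), and seeded additive Gaussian
noise (default SD 30), cropped to the field of view centered on the
isocenter. These degradation numbers are surrogates — the source reports no
quantitative MV-CBCT noise or blur — chosen so the Sobel mode visibly
degrades while the BSE mode still succeeds. The applied shift is recorded
exactly, so ground truth needs no observer.

`make_clinical_like_cases()` generates ten single-tumor cases whose
effective diameters cycle through the published clinical table (5.38–14.35
mm, mean 10.43 mm), stationed 5 upper / 2 middle / 3 lower across both
lungs, each with four CBCT fractions at continuous uniform shifts in
±6 mm per axis (interfractional setup error of a few millimeters with
sub-voxel components; the ±6 mm range is our choice). Two tumors are
wall-adjacent, mirroring the clinical description "close to or attached to
the lung wall": the 14.35 mm tumor attached to the mediastinal lung
boundary, the 5.38 mm tumor 3 mm from it. The attached/close-to mix follows
that wording, and the small tumor is deliberately the *close-to* one — see
the limitation below.

## Numerical choices

- Voxel indices are 0-based with half-open bounding boxes; world
  coordinates are voxel centers, `origin + index × spacing`, with x
  left→right, y anterior→posterior, z inferior→superior.
- NCC uses population standard deviations over the full overlap; windows
  with zero variance receive a sentinel below −1 and can never win the
  argmax; an all-degenerate map raises an error rather than returning NaN.
- Otsu binarization uses 256 bins over the masked set's min–max and keeps
  voxels at or **≥** the maximizing bin edge; a constant set or empty
  foreground falls back to the full mask with a warning.
- The contour dialect voxelizes polygons by the even-odd rule on voxel
  centers (multiple loops on one slice XOR, so nested loops cut holes).
  How the original treatment-planning system voxelized contours is unknown;
  this is our choice.
- Sub-voxel localization is not attempted: matching is on the 1 mm grid and
  the centroid of the binarized region supplies sub-voxel output naturally.
- Seeds: experiment drivers derive per-fraction noise seeds from the master
  seed by a fixed affine scheme, so any fraction can be regenerated in
  isolation.

## Problem sizes

The standard experiments are desk-scale by design: the phantom study runs
three stations (one fraction each) and the clinical-like study 10 cases × 4
fractions, both with 128³ CBCT volumes, a 220×200×240 CT, 5 mm exhaustive
registration and 1 mm exhaustive template matching. One fraction end to end
takes a few seconds per mode on a single core.

## What the simulator does and does not show

Ground truth is exact by construction, so location errors are well defined
without observers. The degradation model reproduces blur, noise, reduced
contrast and rigid motion, but **not** scatter-induced shading or cupping,
ring artifacts, respiratory motion, or tumor deformation. This matters when
interpreting mode comparisons: raw-intensity matching (`mode = "none"`)
against our sharpened, shading-free CBCT is more reliable than it is against
real MV-CBCT, where low-frequency scatter artifacts are a principal cause of
raw-NCC failure while Hessian-based enhancement is largely immune to them.
A passing phantom test therefore demonstrates the pipeline's correctness and
the BSE mode's robustness margin, not a clinical effect size for the
original-template mode.

Known limitations:

- **Juxtapleural small tumors.** A sphere of ≲5 mm diameter *attached* to
  the high-contrast lung boundary has no blob response at σ = d/4: the
  wall's positive second derivative exceeds the tumor's negative curvature
  throughout the sphere, for any blur level, so the BSE condition
  λ1 < 0 never holds there. This is an intrinsic property of
  single-scale Hessian blob enhancement (well known for juxtapleural nodule
  detection). The clinical-like generator therefore attaches only the large
  wall case; localizing small attached tumors would need a wall-suppression
  step outside this package's scope.
- Small templates (≈5³ voxels for the smallest diameters) make NCC
  susceptible to spurious blob-shaped noise matches, since NCC is
  amplitude-invariant; occasional multi-millimeter outliers at the smallest
  diameters are expected at the default noise level.
- Only axis-aligned volumes and translation-only registration are
  supported; rotational setup error is out of scope.
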