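---
title: "From CT volume to printable mandible models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT volume to printable mandible models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mandibular reconstruction after tumour resection is planned on
patient-specific anatomical models and surgical templates derived from head
CT. The digital chain that produces those models decides whether the
printed parts fit: routine head CT is anisotropic (in-plane ~0.4 mm,
reconstructed slice width ~1.5 mm), the partial-volume effect blurs bone
margins, post-operative scans carry metal noise from titanium plates, and
every processing step between the DICOM series and the STL file can add
shape error. `osteoplan` implements that chain — noise filtering, isotropic
resampling, threshold/region-growing segmentation with resection curves,
isosurface meshing, mirror-based template design, resected-volume
estimation, and best-fit deviation QC — with every stage testable against a
synthetic phantom whose geometry is known analytically.

## Data model

A `VoxelVolume` is a 3-D grid of Hounsfield units with spacing, origin and
an orthonormal direction matrix in the DICOM-native LPS patient frame;
values are samples at voxel centers and indices are 0-based, so
`world = origin + direction %*% (i*sx, j*sy, k*sz)`. All meshes
(`TriMesh`), plans (`ResectionPlan`) and QC reports live in the same frame,
which avoids any conversion layer between slices and surfaces. Slice
spacing is always derived from inter-slice positions rather than the
SliceThickness tag, because acquired and reconstructed slice widths differ
on clinical scanners.

## Image conditioning

**Minimum filter.** Post-operative scans show bright streak/salt noise near
the fixation plate. The conditioning step is a true rank filter: each pixel
is replaced by the minimum over a `window x window` neighbourhood within
its 2-D slice (default 3x3). A minimum filter is not a convolution — it is
monotone, contractive (output <= input) and idempotent on constants — and
is applied per slice because the noise is an in-plane reconstruction
artifact. The window size is configurable; 3 is the default because larger
windows visibly erode thin cortical bone at 0.4 mm pixels.

**Lanczos resampling.** Segmentation and meshing run on an isotropic grid
(default 0.4 x 0.4 x 0.4 mm) produced by separable a-lobed Lanczos
windowed-sinc interpolation (a = 3 by default; 2 and 4 are available). Per
sample, the 2a taps along each axis are renormalized to sum to one, so
constant regions are reproduced exactly and no DC shift is introduced.
Edges clamp to the border voxel: introducing synthetic air at the border
would corrupt threshold segmentation near the field-of-view edge. The
output grid keeps the input origin and covers the input bounding box; the
negative side lobes of the kernel may overshoot near metal edges, which is
accepted because segmentation uses thresholds, not extrema.

## Segmentation

Bone is selected by `HU >= 200` (the averaged adult operating point for
mandibular cortical bone); in post-operative mode an upper threshold
(default 1700 HU) additionally separates bone from titanium. Resection
curves — closed polylines drawn on slices and swept over a patient-mm range
along the slice axis — and cutting planes partition the mask into resected
and retained bone; membership is by voxel center with the even-odd rule,
boundary inclusive, so complementary `keep` modes partition the mask
exactly. Seeded region growing (26-connectivity by default, to keep thin
cortical shells connected) then retains the components connected to the
seeds; without seeds the pipeline keeps the largest component.

Two properties of this stage are worth stating because they are visible in
the tests. First, thresholding a partial-volume-blurred image at 200 HU
places the implied boundary *outside* the true bone surface: with a
Gaussian ramp of width sigma between soft tissue (~40 HU) and bone
(~1200 HU), the 200 HU level sits at about `1.09 * sigma` (~0.44 mm at
sigma = 0.4 mm) outside the anatomical interface. Second, dual thresholding
alone cannot remove a metal object entirely: the blurred shell of the plate
re-enters the [200, 1700] band (about 9% of plate voxels on the phantom),
and it is the region-growing step that discards this disconnected shell.
Both effects are inherent to threshold segmentation, not implementation
artifacts.

## Isosurface extraction

Surfaces are extracted from the HU field (not the binary mask) at an
iso-value, with vertices placed by linear interpolation along cell edges —
this is what removes the stair-step artifact of voxel-resolution surfaces
and avoids any post-hoc smoothing or repair. Each lattice cube is
decomposed into the six Freudenthal tetrahedra sharing the main diagonal; a
tetrahedral decomposition has no ambiguous configurations and is
translation-compatible across the lattice, so crossing points on shared
edges are computed bit-identically from both sides and the welded surface
is watertight and consistently oriented by construction (higher HU =
inside, outward normals). The volume is padded by one air voxel so surfaces
close at the border, and extraction can be restricted to the cubes touching
the (dilated) segmented component.

The pipeline default iso equals the lower threshold (200 HU), matching how
threshold-driven clinical software behaves; accuracy experiments that
compare against analytic ground truth extract at the mid-HU level instead,
where the symmetric partial-volume ramp is unbiased (see the round-trip
section). Both choices are exposed through `isoHU`.

## Template design and model set

The reconstruction template mirrors the healthy hemi-mandible across the
sagittal plane (default: the YZ plane through the segmentation's center of
mass, overridable). Reflection is exact (`v' = v - 2((v-p).n)n`, winding
reversed), and the healthy-half/mirror union is evaluated as a level set on
a plane-aligned grid: the signed distance of the input mesh is sampled on a
grid symmetric about the plane (exact ray-parity sign, exact distances in a
narrow band), the pathological half of the field is replaced by its
mirrored counterpart, and the zero level is re-extracted. This voxel-based
boolean is robust on anatomical meshes where exact geometric booleans
routinely fail; its geometric error is bounded by the boolean voxel size
(0.2 mm by default) and is confined to the seam region.

Resection sites are marked as V-grooves (default 0.6 mm deep, 0.8 mm wide —
dimensions chosen to survive 0.15 mm print layers) engraved along the
surface trace of each cutting plane/curve by subtracting a swept wedge in
the same level-set representation.

`makeModelSet()` assembles the four print models: A, the mandible with
grooves; B, the template; C, the plan-bounded resected region, whose mesh
is the zero level of `min(HU - iso, plan field)` so the cut faces are
closed planar caps; and D, the resection-volume reference solid (the same
solid as C, reported with its metrics). The volume of C is the
resected-bone estimate used to size the fibula graft.

## Accuracy verification

`bestFitAlign()` is an iterative-closest-point rigid registration: the
moving mesh is sampled uniformly by area, samples are matched to exact
closest points on the fixed surface through a uniform-grid index, and the
per-iteration rigid update minimizes the point-to-plane residual (the
distances projected on the nominal surface normals), with a Kabsch
point-to-point step as a degenerate-case fallback. The point-to-plane
update was chosen because it converges quadratically near the optimum —
with a pure point-to-point update the iteration stalls at its linear rate
before the pose is recovered to the 0.1 degree / 0.01 mm level — and it is
the minimizer industrial inspection best-fits use. Iterations stop when the
RMS change between successive iterations falls below 0.001 mm (the stated
accuracy of the inspection software this mirrors, read as a convergence
tolerance), with an error raised if the RMS rises for ten consecutive
iterations. The initial pose is picked from identity, centroid-matching and
principal-axes candidates by lowest starting RMS; principal axes alone are
ambiguous in sign and useless on near-symmetric parts, which is why the
candidates are raced instead of trusted.

`deviationMap()` samples the aligned measured surface (4 samples/mm^2 by
default) and reports signed point-to-surface distances — positive outside,
by the angle-weighted pseudonormal at the closest point, which gives the
correct sign on edges and vertices — with min/max/mean/RMS/p95 statistics
and the fraction within the tolerance band (default +/- 0.15 mm, the shape
tolerance the printed models are held to; re-checkable at the +/- 0.25 mm
clinical planning bound with `toleranceCheck()`).

## The synthetic phantom

`PhantomSpec()` describes a mandible-like solid — a tube swept along a
parabolic body arc (default 90 x 55 mm, 5 mm radius), two rami capsules
with condylar sphere caps — with soft tissue at 40 HU, cortical bone at
1200 HU and an optional 30 x 1.5 x 10 mm fixation plate at 3000 HU standing
1.5 mm off the chin (adjacent but not blurred into the bone, so the
dual-threshold separation is observable; a plate in bony contact cannot be
separated by thresholds alone). Partial volume is modelled by evaluating
the Gaussian CDF of the analytic signed distance (`pnorm(-sdf/sigma)`,
sigma = 0.4 mm by default, one in-plane voxel), which is exactly the
Gaussian-blurred step for a locally planar interface; metal artifact is
modelled as 2% salt noise within 3 mm of the plate plus additive Gaussian
HU noise (10 HU), all under a fixed seed. The default grid is the clinical
0.4 x 0.4 x 1.5 mm anisotropic CT grid.

What the phantom does *not* emulate: teeth and trabecular texture,
beam-hardening/streak physics (the salt model only exercises the minimum
filter's purpose), gantry tilt, and scanner-specific PSFs. Passing tests
therefore demonstrate the correctness and internal accuracy of the digital
chain, not clinical segmentation performance on real anatomy.

Ground truth is extracted from the analytic zero level set, by default at
0.1 mm (`gtResolution`); the chord error of that surface (~h^2/8r) is below
a micron for the default radii, negligible against the 0.15 mm band. Test
fixtures use a scaled-down phantom (40 mm arc) and 0.2-0.25 mm ground
truth; the acceptance experiment uses a 60 mm body with a 10 mm sphere at
0.15 mm ground truth. These sizes keep the whole suite in the minutes
range; the measured deviations are insensitive to them.

## The digital round trip

`digitalRoundTrip()` is the accuracy experiment the package reports:
voxelize a ground-truth surface with the partial-volume ramp at 0.4 mm
isotropic spacing and zero noise, segment at 200 HU, keep the connected
component, extract the isosurface at the mid-HU level, best-fit align to
the ground truth, and read off the signed deviation map. The mid-HU iso is
used because the half-maximum level of a symmetric ramp estimates the true
interface without bias, so the experiment measures the chain's error rather
than the known threshold offset; extraction at 200 HU would measure the
~0.44 mm dilation discussed above, which is a property of threshold
segmentation, not of the implementation. On the sphere-plus-body phantom
the maximum absolute deviation is ~0.12 mm, within the +/- 0.15 mm band;
the residual concentrates at the sphere-tube blend crease, where the
locally-planar assumption behind the ramp is weakest.

## Numerical choices and degenerate inputs

- Vertex welding quantizes at 1e-9 of a voxel (bit-identical shared-edge
  crossings make this safe); STL reading deduplicates at 1e-6 mm.
- Boundary ties: voxel centers exactly on a plan plane or curve count as
  inside; iso-values equal to a corner value classify the corner as
  outside (`> iso` is inside).
- Ray-parity voxelization offsets the ray lattice by 1e-4 voxel to dodge
  edge-exact hits; the offset is orders of magnitude below any reported
  tolerance.
- Degenerate inputs error early and specifically: single-slice series,
  non-uniform slice steps (the offending gap is named), missing rescale
  tags, even filter windows, inverted thresholds, empty masks and empty
  plans, open polylines, self-intersecting curves, zero plane normals,
  non-watertight meshes where solids are required, truncated STL files.
- The print-cost estimator is a cost *structure* (volume x infill +
  0.8 mm shell allowance, linear rates; PLA density 1.24 g/cm^3, 0.15 mm
  layers kept as a parameter), not a price oracle: absolute figures depend
  on local prices and machine depreciation, so none are asserted.
- The CLI (`inst/cli/osteoplan.R`) and `scripts/acceptance.R` are thin
  wrappers over the exported functions; everything they do is available,
  and tested, at the R level.

## Known limitations

Non-identity direction matrices (gantry tilt) are supported by the
coordinate model but untested against clinical data. Resection curves are
applied in the patient axes of the curve's slice plane; strongly oblique
volumes should supply cutting planes instead. Region growing is binary
(mask connectivity); a grey-tolerance mode would be the natural extension.
Template booleans assume the symmetry plane roughly matches the scanner
pose, as the mirroring procedure itself does.
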