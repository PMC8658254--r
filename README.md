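# osteoplan

Digital chain for patient-specific mandibular reconstruction planning:
from a CT volume in Hounsfield units to printable anatomical models,
mirror-based surgical templates, a resected-bone volume estimate, and a
quantitative accuracy report. It is written for surgeons' engineering
support teams and medical-image-analysis researchers who need the whole
chain — not a viewer, not a slicer — as scriptable, testable R functions.

## What it does

Routine head CT is anisotropic (about 0.4 × 0.4 × 1.5 mm voxels); the
partial-volume effect blurs bone margins, and post-operative scans carry
metal noise from titanium fixation plates. The package implements the
processing chain that turns such a scan into print-ready geometry:

1. **DICOM I/O** — reads a CT series into a `VoxelVolume` (HU = slope ·
   stored + intercept, slice spacing from inter-slice positions, LPS
   patient frame); writes one back for phantom data.
2. **Conditioning** — a per-slice rank **minimum filter** (window *w*,
   default 3) suppresses bright metal noise; **Lanczos resampling**
   (separable a-lobed windowed sinc, a = 3, per-sample weights normalized
   to Σw = 1) interpolates to isotropic 0.4 mm voxels.
3. **Segmentation** — bone by thresholds (HU ≥ 200; post-operatively also
   HU ≤ 1700 to separate titanium), optional resection curves/planes, then
   seeded region growing under 6/26-connectivity.
4. **Meshing** — marching-cubes-family isosurface extraction on the HU
   field with linear edge interpolation (watertight by tetrahedral cube
   decomposition); mesh volume *V* = ⅙ Σ det(v₁ v₂ v₃) by the divergence
   theorem; binary STL in/out.
5. **Template CAD** — mirror of the healthy hemi-mandible across the
   sagittal plane, v′ = v − 2((v−p)·n)n, united with the healthy half as a
   level-set boolean; V-groove marks at the planned osteotomies; the model
   set A (mandible), B (template), C (resected region, whose volume is
   V_resect), D (volume reference).
6. **QC** — best-fit rigid alignment (ICP with closest-point
   correspondences, point-to-plane updates, 0.001 mm convergence
   tolerance) and signed deviation maps, min/max/mean/RMS/p95 and the
   fraction within a ±0.15 mm tolerance band (re-checkable at ±0.25 mm).

A synthetic **phantom** module generates mandible-like CT volumes (soft
tissue ≈ 40 HU, bone ≈ 1200 HU, metal ≈ 3000 HU, Gaussian-CDF
partial-volume ramp, seeded noise) with analytic ground-truth surfaces, so
every stage is testable without patient data.

## Worked example

The digital round trip measures the accuracy of the chain itself:
an analytic surface is voxelized with a partial-volume ramp at 0.4 mm,
segmented, re-meshed, aligned, and compared against where it started.

```r
library(osteoplan)

gt  <- sphereBodyPhantom(arcWidth = 40, arcDepth = 20, resolution = 0.2)
meshMetrics(gt)
#> MeshMetrics: volume 6445.06 mm^3, area 2364.28 mm^2, watertight, 1 component(s)

rep <- digitalRoundTrip(gt)      # voxelize -> segment -> extract -> best fit
rep
#> DeviationReport: 9463 samples, tolerance +/- 0.15 mm
#>   min -0.0253  max 0.1112  mean -0.0030  rms 0.0072  p95|d| 0.0124 mm
#>   100.00% of samples within tolerance

toleranceCheck(rep, 0.15)$pass
#> TRUE
```

The maximum absolute deviation (0.11 mm here) is the figure held against
the ±0.15 mm shape tolerance for printed surgical models; the mean and RMS
show the chain is essentially unbiased away from surface creases.

The full pipeline runs from a DICOM directory:

```r
spec  <- PhantomSpec(seed = 1)                    # or a real CT series
files <- writePhantomDataset(spec, "phantom")
cfg   <- pipelineConfig(input = files$dicom, outputDir = "run",
                        plan = readResectionPlan("plan.json"))
manifest <- runPipeline(cfg)                      # model_A..D.stl + manifest
manifest$vResect                                  # resected volume, mm^3
```

A thin command-line wrapper with `plan`, `qc`, `phantom` and `cost`
subcommands is installed at `inst/cli/osteoplan.R`.

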