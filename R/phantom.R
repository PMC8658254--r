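#' Construct a phantom specification
#'
#' Defaults describe a life-size mandible-like structure imaged under a
#' routine head-CT regime: a 90 x 55 mm parabolic body arc of 5 mm tube
#' radius with 40 mm rami and condylar caps, cortical-bone HU 1200 in 40 HU
#' soft tissue, partial-volume blur of one in-plane voxel (0.4 mm),
#' 10 HU additive noise and the anisotropic 0.4 x 0.4 x 1.5 mm voxel grid.
#' The optional fixation plate is a 30 x 1.5 x 10 mm box at 3000 HU in
#' front of the chin with localized salt noise, exercising the
#' upper-threshold and minimum-filter steps.
#'
#' @param arcWidth,arcDepth,tubeRadius,ramusHeight,ramusRadius,condyleRadius
#'   geometry in mm.
#' @param huAir,huSoft,huBone,huMetal tissue HU levels.
#' @param plate logical, add the fixation plate.
#' @param plateLength,plateThickness,plateHeight plate box dimensions (mm).
#' @param pvBlurSigma partial-volume blur sigma (mm); 0 disables blur.
#' @param noiseSigma additive Gaussian HU noise; 0 disables.
#' @param spacing voxel spacing (mm).
#' @param margin soft-tissue padding around the bone (mm).
#' @param gtResolution ground-truth surface sampling step (mm).
#' @param seed RNG seed; the volume is bit-identical for equal seeds.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(arcWidth = 90, arcDepth = 55, tubeRadius = 5,
                        ramusHeight = 40, ramusRadius = 4, condyleRadius = 6,
                        huAir = -1000, huSoft = 40, huBone = 1200,
                        huMetal = 3000, plate = FALSE, plateLength = 30,
                        plateThickness = 1.5, plateHeight = 10,
                        pvBlurSigma = 0.4, noiseSigma = 10,
                        spacing = c(0.4, 0.4, 1.5), margin = 4,
                        gtResolution = 0.1, seed = 1) {
  new("PhantomSpec", arcWidth = arcWidth, arcDepth = arcDepth,
      tubeRadius = tubeRadius, ramusHeight = ramusHeight,
      ramusRadius = ramusRadius, condyleRadius = condyleRadius,
      huAir = huAir, huSoft = huSoft, huBone = huBone, huMetal = huMetal,
      plate = plate, plateLength = plateLength,
      plateThickness = plateThickness, plateHeight = plateHeight,
      pvBlurSigma = pvBlurSigma, noiseSigma = noiseSigma,
      spacing = as.numeric(spacing), margin = margin,
      gtResolution = gtResolution, seed = seed)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: body %g x %g mm, tube r=%g mm, rami %g mm%s\n",
              object@arcWidth, object@arcDepth, object@tubeRadius,
              object@ramusHeight,
              if (object@plate) ", with plate" else ""))
  cat(sprintf("  HU soft/bone/metal %g/%g/%g, blur %g mm, noise %g HU, spacing %g x %g x %g mm\n",
              object@huSoft, object@huBone, object@huMetal,
              object@pvBlurSigma, object@noiseSigma, object@spacing[1],
              object@spacing[2], object@spacing[3]))
})

# analytic solid: polyline-swept tube + rami capsules + condyle spheres
phantomGeometry <- function(spec) {
  w <- spec@arcWidth; dep <- spec@arcDepth
  xs <- seq(-w / 2, w / 2, length.out = 201)
  poly <- cbind(xs, dep * (xs / (w / 2))^2, 0)
  ends <- poly[c(1, nrow(poly)), ]
  caps <- matrix(c(ends[1, ], ends[1, ] + c(0, 0, spec@ramusHeight),
                   spec@ramusRadius,
                   ends[2, ], ends[2, ] + c(0, 0, spec@ramusHeight),
                   spec@ramusRadius), 2, 7, byrow = TRUE)
  sph <- matrix(c(ends[1, ] + c(0, 0, spec@ramusHeight), spec@condyleRadius,
                  ends[2, ] + c(0, 0, spec@ramusHeight), spec@condyleRadius),
                2, 4, byrow = TRUE)
  rmax <- max(spec@tubeRadius, spec@condyleRadius, spec@ramusRadius)
  lo <- c(-w / 2 - rmax, -spec@tubeRadius, -rmax)
  hi <- c(w / 2 + rmax, dep + rmax, spec@ramusHeight + spec@condyleRadius)
  plate <- NULL
  if (spec@plate) {
    # 1.5 mm soft-tissue standoff: adjacent to the bone but not blurred
    # into it, so the dual threshold can separate the two structures
    cen <- c(0, -(spec@tubeRadius + spec@plateThickness / 2 + 1.5), 0)
    half <- c(spec@plateLength, spec@plateThickness, spec@plateHeight) / 2
    plate <- list(center = cen, half = half)
    lo <- pmin(lo, cen - half)
    hi <- pmax(hi, cen + half)
  }
  list(polyline = poly, tubeRadius = spec@tubeRadius, capsules = caps,
       spheres = sph, plate = plate, lo = lo, hi = hi)
}

phantomSDF <- function(geom, pts) {
  cpp_sdf_points(rbindVec(pts), geom$polyline, geom$tubeRadius,
                 geom$capsules, geom$spheres)
}

.boxSDF <- function(pts, center, half) {
  q <- abs(sweep(rbindVec(pts), 2, center, `-`))
  q <- sweep(q, 2, half, `-`)
  qp <- pmax(q, 0)
  sqrt(rowSums(qp^2)) + pmin(apply(q, 1, max), 0)
}

# partial-volume blend: Gaussian-blurred step across the boundary,
# evaluated as the normal CDF of the signed distance
.pvBlend <- function(sdf, sigma) {
  if (sigma <= 0) as.numeric(sdf <= 0) else pnorm(-sdf / sigma)
}

#' Generate a synthetic mandible-like CT phantom with ground truth
#'
#' Builds the analytic signed-distance solid of the phantom, samples it on
#' the CT grid as a smooth HU blend (bone inside, soft tissue outside, a
#' Gaussian-CDF partial-volume ramp of width \code{pvBlurSigma} across the
#' boundary), optionally adds the metal plate with localized salt noise,
#' adds seeded Gaussian HU noise, and extracts the analytic zero-level
#' ground-truth surface at \code{gtResolution}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param groundTruth logical; extract the ground-truth mesh (set FALSE to
#'   skip the fine-resolution extraction when only the volume is needed).
#' @return list with \code{volume} (\linkS4class{VoxelVolume}),
#'   \code{groundTruth} (\linkS4class{TriMesh} or NULL), \code{labels}
#'   (list of bone and optional plate \linkS4class{SegmentationMask}s) and
#'   \code{spec}.
#' @export
generatePhantom <- function(spec = PhantomSpec(), groundTruth = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  geom <- phantomGeometry(spec)
  g <- gridOverBBox(geom$lo, geom$hi, spec@spacing, pad = spec@margin)
  vol <- VoxelVolume(array(0, g$dims), spacing = g$step, origin = g$origin)
  d <- g$dims
  hu <- array(0, d)
  sdf <- array(0, d)
  sdfPlate <- if (spec@plate) array(0, d) else NULL
  for (k in seq_len(d[3])) {
    pts <- slabWorldCoords(vol, k - 1)
    s <- phantomSDF(geom, pts)
    sdf[, , k] <- s
    h <- spec@huSoft + (spec@huBone - spec@huSoft) * .pvBlend(s, spec@pvBlurSigma)
    if (spec@plate) {
      sb <- .boxSDF(pts, geom$plate$center, geom$plate$half)
      sdfPlate[, , k] <- sb
      h <- pmax(h, spec@huSoft +
                  (spec@huMetal - spec@huSoft) * .pvBlend(sb, spec@pvBlurSigma))
    }
    hu[, , k] <- h
  }
  hu <- withSeed(spec@seed, {
    if (spec@plate) {
      near <- which(sdfPlate < 3)
      salt <- near[runif(length(near)) < 0.02]
      hu[salt] <- spec@huMetal
    }
    if (spec@noiseSigma > 0)
      hu <- hu + array(rnorm(prod(d), 0, spec@noiseSigma), d)
    hu
  })
  vol@data <- hu
  labels <- list(bone = SegmentationMask(sdf <= 0, vol))
  if (spec@plate) labels$plate <- SegmentationMask(sdfPlate <= 0, vol)
  gt <- NULL
  if (groundTruth) gt <- phantomGroundTruth(spec, geom)
  list(volume = vol, groundTruth = gt, labels = labels, spec = spec)
}

# Extract the analytic zero level set on a fine grid, slab by slab so the
# fine field never needs to be held in memory at once.
phantomGroundTruth <- function(spec, geom = phantomGeometry(spec)) {
  res <- spec@gtResolution
  lo <- geom$lo - 2 * res
  hi <- geom$hi + 2 * res
  dims <- as.integer(ceiling((hi - lo) / res)) + 1L
  marchFunctionField(function(pts) -phantomSDF(geom, pts),
                     origin = lo, step = rep(res, 3), dims = dims, iso = 0)
}

# Layered marching over a field given as a function of world points
# (inside where f > iso); slabs are evaluated twice at most once.
marchFunctionField <- function(f, origin, step, dims, iso = 0) {
  xy <- cbind(rep(seq_len(dims[1]) - 1, times = dims[2]) * step[1] + origin[1],
              rep(seq_len(dims[2]) - 1, each = dims[1]) * step[2] + origin[2])
  slab <- function(k)
    matrix(f(cbind(xy, origin[3] + (k - 1) * step[3])), dims[1], dims[2])
  pieces <- vector("list", dims[3] - 1L)
  f0 <- slab(1)
  for (k in seq_len(dims[3] - 1L)) {
    f1 <- slab(k + 1)
    tris <- cpp_march_layer(f0, f1, iso, k - 1L, NULL)
    if (nrow(tris)) pieces[[k]] <- tris
    f0 <- f1
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) stop("iso-level produced no surface")
  m <- cpp_weld_triangles(do.call(rbind, pieces), 1e-9)
  verts <- sweep(sweep(m$vertices, 2, step, `*`), 2, origin, `+`)
  TriMesh(verts, m$faces)
}

#' Voxelize a watertight mesh into an HU volume
#'
#' Inside/outside classification by ray parity, with a smooth
#' partial-volume HU ramp of width ~\code{blurSigma} across the surface
#' (exact signed distance within a narrow band), so isosurface extraction
#' at the midpoint HU recovers the surface with sub-voxel accuracy.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param huInside,huOutside HU levels of the solid and the background.
#' @param blurSigma partial-volume ramp sigma (mm); 0 gives a crisp step.
#' @param margin grid padding around the mesh (mm).
#' @return A \linkS4class{VoxelVolume}.
#' @export
voxelizeMesh <- function(mesh, spacing = c(0.4, 0.4, 0.4), huInside = 1200,
                         huOutside = 40, blurSigma = 0.4, margin = NULL) {
  stopifnot(is(mesh, "TriMesh"))
  spacing <- rep(spacing, length.out = 3)
  topo <- cpp_mesh_topology(faces(mesh), nrow(vertices(mesh)))
  if (!topo$watertight)
    stop("mesh is not watertight; cannot voxelize")
  if (is.null(margin)) margin <- max(4 * blurSigma, 3 * max(spacing))
  V <- vertices(mesh)
  g <- gridOverBBox(apply(V, 2, min), apply(V, 2, max), spacing, pad = margin)
  band <- max(4 * blurSigma, 2 * max(spacing))
  sdf <- meshSDFGrid(mesh, g$origin, g$step, g$dims, band = band,
                     extraIters = as.integer(ceiling(band / min(spacing))))
  hu <- huOutside + (huInside - huOutside) * .pvBlend(sdf, blurSigma)
  VoxelVolume(array(hu, g$dims), spacing = g$step, origin = g$origin)
}

#' Digital round-trip accuracy experiment
#'
#' The accuracy content of the modelling chain, run digitally: voxelize a
#' ground-truth surface with a partial-volume ramp, segment by threshold and
#' connectivity, extract the isosurface at the midpoint HU (the unbiased
#' surface estimate under a symmetric partial-volume ramp), best-fit align
#' the reconstruction to the ground truth, and report the signed deviation
#' map. The maximum absolute deviation is the figure compared against the
#' +/- 0.15 mm shape tolerance.
#'
#' @param groundTruth the ground-truth \linkS4class{TriMesh}.
#' @param spacing voxel spacing of the digital CT grid (mm).
#' @param huInside,huOutside,blurSigma imaging model, as
#'   \code{\link{voxelizeMesh}}.
#' @param lowerHU segmentation threshold (default 200).
#' @param connectivity region-growing connectivity.
#' @param samplesPerMm2,tolerance,seed deviation-map parameters.
#' @param icpTol ICP convergence tolerance (mm).
#' @return A \linkS4class{DeviationReport}.
#' @export
digitalRoundTrip <- function(groundTruth, spacing = c(0.4, 0.4, 0.4),
                             huInside = 1200, huOutside = 40,
                             blurSigma = 0.4, lowerHU = 200,
                             connectivity = 26, samplesPerMm2 = 4,
                             tolerance = 0.15, seed = 1, icpTol = 0.001) {
  vol <- voxelizeMesh(groundTruth, spacing, huInside, huOutside, blurSigma)
  mask <- thresholdMask(vol, lowerHU)
  grown <- largestComponent(mask, connectivity)
  recon <- extractIsosurface(vol, (huInside + huOutside) / 2,
                             restrict = grown)
  tf <- bestFitAlign(recon, groundTruth, tol = icpTol, seed = seed)
  deviationMap(recon, groundTruth, tf, samplesPerMm2 = samplesPerMm2,
               tolerance = tolerance, seed = seed)
}

#' Analytic sphere-plus-body reference surface
#'
#' Smooth analytic phantom for round-trip accuracy experiments: a sphere
#' blended with a parabolic-tube mandibular body, extracted from its exact
#' signed-distance field at the requested resolution. The sphere tests
#' curvature handling, the bent tube tests the elongated cortical-shell
#' geometry.
#'
#' @param arcWidth,arcDepth,tubeRadius body parabola and tube radius (mm).
#' @param sphereRadius,sphereCenter the sphere (mm).
#' @param resolution surface sampling step (mm).
#' @return A watertight \linkS4class{TriMesh}.
#' @export
sphereBodyPhantom <- function(arcWidth = 60, arcDepth = 30, tubeRadius = 4,
                              sphereRadius = 10, sphereCenter = c(0, 0, 0),
                              resolution = 0.1) {
  xs <- seq(-arcWidth / 2, arcWidth / 2, length.out = 201)
  poly <- cbind(xs, arcDepth * (xs / (arcWidth / 2))^2, 0)
  caps <- matrix(0, 0, 7)
  sph <- matrix(c(sphereCenter, sphereRadius), 1, 4)
  rmax <- max(tubeRadius, sphereRadius)
  lo <- pmin(c(-arcWidth / 2 - tubeRadius, -tubeRadius, -tubeRadius),
             sphereCenter - sphereRadius) - 2 * resolution
  hi <- pmax(c(arcWidth / 2 + tubeRadius, arcDepth + tubeRadius, tubeRadius),
             sphereCenter + sphereRadius) + 2 * resolution
  dims <- as.integer(ceiling((hi - lo) / resolution)) + 1L
  f <- function(pts) -cpp_sdf_points(pts, poly, tubeRadius, caps, sph)
  marchFunctionField(f, origin = lo, step = rep(resolution, 3), dims = dims,
                     iso = 0)
}

specAsList <- function(spec) {
  nm <- slotNames(spec)
  out <- lapply(nm, function(s) slot(spec, s))
  names(out) <- nm
  out
}

specFromList <- function(lst) do.call(PhantomSpec, lst)

#' Write a complete phantom dataset to disk
#'
#' DICOM series, binary ground-truth STL, run-length-encoded label masks
#' (JSON) and the spec itself (JSON), giving an end-to-end test input
#' without patient data.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param outDir output directory.
#' @return Invisibly, a named list of the written paths.
#' @export
writePhantomDataset <- function(spec, outDir) {
  ph <- generatePhantom(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dicomDir <- file.path(outDir, "dicom")
  writeDicomSeries(ph$volume, dicomDir)
  stl <- file.path(outDir, "ground_truth.stl")
  writeSTL(ph$groundTruth, stl)
  rleOf <- function(mask) {
    r <- rle(as.vector(maskData(mask)))
    list(dims = dim(mask), lengths = r$lengths, values = r$values)
  }
  labels <- file.path(outDir, "labels.json")
  jsonlite::write_json(lapply(ph$labels, rleOf), labels, digits = NA)
  specFile <- file.path(outDir, "phantom_spec.json")
  jsonlite::write_json(specAsList(spec), specFile, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(dicom = dicomDir, groundTruth = stl, labels = labels,
                 spec = specFile))
}
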