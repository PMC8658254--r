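#' Construct a symmetry plane
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized here, zero is an error. The
#'   default X normal gives the sagittal (YZ) plane used to mirror the
#'   healthy hemi-mandible onto the pathological side.
#' @return A \linkS4class{SymmetryPlane}.
#' @export
SymmetryPlane <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  new("SymmetryPlane", point = as.numeric(point),
      normal = unitv(as.numeric(normal)))
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex, \code{v' = v - 2 ((v - p) . n) n}, and reverses
#' the face winding so outward orientation is preserved. Reflection is an
#' isometry: volume and area are preserved exactly.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param plane a \linkS4class{SymmetryPlane}.
#' @return The mirrored \linkS4class{TriMesh}.
#' @export
mirrorMesh <- function(mesh, plane) {
  stopifnot(is(mesh, "TriMesh"), is(plane, "SymmetryPlane"))
  n <- plane@normal
  V <- vertices(mesh)
  dist <- (sweep(V, 2, plane@point, `-`) %*% n)[, 1]
  V2 <- V - 2 * outer(dist, n)
  TriMesh(V2, faces(mesh)[, c(1, 3, 2), drop = FALSE])
}

#' Build the mirror-based reconstruction template
#'
#' The healthy half-space portion of the mandible surface is united with its
#' own mirror image across the symmetry plane, producing the template on
#' which a titanium splint can be pre-bent for the pathological side. The
#' union is evaluated as a level set on a plane-aligned grid (the
#' mirror-composed signed distance of the input mesh), then re-extracted, so
#' the result is watertight by construction; the geometric error is bounded
#' by the boolean voxel size.
#'
#' @param mesh a watertight \linkS4class{TriMesh} the plane intersects.
#' @param plane the \linkS4class{SymmetryPlane}.
#' @param healthySide +1 if the healthy side is the one the normal points
#'   to, -1 otherwise.
#' @param voxel boolean grid step in mm (default 0.2).
#' @return A watertight \linkS4class{TriMesh}.
#' @export
buildReconstructionTemplate <- function(mesh, plane, healthySide = 1,
                                        voxel = 0.2) {
  stopifnot(is(mesh, "TriMesh"), is(plane, "SymmetryPlane"))
  n <- if (healthySide >= 0) plane@normal else -plane@normal
  B <- planeBasis(n)
  Vf <- sweep(vertices(mesh), 2, plane@point, `-`) %*% B
  if (min(Vf[, 1]) >= 0 || max(Vf[, 1]) <= 0)
    stop("symmetry plane does not intersect the mesh")
  fmesh <- TriMesh(Vf, faces(mesh))
  h <- voxel
  pad <- 3 * h
  hx <- max(Vf[, 1]) + pad
  M <- as.integer(ceiling(hx / h))
  nx <- 2L * M
  x0 <- -(M - 0.5) * h
  ylo <- min(Vf[, 2]) - pad; yhi <- max(Vf[, 2]) + pad
  zlo <- min(Vf[, 3]) - pad; zhi <- max(Vf[, 3]) + pad
  ny <- as.integer(ceiling((yhi - ylo) / h)) + 1L
  nz <- as.integer(ceiling((zhi - zlo) / h)) + 1L
  orig <- c(x0, ylo, zlo)
  dims <- c(nx, ny, nz)
  phi <- meshSDFGrid(fmesh, orig, h, dims, band = 3 * h)
  g <- phi
  g[seq_len(M), , ] <- phi[nx + 1L - seq_len(M), , ]   # mirrored healthy half
  tmpl <- marchSDF(g, orig, h)
  Vw <- sweep(vertices(tmpl) %*% t(B), 2, plane@point, `+`)
  TriMesh(Vw, faces(tmpl))
}

#' Engrave resection-site grooves on a model surface
#'
#' Marks the planned osteotomy sites on the anatomical model: a V-groove of
#' the given depth and width is cut along the surface trace of each cutting
#' plane/curve of the plan (voxel-based boolean subtraction of the swept
#' wedge), leaving the mesh watertight. Groove dimensions default to
#' 0.6 x 0.8 mm, chosen to remain visible at fused-filament print
#' resolution.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @param plan a non-empty \linkS4class{ResectionPlan}.
#' @param grooveDepth groove depth in mm; 0 returns the mesh unchanged.
#' @param grooveWidth groove opening width in mm.
#' @param voxel boolean grid step in mm.
#' @return A \linkS4class{TriMesh} with attribute \code{grooves}: the
#'   labels of the engraved cutters.
#' @export
markResectionSites <- function(mesh, plan, grooveDepth = 0.6,
                               grooveWidth = 0.8, voxel = 0.2) {
  stopifnot(is(mesh, "TriMesh"), is(plan, "ResectionPlan"))
  if (grooveDepth == 0) return(mesh)
  if (grooveDepth < 0 || grooveWidth <= 0)
    stop("groove dimensions must be positive")
  if (planIsEmpty(plan)) stop("resection plan is empty")
  V <- vertices(mesh)
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  h <- voxel
  g <- gridOverBBox(lo, hi, h, pad = 3 * h)
  ijk <- arrayInd(seq_len(prod(g$dims)), g$dims) - 1L
  pts <- sweep(sweep(ijk, 2, g$step, `*`), 2, g$origin, `+`)
  cutters <- c(lapply(plan@planes, function(pl) list(kind = "plane", x = pl)),
               lapply(plan@curves, function(cv) list(kind = "curve", x = cv)))
  labels <- character(0)
  pdList <- vector("list", length(cutters))
  ddAll <- rep(0, nrow(pts))
  for (i in seq_along(cutters)) {
    ct <- cutters[[i]]
    if (ct$kind == "plane") {
      pd <- abs((sweep(pts, 2, ct$x$point, `-`) %*% ct$x$normal)[, 1])
      labels <- c(labels, ct$x$label)
    } else {
      cv <- ct$x
      ax <- match(cv$axis, c("x", "y", "z"))
      d2 <- cpp_dist_to_polyline2d(pts[, -ax, drop = FALSE],
                                   cv$points[, -ax, drop = FALSE])
      t <- pts[, ax]
      dt <- pmax(0, pmax(cv$range[1] - t, t - cv$range[2]))
      pd <- sqrt(d2^2 + dt^2)
      labels <- c(labels, cv$label)
    }
    pdList[[i]] <- pd
    ddAll <- pmax(ddAll, grooveDepth * pmax(0, 1 - 2 * pd / grooveWidth))
  }
  band <- grooveDepth + grooveWidth / 2 + 3 * h
  # exact distances near the surface and throughout the groove wedge region
  phi <- meshSDFGrid(mesh, g$origin, g$step, g$dims, band = band,
                     extra = array(ddAll > 0, g$dims))
  nearSurf <- abs(phi) < max(g$step)
  for (i in seq_along(cutters)) {
    if (!any(nearSurf & pdList[[i]] < grooveWidth / 2))
      stop(sprintf("cutting geometry '%s' does not intersect the mesh surface",
                   labels[i]))
  }
  psi2 <- -phi - array(ddAll, g$dims)   # penetration minus wedge depth
  out <- marchSDF(-psi2, g$origin, g$step)
  attr(out, "grooves") <- labels
  out
}

setClassUnion("TriMeshOrNULL", c("TriMesh", "NULL"))

#' Model set A-D for printing
#'
#' The four print models of a mandibular reconstruction case: A, the
#' segmented mandible with engraved resection sites; B, the mirror-based
#' reconstruction template; C, the plan-bounded resected region; D, the
#' resection-volume reference solid (the same solid as C, carried with its
#' volume metrics, which size the fibula graft).
#'
#' @slot modelA,modelB,modelC,modelD \linkS4class{TriMesh} or NULL.
#' @slot manifest list of parameters and per-model metrics, including
#'   \code{vResect} (mm^3).
#' @export
setClass("ModelSet",
  representation(modelA = "TriMeshOrNULL", modelB = "TriMeshOrNULL",
                 modelC = "TriMeshOrNULL", modelD = "TriMeshOrNULL",
                 manifest = "list"))

setMethod("show", "ModelSet", function(object) {
  for (m in c("A", "B", "C", "D")) {
    mm <- slot(object, paste0("model", m))
    if (is.null(mm)) cat(sprintf("model %s: (not produced)\n", m))
    else cat(sprintf("model %s: %d faces, %.1f mm^3\n", m, nrow(faces(mm)),
                     object@manifest$metrics[[m]]$volume))
  }
  if (!is.null(object@manifest$vResect))
    cat(sprintf("V_resect = %.1f mm^3\n", object@manifest$vResect))
})

#' Segment a volume and assemble the print model set
#'
#' Runs threshold segmentation, seeded region growing (or largest-component
#' selection when no seeds are given), isosurface extraction, groove
#' engraving, template construction and resected-region meshing, returning
#' the four print models with their metrics. The resected-region solid is
#' the intersection of the bone level set with the plan region, so its cut
#' faces are closed planar caps and its volume is the resected-bone estimate
#' \code{vResect}.
#'
#' @param volume a \linkS4class{VoxelVolume} (typically already resampled to
#'   isotropic voxels).
#' @param lowerHU,upperHU segmentation thresholds (HU); \code{upperHU} NULL
#'   for single-threshold mode.
#' @param plan optional \linkS4class{ResectionPlan}; without one, models C/D
#'   are skipped with a warning and A carries no grooves.
#' @param plane optional \linkS4class{SymmetryPlane}; default is the YZ
#'   plane through the segmentation's center of mass.
#' @param seeds optional world-mm seed points for region growing.
#' @param connectivity 6 or 26.
#' @param isoHU extraction iso-value; defaults to \code{lowerHU}.
#' @param grooveDepth,grooveWidth resection-mark groove size (mm).
#' @param templateVoxel boolean grid step for template/groove operations.
#' @return A \linkS4class{ModelSet}.
#' @export
makeModelSet <- function(volume, lowerHU = 200, upperHU = NULL, plan = NULL,
                         plane = NULL, seeds = NULL, connectivity = 26,
                         isoHU = lowerHU, grooveDepth = 0.6,
                         grooveWidth = 0.8, templateVoxel = 0.2) {
  stopifnot(is(volume, "VoxelVolume"))
  mask <- thresholdMask(volume, lowerHU, upperHU)
  grown <- if (is.null(seeds)) largestComponent(mask, connectivity)
           else regionGrow(mask, seeds, connectivity)
  meshFull <- extractIsosurface(volume, isoHU, restrict = grown)
  if (is.null(plane)) {
    idx <- which(maskData(grown))
    com <- colMeans(voxelToWorld(grown, arrayInd(idx, dim(grown)) - 1L))
    plane <- SymmetryPlane(point = com, normal = c(1, 0, 0))
  }
  warnings <- character(0)
  grooves <- character(0)
  if (!planIsEmpty(plan)) {
    modelA <- markResectionSites(meshFull, plan, grooveDepth, grooveWidth,
                                 voxel = templateVoxel)
    grooves <- attr(modelA, "grooves")
  } else {
    modelA <- meshFull
  }
  modelB <- buildReconstructionTemplate(meshFull, plane,
                                        voxel = templateVoxel)
  modelC <- NULL
  if (!planIsEmpty(plan)) {
    maskC <- applyResectionPlan(grown, plan, keep = "inside")
    modelC <- .resectedMesh(volume, grown, plan, isoHU, maskC)
  } else {
    warnings <- c(warnings, "empty resection plan: models C/D skipped")
    warning("empty resection plan: models C/D skipped")
  }
  metrics <- list()
  for (nm in c("A", "B", "C")) {
    mm <- switch(nm, A = modelA, B = modelB, C = modelC)
    if (!is.null(mm)) {
      mt <- meshMetrics(mm)
      metrics[[nm]] <- list(volume = mt@volume, area = mt@area,
                            watertight = mt@watertight,
                            components = mt@components)
    }
  }
  if (!is.null(modelC)) metrics$D <- metrics$C
  manifest <- list(
    parameters = list(lowerHU = lowerHU, upperHU = upperHU, isoHU = isoHU,
                      connectivity = connectivity,
                      grooveDepth = grooveDepth, grooveWidth = grooveWidth,
                      templateVoxel = templateVoxel,
                      plane = list(point = plane@point,
                                   normal = plane@normal)),
    metrics = metrics,
    grooves = grooves,
    vResect = if (!is.null(modelC)) metrics$C$volume else NULL,
    warnings = warnings)
  new("ModelSet", modelA = modelA, modelB = modelB, modelC = modelC,
      modelD = modelC, manifest = manifest)
}

# Closed mesh of (bone level set) intersect (plan region): min of the
# HU-offset field and the plan's signed region field, marched at zero.
.resectedMesh <- function(volume, grown, plan, isoHU, maskC) {
  if (!any(maskData(maskC))) stop("resection plan selects no bone voxels")
  d <- dim(volume)
  huNorm <- (voxelData(volume) - isoHU) / 100   # sign-correct mm-ish scale
  reg <- array(0, d)
  for (k in seq_len(d[3]))
    reg[, , k] <- planRegionField(plan, slabWorldCoords(volume, k - 1))
  fIn <- pmin(huNorm, reg)                      # inside-positive
  pad <- array(-1, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fIn
  keep <- array(FALSE, d + 2L)
  keep[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
    array(cpp_dilate_mask(as.logical(maskData(maskC)), d), d)
  keep <- array(cpp_dilate_mask(as.logical(keep), d + 2L), d + 2L)
  m <- marchArray(pad, 0, keep)
  TriMesh(voxelToWorld(volume, m$vertices - 1), m$faces)
}
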