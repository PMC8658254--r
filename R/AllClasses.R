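# Central S4 containers. Patient space is DICOM-native LPS, units mm;
# voxel values are sampled at voxel centers with 0-based indices, so
# world(i,j,k) = origin + direction %*% (i*sx, j*sy, k*sz).

.defaultLowerHU <- 200
.defaultUpperHU <- 1700

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' CT voxel volume in Hounsfield units
#'
#' A 3-D scalar grid of HU values with its placement in patient space
#' (LPS, mm): voxel spacing, origin (world position of voxel \code{(0,0,0)})
#' and an orthonormal direction matrix of axis cosines. Values are samples at
#' voxel centers; indices are 0-based in all world-mapping arithmetic.
#'
#' @slot data 3-D numeric array of HU values, dimensions (nx, ny, nz).
#' @slot spacing numeric(3), voxel edge lengths in mm, strictly positive.
#' @slot origin numeric(3), world coordinate (mm) of the center of voxel
#'   (0,0,0).
#' @slot direction 3x3 orthonormal matrix; columns are the world directions
#'   of the i, j, k index axes.
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), direction = diag(3)))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  D <- object@direction
  if (!all(dim(D) == c(3L, 3L)) ||
      max(abs(crossprod(D) - diag(3))) > 1e-6)
    msg <- c(msg, "direction must be a 3x3 orthonormal matrix (tol 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Boolean segmentation mask aligned with a voxel volume
#'
#' A logical grid voxel-for-voxel aligned with the \linkS4class{VoxelVolume}
#' it was derived from; carries the same spacing/origin/direction so voxel
#' counts convert to mm^3 and voxel centers to world coordinates.
#'
#' @slot mask 3-D logical array.
#' @slot spacing,origin,direction geometry, as in
#'   \linkS4class{VoxelVolume}.
#' @export
setClass("SegmentationMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), direction = diag(3)))

setValidity("SegmentationMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3-D logical array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Triangle surface mesh in patient coordinates
#'
#' Vertices in mm, faces as 1-based vertex-index triples wound
#' counter-clockwise when seen from outside (outward normals).
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3), 1-based indices into vertices.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriMesh", function(object) {
  msg <- character()
  V <- object@vertices; F <- object@faces
  if (ncol(V) != 3L || !is.numeric(V))
    msg <- c(msg, "vertices must be an n x 3 numeric matrix")
  if (ncol(F) != 3L)
    msg <- c(msg, "faces must be an m x 3 index matrix")
  else if (nrow(F) > 0 && (min(F) < 1L || max(F) > nrow(V)))
    msg <- c(msg, "faces reference out-of-range vertices")
  if (length(msg)) msg else TRUE
})

#' Resection plan: cutting curves and planes
#'
#' Labelled geometry separating resected from retained bone: closed planar
#' polylines swept along a slice axis over a patient-mm range, and/or
#' oriented cutting planes. The kept side of a plane is the side the normal
#' points away from (\code{(x - point) . normal <= 0} is inside); a curve's
#' swept region is the even-odd interior of its polygon within its axis
#' range, boundary inclusive.
#'
#' @slot curves list of \code{list(points, axis, range, label)}: closed
#'   polyline (n x 3 mm, first row equals last), axis one of "x","y","z",
#'   range numeric(2) in mm along that axis.
#' @slot planes list of \code{list(point, normal, label)}; unit normals.
#' @export
setClass("ResectionPlan",
  representation(curves = "list", planes = "list"))

setValidity("ResectionPlan", function(object) {
  msg <- character()
  for (cv in object@curves) {
    P <- cv$points
    if (!is.matrix(P) || ncol(P) != 3L || nrow(P) < 4L)
      { msg <- c(msg, "curve points must be an n x 3 matrix, n >= 4"); next }
    if (max(abs(P[1, ] - P[nrow(P), ])) > 1e-9)
      msg <- c(msg, sprintf("curve '%s' is an open polyline (first point != last point)",
                            if (is.null(cv$label)) "?" else cv$label))
    if (!cv$axis %in% c("x", "y", "z"))
      msg <- c(msg, "curve axis must be one of 'x','y','z'")
    if (length(cv$range) != 2L || cv$range[1] > cv$range[2])
      msg <- c(msg, "curve range must be an increasing mm interval")
    ax <- match(cv$axis, c("x", "y", "z"))
    poly <- P[-nrow(P), -ax, drop = FALSE]
    if (nrow(poly) >= 4L && .polygonSelfIntersects(poly))
      msg <- c(msg, sprintf("curve '%s' is self-intersecting in its plane",
                            if (is.null(cv$label)) "?" else cv$label))
  }
  for (pl in object@planes) {
    n <- pl$normal
    if (length(n) != 3L || sqrt(sum(n^2)) < 1e-12)
      msg <- c(msg, "plane normal must be a non-zero 3-vector")
    else if (abs(sqrt(sum(n^2)) - 1) > 1e-9)
      msg <- c(msg, "plane normal must be unit length")
    if (length(pl$point) != 3L)
      msg <- c(msg, "plane point must be a 3-vector")
  }
  if (length(msg)) msg else TRUE
})

#' Mirror symmetry plane
#'
#' Plane given by a point and a unit normal; the default for mandibular work
#' is the sagittal (YZ) plane, normal along +X.
#'
#' @slot point numeric(3), mm.
#' @slot normal numeric(3), unit length within 1e-9.
#' @export
setClass("SymmetryPlane",
  representation(point = "numeric", normal = "numeric"))

setValidity("SymmetryPlane", function(object) {
  if (length(object@normal) != 3L ||
      abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be unit length (tol 1e-9)")
  if (length(object@point) != 3L || any(!is.finite(object@point)))
    return("point must be 3 finite values")
  TRUE
})

#' Rigid-body transform
#'
#' Proper rotation plus translation, applied as \code{R x + t}.
#'
#' @slot rotation 3x3 orthonormal matrix with det +1 (tol 1e-9).
#' @slot translation numeric(3), mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)) || max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (tol 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det +1)")
  if (length(object@translation) != 3L)
    return("translation must be a 3-vector")
  TRUE
})

#' Signed surface-deviation report
#'
#' Best-fit transform, per-sample signed point-to-surface distances
#' (positive = outside the nominal surface) and summary statistics against a
#' tolerance band.
#'
#' @slot transform the \linkS4class{RigidTransform} applied to the measured
#'   mesh before sampling.
#' @slot distances signed distances in mm, one per surface sample.
#' @slot samples sample points (n x 3 mm) on the transformed measured mesh.
#' @slot stats list: min, max, mean, rms, p95_abs (mm).
#' @slot tolerance tolerance band half-width in mm.
#' @slot fractionWithin proportion of samples with |d| <= tolerance.
#' @export
setClass("DeviationReport",
  representation(transform = "RigidTransform", distances = "numeric",
                 samples = "matrix", stats = "list", tolerance = "numeric",
                 fractionWithin = "numeric"))

setValidity("DeviationReport", function(object) {
  msg <- character()
  if (object@fractionWithin < 0 || object@fractionWithin > 1)
    msg <- c(msg, "fractionWithin must lie in [0, 1]")
  s <- object@stats
  if (length(object@distances)) {
    if (s$rms^2 + 1e-12 < s$mean^2)
      msg <- c(msg, "rms^2 must be >= mean^2")
    if (s$max + 1e-12 < s$mean || s$mean + 1e-12 < s$min)
      msg <- c(msg, "stats must satisfy max >= mean >= min")
  }
  if (length(msg)) msg else TRUE
})

#' Mesh metrics
#'
#' Volume by the divergence theorem, triangle-area sum, watertightness and
#' connected-component count.
#'
#' @slot volume mm^3 (positive for a watertight, outward-oriented mesh).
#' @slot area mm^2.
#' @slot watertight logical.
#' @slot components integer.
#' @export
setClass("MeshMetrics",
  representation(volume = "numeric", area = "numeric",
                 watertight = "logical", components = "integer"))

#' Synthetic mandible-like CT phantom specification
#'
#' Parameters of the analytic phantom: a tube swept along a parabolic body
#' arc, two rami capsules capped by condylar spheres, tissue HU levels,
#' an optional fixation-plate box at metal HU with localized salt noise,
#' partial-volume blur, additive HU noise, anisotropic spacing and the RNG
#' seed. The signed-distance geometry doubles as analytic ground truth.
#'
#' @slot arcWidth,arcDepth parabola of the mandibular body (mm).
#' @slot tubeRadius body tube radius (mm).
#' @slot ramusHeight,ramusRadius,condyleRadius rami capsules and condylar
#'   sphere caps (mm).
#' @slot huAir,huSoft,huBone,huMetal tissue HU levels.
#' @slot plate logical; add a fixation-plate box at metal HU.
#' @slot plateLength,plateThickness,plateHeight plate box dimensions (mm).
#' @slot pvBlurSigma partial-volume blur sigma (mm).
#' @slot noiseSigma additive Gaussian HU noise sigma.
#' @slot spacing voxel spacing (mm), anisotropic CT default.
#' @slot margin soft-tissue padding around the bone bounding box (mm).
#' @slot gtResolution ground-truth isosurface sampling step (mm).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(arcWidth = "numeric", arcDepth = "numeric",
                 tubeRadius = "numeric", ramusHeight = "numeric",
                 ramusRadius = "numeric", condyleRadius = "numeric",
                 huAir = "numeric", huSoft = "numeric", huBone = "numeric",
                 huMetal = "numeric", plate = "logical",
                 plateLength = "numeric", plateThickness = "numeric",
                 plateHeight = "numeric", pvBlurSigma = "numeric",
                 noiseSigma = "numeric", spacing = "numeric",
                 margin = "numeric", gtResolution = "numeric",
                 seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (!(object@huAir < object@huSoft))
    msg <- c(msg, "HU ordering violated: need huAir < huSoft")
  if (!(object@huSoft < .defaultLowerHU && .defaultLowerHU <= object@huBone))
    msg <- c(msg, sprintf("HU ordering violated: need huSoft < %d <= huBone",
                          .defaultLowerHU))
  if (object@plate &&
      !(object@huBone < .defaultUpperHU && .defaultUpperHU <= object@huMetal))
    msg <- c(msg, sprintf("HU ordering violated: need huBone < %d <= huMetal when plate enabled",
                          .defaultUpperHU))
  if (any(c(object@arcWidth, object@arcDepth, object@tubeRadius,
            object@gtResolution) <= 0))
    msg <- c(msg, "geometry parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Print-cost model
#'
#' Simple linear material/machine cost structure for fused filament
#' fabrication; prices are external assumptions, not outputs of the method.
#'
#' @slot filamentDensity g/cm^3 (PLA default 1.24).
#' @slot pricePerKg currency per kg of filament.
#' @slot infill infill fraction in (0, 1].
#' @slot machineRate currency per machine hour.
#' @slot printSpeed deposition-rate proxy, cm^3/h.
#' @slot layerThickness print layer height (mm), kept as a cost parameter.
#' @export
setClass("CostModel",
  representation(filamentDensity = "numeric", pricePerKg = "numeric",
                 infill = "numeric", machineRate = "numeric",
                 printSpeed = "numeric", layerThickness = "numeric"))

setValidity("CostModel", function(object) {
  vals <- c(object@filamentDensity, object@pricePerKg, object@machineRate,
            object@printSpeed, object@layerThickness)
  if (any(vals <= 0)) return("all rates must be positive")
  if (object@infill <= 0 || object@infill > 1)
    return("infill must lie in (0, 1]")
  TRUE
})
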