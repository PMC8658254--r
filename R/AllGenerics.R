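#' @name accessors
#' @title Accessors for osteoplan containers
#' @description Slot accessors for the package's S4 containers; use these
#'   rather than \code{@} access.
#' @param x an osteoplan object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("deviationStats", function(x) standardGeneric("deviationStats"))
#' @rdname accessors
#' @export
setGeneric("fractionWithin", function(x) standardGeneric("fractionWithin"))

setMethod("spacing", "VoxelVolume", function(x) x@spacing)
setMethod("spacing", "SegmentationMask", function(x) x@spacing)
setMethod("origin", "VoxelVolume", function(x) x@origin)
setMethod("origin", "SegmentationMask", function(x) x@origin)
setMethod("direction", "VoxelVolume", function(x) x@direction)
setMethod("direction", "SegmentationMask", function(x) x@direction)
setMethod("voxelData", "VoxelVolume", function(x) x@data)
setMethod("maskData", "SegmentationMask", function(x) x@mask)
setMethod("vertices", "TriMesh", function(x) x@vertices)
setMethod("faces", "TriMesh", function(x) x@faces)
setMethod("rotation", "RigidTransform", function(x) x@rotation)
setMethod("translation", "RigidTransform", function(x) x@translation)
setMethod("distances", "DeviationReport", function(x) x@distances)
setMethod("deviationStats", "DeviationReport", function(x) x@stats)
setMethod("fractionWithin", "DeviationReport", function(x) x@fractionWithin)

#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))
#' @export
setMethod("dim", "SegmentationMask", function(x) dim(x@mask))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
              min(object@data), max(object@data),
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@mask)
  n <- sum(object@mask)
  cat(sprintf("SegmentationMask %d x %d x %d, %d voxels set (%.1f mm^3)\n",
              d[1], d[2], d[3], n, n * prod(object@spacing)))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (nrow(object@vertices)) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "DeviationReport", function(object) {
  s <- object@stats
  cat(sprintf("DeviationReport: %d samples, tolerance +/- %.3g mm\n",
              length(object@distances), object@tolerance))
  cat(sprintf("  min %.4f  max %.4f  mean %.4f  rms %.4f  p95|d| %.4f mm\n",
              s$min, s$max, s$mean, s$rms, s$p95_abs))
  cat(sprintf("  %.2f%% of samples within tolerance\n",
              100 * object@fractionWithin))
})

setMethod("show", "MeshMetrics", function(object) {
  cat(sprintf("MeshMetrics: volume %.2f mm^3, area %.2f mm^2, %s, %d component(s)\n",
              object@volume, object@area,
              if (object@watertight) "watertight" else "not watertight",
              object@components))
})

setMethod("show", "SymmetryPlane", function(object) {
  cat(sprintf("SymmetryPlane through (%.2f, %.2f, %.2f), normal (%.3f, %.3f, %.3f)\n",
              object@point[1], object@point[2], object@point[3],
              object@normal[1], object@normal[2], object@normal[3]))
})
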