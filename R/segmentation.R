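#' Hounsfield threshold segmentation
#'
#' Boolean mask of voxels with \code{lowerHU <= HU} and, when an upper
#' threshold is set, \code{HU <= upperHU}. The lower default of 200 HU
#' extracts mandibular bone; the upper threshold (default off; 1700 HU in
#' post-operative mode) separates bone from a titanium fixation plate.
#'
#' @param volume a \linkS4class{VoxelVolume} with finite HU.
#' @param lowerHU lower threshold in HU (default 200).
#' @param upperHU upper threshold in HU, or NULL for single-threshold mode.
#' @return A \linkS4class{SegmentationMask} sharing the volume's geometry.
#' @export
thresholdMask <- function(volume, lowerHU = 200, upperHU = NULL) {
  stopifnot(is(volume, "VoxelVolume"))
  if (!is.null(upperHU) && lowerHU >= upperHU)
    stop("lower threshold must be below the upper threshold")
  hu <- voxelData(volume)
  if (any(!is.finite(hu))) stop("volume contains non-finite values")
  m <- hu >= lowerHU
  if (!is.null(upperHU)) m <- m & hu <= upperHU
  SegmentationMask(m, volume)
}

#' Seeded region growing on a binary mask
#'
#' Returns the union of the connected components of the mask that contain at
#' least one seed, under 6- or 26-connectivity. This is the final
#' segmentation step: thresholding proposes candidate voxels, the grown
#' region keeps only the structure connected to the seeds.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param seeds n x 3 matrix (or length-3 vector) of seed points in world mm.
#' @param connectivity 6 or 26 (default 26, which keeps thin cortical bone
#'   connected at fine voxel sizes).
#' @return A \linkS4class{SegmentationMask}, a subset of the input.
#' @export
regionGrow <- function(mask, seeds, connectivity = 26) {
  stopifnot(is(mask, "SegmentationMask"))
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  seeds <- rbindVec(seeds)
  idx <- round(worldToVoxel(mask, seeds))
  d <- dim(mask)
  oob <- idx[, 1] < 0 | idx[, 2] < 0 | idx[, 3] < 0 |
    idx[, 1] >= d[1] | idx[, 2] >= d[2] | idx[, 3] >= d[3]
  if (any(oob))
    stop(sprintf("seed (%s) maps outside the volume",
                 paste(sprintf("%.2f", seeds[which(oob)[1], ]),
                       collapse = ", ")))
  lin <- 1 + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
  if (!any(maskData(mask)[lin]))
    stop(sprintf("no seed lies in a true voxel: %s",
                 paste(apply(seeds, 1, function(p)
                   sprintf("(%.2f, %.2f, %.2f)", p[1], p[2], p[3])),
                   collapse = "; ")))
  grown <- cpp_region_grow(as.logical(maskData(mask)), d,
                           matrix(as.integer(idx), ncol = 3),
                           as.integer(connectivity))
  SegmentationMask(array(grown, d), mask)
}

#' Largest connected component of a mask
#'
#' Seed-free fallback used by the pipeline when no seed points are given:
#' keeps the largest connected component, which for a thresholded head CT is
#' the mandible once the threshold has isolated bone.
#'
#' @inheritParams regionGrow
#' @return A \linkS4class{SegmentationMask}.
#' @export
largestComponent <- function(mask, connectivity = 26) {
  stopifnot(is(mask, "SegmentationMask"))
  out <- cpp_largest_component(as.logical(maskData(mask)), dim(mask),
                               as.integer(connectivity))
  SegmentationMask(array(out, dim(mask)), mask)
}
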