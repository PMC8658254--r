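#' Construct a VoxelVolume
#'
#' @param data 3-D numeric array of HU values (nx, ny, nz).
#' @param spacing voxel spacing in mm, length 3, strictly positive.
#' @param origin world coordinate (mm, LPS) of the center of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix of index-axis direction cosines.
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' vol <- VoxelVolume(array(-1000, c(4, 4, 4)), spacing = c(0.4, 0.4, 1.5))
#' spacing(vol)
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  new("VoxelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' Construct a SegmentationMask
#'
#' @param mask 3-D logical array.
#' @param geometry a \linkS4class{VoxelVolume} or
#'   \linkS4class{SegmentationMask} supplying spacing/origin/direction; the
#'   mask must match its shape.
#' @return A \linkS4class{SegmentationMask}.
#' @export
SegmentationMask <- function(mask, geometry) {
  if (!identical(dim(mask), dim(geometry)))
    stop("mask shape must equal the source volume shape")
  new("SegmentationMask", mask = mask, spacing = spacing(geometry),
      origin = origin(geometry), direction = direction(geometry))
}

#' Map between voxel indices and world coordinates
#'
#' Voxel indices are 0-based and continuous; index (i,j,k) maps to
#' \code{origin + direction \%*\% (i*sx, j*sy, k*sz)}. The mapping is affine
#' and exactly invertible.
#'
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{SegmentationMask}.
#' @param ijk,xyz n x 3 matrix (or length-3 vector) of 0-based voxel indices
#'   / world mm coordinates.
#' @return n x 3 matrix of world coordinates (mm) or continuous voxel
#'   indices.
#' @examples
#' vol <- VoxelVolume(array(0, c(8, 8, 4)), spacing = c(0.4, 0.4, 1.5),
#'                    origin = c(-10, 5, 30))
#' w <- voxelToWorld(vol, c(2, 3, 1))
#' worldToVoxel(vol, w)   # recovers (2, 3, 1)
#' @export
voxelToWorld <- function(x, ijk) {
  ijk <- rbindVec(ijk)
  sc <- sweep(ijk, 2, spacing(x), `*`)
  sweep(sc %*% t(direction(x)), 2, origin(x), `+`)
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(x, xyz) {
  xyz <- rbindVec(xyz)
  d <- sweep(xyz, 2, origin(x), `-`) %*% direction(x)
  sweep(d, 2, spacing(x), `/`)
}

rbindVec <- function(m) {
  if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
}

# world coordinates of all voxel centers in slab k (0-based), as an
# (nx*ny) x 3 matrix ordered i-fastest
slabWorldCoords <- function(x, k) {
  d <- dim(x)
  ij <- cbind(rep(seq_len(d[1]) - 1, times = d[2]),
              rep(seq_len(d[2]) - 1, each = d[1]),
              k)
  voxelToWorld(x, ij)
}

# volume of one voxel in mm^3
voxelVolumeMm3 <- function(x) prod(spacing(x))
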