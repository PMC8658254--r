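#' Construct a TriMesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 matrix of 1-based vertex indices, counter-clockwise
#'   from outside.
#' @return A \linkS4class{TriMesh}.
#' @export
TriMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("TriMesh", vertices = as.matrix(vertices), faces = faces)
}

# March an index-space scalar array layer by layer; returns a welded mesh in
# continuous 0-based index coordinates. `keep` (optional logical array, same
# dims) limits processing to cubes with at least one flagged corner.
marchArray <- function(arr, iso, keep = NULL, weldTol = 1e-9) {
  d <- dim(arr)
  pieces <- vector("list", d[3] - 1L)
  for (k in seq_len(d[3] - 1L)) {
    keepMat <- NULL
    if (!is.null(keep)) {
      k0 <- keep[, , k]; k1 <- keep[, , k + 1L]
      a <- function(m) m[-d[1], -d[2]] | m[-1, -d[2]] | m[-d[1], -1] | m[-1, -1]
      keepMat <- a(k0) | a(k1)
      if (!any(keepMat)) next
    }
    tris <- cpp_march_layer(arr[, , k], arr[, , k + 1L], iso, k - 1L, keepMat)
    if (nrow(tris)) pieces[[k]] <- tris
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) stop("iso-level produced no surface")
  cpp_weld_triangles(do.call(rbind, pieces), weldTol)
}

#' Extract an isosurface triangle mesh from a CT volume
#'
#' Marching-cubes family extraction of the surface where the HU field
#' crosses \code{isoHU}: each lattice cube is decomposed into six
#' tetrahedra (a translation-compatible decomposition, so the surface is
#' watertight and topologically consistent), vertices are placed by linear
#' interpolation along cell edges, and faces are oriented with outward
#' normals (the higher-HU side is the inside). The volume is padded with one
#' air voxel layer so surfaces close at the border. With \code{restrict},
#' only cubes touching the (1-voxel-dilated) mask are processed, confining
#' the surface to the segmented structure.
#'
#' @param volume a \linkS4class{VoxelVolume}, shape >= (2,2,2).
#' @param isoHU iso-value in HU; must lie strictly inside the HU range of
#'   the (restricted) region.
#' @param restrict optional \linkS4class{SegmentationMask} aligned with the
#'   volume.
#' @return A \linkS4class{TriMesh} in patient mm.
#' @export
extractIsosurface <- function(volume, isoHU, restrict = NULL) {
  stopifnot(is(volume, "VoxelVolume"))
  d <- dim(volume)
  if (any(d < 2L)) stop("volume shape must be at least (2,2,2)")
  hu <- voxelData(volume)
  keep <- NULL
  if (!is.null(restrict)) {
    stopifnot(is(restrict, "SegmentationMask"))
    if (!identical(dim(restrict), d))
      stop("restriction mask shape differs from the volume")
    if (!any(maskData(restrict))) stop("restricted region is empty")
    dil <- array(cpp_dilate_mask(as.logical(maskData(restrict)), d), d)
    vals <- range(hu[dil])
  } else {
    vals <- range(hu)
  }
  if (isoHU <= vals[1] || isoHU >= vals[2])
    stop(sprintf("iso value %g HU outside the data range [%g, %g]",
                 isoHU, vals[1], vals[2]))
  padVal <- min(-1000, isoHU - 1)
  padded <- array(padVal, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- hu
  if (!is.null(restrict)) {
    keep <- array(FALSE, d + 2L)
    keep[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- dil
    # keep border cubes adjacent to mask voxels on the volume boundary
    keep <- array(cpp_dilate_mask(as.logical(keep), d + 2L), d + 2L)
  }
  m <- marchArray(padded, isoHU, keep)
  verts <- voxelToWorld(volume, m$vertices - 1)
  TriMesh(verts, m$faces)
}

#' Mesh metrics: volume, area, watertightness
#'
#' Volume by the divergence theorem (signed tetrahedra against the origin),
#' area as the triangle-area sum, watertightness (every directed edge
#' matched by its reverse exactly once) and connected-component count. A
#' negative signed volume means the mesh is oriented inward; the magnitude
#' is reported with a warning.
#'
#' @param mesh a non-empty \linkS4class{TriMesh}.
#' @return A \linkS4class{MeshMetrics}.
#' @examples
#' cube <- osteoplan:::unitCubeMesh(10)
#' meshMetrics(cube)   # 1000 mm^3, 600 mm^2
#' @export
meshMetrics <- function(mesh) {
  stopifnot(is(mesh, "TriMesh"))
  if (nrow(faces(mesh)) == 0L) stop("empty mesh")
  va <- cpp_mesh_vol_area(vertices(mesh), faces(mesh))
  topo <- cpp_mesh_topology(faces(mesh), nrow(vertices(mesh)))
  vol <- va[1]
  if (topo$watertight && vol < 0) {
    warning("mesh is oriented inward (negative signed volume); reporting the magnitude")
    vol <- -vol
  }
  new("MeshMetrics", volume = vol, area = va[2],
      watertight = topo$watertight, components = as.integer(topo$components))
}

#' Read and write STL surface meshes
#'
#' Binary little-endian STL (mm units) is the print interchange format;
#' ASCII STL is accepted on read. Vertices are deduplicated within 1e-6 mm
#' on read. Truncated binary files and facet counts inconsistent with the
#' file length are errors.
#'
#' @param path STL file path.
#' @param mesh a \linkS4class{TriMesh}.
#' @return \code{readSTL}: a \linkS4class{TriMesh}; \code{writeSTL}: the
#'   path, invisibly.
#' @export
readSTL <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  size <- file.info(path)$size
  if (size < 15) stop(sprintf("truncated STL '%s': %d bytes", path, size))
  head <- readBin(path, "raw", n = min(size, 512))
  isAscii <- identical(rawToChar(head[1:5]), "solid") &&
    grepl("facet", rawToChar(head[head != as.raw(0)]), fixed = TRUE)
  tris <- if (isAscii) .readStlAscii(path) else cpp_read_stl_binary(path)
  m <- cpp_weld_triangles(tris, 1e-6)
  TriMesh(m$vertices, m$faces)
}

.readStlAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop(sprintf("malformed ASCII STL '%s'", path))
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  matrix(as.vector(t(nums)), ncol = 9, byrow = TRUE)
}

#' @rdname readSTL
#' @export
writeSTL <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  cpp_write_stl_binary(path, vertices(mesh), faces(mesh))
  invisible(path)
}

#' Export a coloured mesh as ASCII PLY
#'
#' Per-vertex scalars (e.g. signed deviations) are mapped onto a diverging
#' blue-white-red scale clipped at \code{+/-clip}, mimicking inspection
#' deviation maps.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param path output file.
#' @param scalar optional numeric per-vertex values.
#' @param clip colour scale clip (default max |scalar|).
#' @return The path, invisibly.
#' @export
writePLY <- function(mesh, path, scalar = NULL, clip = NULL) {
  stopifnot(is(mesh, "TriMesh"))
  V <- vertices(mesh); F <- faces(mesh)
  hasCol <- !is.null(scalar)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               if (hasCol) c("property uchar red", "property uchar green",
                             "property uchar blue"),
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (hasCol) {
    if (is.null(clip)) clip <- max(abs(scalar), 1e-12)
    t <- pmin(1, pmax(-1, scalar / clip))
    g <- round(255 * (1 - abs(t)))
    r <- round(255 * ifelse(t > 0, 1, 1 + t))
    b <- round(255 * ifelse(t > 0, 1 - t, 1))
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                       V[, 1], V[, 2], V[, 3], r, g, b), con)
  } else {
    writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
             con)
  invisible(path)
}

# axis-aligned cube mesh (12 triangles, outward normals); test/QC fixture
unitCubeMesh <- function(edge = 1, center = c(0, 0, 0)) {
  h <- edge / 2
  corn <- as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h)))
  V <- sweep(corn, 2, center, `+`)
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  TriMesh(V, F)
}

# geodesic icosphere by subdivision; analytic-volume test fixture
icosphereMesh <- function(radius = 1, center = c(0, 0, 0), subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nf <- nrow(F)
    newF <- matrix(0L, nf * 4, 3)
    mid <- new.env(parent = emptyenv())
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      id <- nrow(V)
      assign(key, id, envir = mid)
      id
    }
    for (f in seq_len(nf)) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      newF[(f - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    F <- newF
  }
  TriMesh(sweep(V * radius, 2, center, `+`), F)
}
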