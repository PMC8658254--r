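radialRampVolume <- function(n = 61, sp = 0.4, r0 = 10) {
  cx <- (n - 1) / 2 * sp
  g <- expand.grid(x = (0:(n - 1)) * sp, y = (0:(n - 1)) * sp,
                   z = (0:(n - 1)) * sp)
  r <- sqrt((g$x - cx)^2 + (g$y - cx)^2 + (g$z - cx)^2)
  VoxelVolume(array(1200 - 100 * (r - r0), c(n, n, n)), spacing = rep(sp, 3))
}

test_that("isosurface of a radial ramp recovers the sphere to < 0.05 mm", {
  vol <- radialRampVolume()
  mesh <- extractIsosurface(vol, 1200)
  cx <- (dim(vol)[1] - 1) / 2 * 0.4
  rad <- sqrt(rowSums(sweep(vertices(mesh), 2, rep(cx, 3), `-`)^2))
  expect_lt(max(abs(rad - 10)), 0.05)
  mt <- meshMetrics(mesh)
  expect_true(mt@watertight)
  expect_identical(mt@components, 1L)
  expect_gt(mt@volume, 0)                       # outward orientation
  expect_lt(abs(mt@volume - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.01)
})

test_that("halving the voxel size at least halves the sphere surface error", {
  err <- vapply(c(0.4, 0.2), function(sp) {
    n <- round(24 / sp) + 1
    vol <- radialRampVolume(n, sp)
    cx <- (n - 1) / 2 * sp
    mesh <- extractIsosurface(vol, 1200)
    rad <- sqrt(rowSums(sweep(vertices(mesh), 2, rep(cx, 3), `-`)^2))
    max(abs(rad - 10))
  }, 0)
  expect_gte(err[1] / err[2], 2)
})

test_that("an axis-aligned HU step places the surface exactly halfway", {
  arr <- array(0, c(10, 8, 8))
  arr[6:10, , ] <- 1000                 # step between centers x=4 and x=5
  vol <- VoxelVolume(arr, spacing = c(1, 1, 1))
  mesh <- extractIsosurface(vol, 500)
  V <- vertices(mesh)
  # interior crossings only: the one-voxel air padding closes the surface at
  # the volume border with its own (correct) crossing positions
  interior <- V[, 2] > 0.5 & V[, 2] < 6.5 & V[, 3] > 0.5 & V[, 3] < 6.5
  crossing <- V[interior & V[, 1] > 4.01 & V[, 1] < 4.99, 1]
  expect_gt(length(crossing), 0)
  expect_lt(max(abs(crossing - 4.5)), 1e-6)
})

test_that("iso values outside the data range are rejected", {
  vol <- VoxelVolume(array(-1000, c(4, 4, 4)))
  expect_error(extractIsosurface(vol, 200), "outside the data range")
  ramp <- radialRampVolume(21, 0.4, 3)
  empty <- SegmentationMask(array(FALSE, dim(ramp)), ramp)
  expect_error(extractIsosurface(ramp, 1200, restrict = empty), "empty")
})

test_that("restricted extraction agrees with the mask voxel volume within 5%", {
  vol <- radialRampVolume(61, 0.4)
  mask <- thresholdMask(vol, 1200)      # sphere r = 10
  mesh <- extractIsosurface(vol, 1200, restrict = mask)
  maskVol <- sum(maskData(mask)) * prod(spacing(vol))
  expect_lt(abs(meshMetrics(mesh)@volume - maskVol) / maskVol, 0.05)
})

test_that("mesh metrics are exact on the 10 mm cube and 1% on the icosphere", {
  cube <- osteoplan:::unitCubeMesh(10)
  mt <- meshMetrics(cube)
  expect_equal(mt@volume, 1000)
  expect_equal(mt@area, 600)
  expect_true(mt@watertight)
  ico <- osteoplan:::icosphereMesh(10, subdiv = 4)
  expect_lt(abs(meshMetrics(ico)@volume - 4188.79) / 4188.79, 0.01)
  holed <- TriMesh(vertices(cube), faces(cube)[-1, ])
  expect_warning(mth <- meshMetrics(holed), NA)
  expect_false(mth@watertight)
  expect_error(meshMetrics(TriMesh(matrix(0, 0, 3), matrix(0L, 0, 3))),
               "empty")
})

test_that("an inward-oriented mesh is reported with a warning", {
  cube <- osteoplan:::unitCubeMesh(10)
  flipped <- TriMesh(vertices(cube), faces(cube)[, c(1, 3, 2)])
  expect_warning(mt <- meshMetrics(flipped), "inward")
  expect_equal(mt@volume, 1000)
})

test_that("binary STL round-trips the mesh up to vertex order", {
  mesh <- osteoplan:::icosphereMesh(7, center = c(1, 2, 3), subdiv = 2)
  f <- withr::local_tempfile(fileext = ".stl")
  writeSTL(mesh, f)
  back <- readSTL(f)
  expect_identical(nrow(faces(back)), nrow(faces(mesh)))
  expect_equal(sort(round(as.vector(vertices(back)), 5)),
               sort(round(as.vector(vertices(mesh)), 5)), tolerance = 1e-4)
  expect_equal(meshMetrics(back)@volume, meshMetrics(mesh)@volume,
               tolerance = 1e-5)
})

test_that("ASCII STL is accepted on read", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid one",
               " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 0 1 0",
               "  endloop", " endfacet",
               "endsolid one"), f)
  m <- readSTL(f)
  expect_identical(nrow(vertices(m)), 3L)
  expect_identical(nrow(faces(m)), 1L)
})

test_that("truncated or inconsistent binary STL files are errors", {
  mesh <- osteoplan:::unitCubeMesh(5)
  f <- withr::local_tempfile(fileext = ".stl")
  writeSTL(mesh, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  half <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw[1:(84 + 5 * 50 + 20)], half)     # cut inside facet 6
  expect_error(readSTL(half), "byte")
  bad <- withr::local_tempfile(fileext = ".stl")
  raw2 <- raw
  raw2[81:84] <- writeBin(5L, raw(), size = 4, endian = "little")  # says 5
  writeBin(raw2, bad)
  expect_error(readSTL(bad), "inconsistent")
})
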