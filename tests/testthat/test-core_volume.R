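test_that("DICOM write/read round-trips HU, spacing, origin and direction", {
  set.seed(11)
  hu <- array(rnorm(16 * 12 * 5, 100, 400) + 0.3, c(16, 12, 5))
  vol <- VoxelVolume(hu, spacing = c(0.4, 0.4, 1.5), origin = c(-12, 3.5, 40))
  dir <- withr::local_tempdir()
  writeDicomSeries(vol, dir)
  expect_length(list.files(dir), 5L)
  back <- readDicomSeries(dir)
  expect_lt(max(abs(voxelData(back) - hu)), 0.5)    # integer HU storage
  expect_lt(max(abs(spacing(back) - spacing(vol))), 1e-6)
  expect_lt(max(abs(origin(back) - origin(vol))), 1e-6)
  expect_lt(max(abs(direction(back) - direction(vol))), 1e-6)
})

test_that("anisotropic CT spacing survives the DICOM round trip", {
  vol <- VoxelVolume(array(-1000, c(6, 6, 4)), spacing = c(0.4, 0.4, 1.5))
  dir <- withr::local_tempdir()
  writeDicomSeries(vol, dir)
  back <- readDicomSeries(dir)
  expect_identical(spacing(back), c(0.4, 0.4, 1.5))
  expect_identical(range(voxelData(back)), c(-1000, -1000))
  expect_length(list.files(dir), 4L)
})

test_that("degenerate or malformed series are rejected with clear errors", {
  vol <- VoxelVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1.5))
  one <- withr::local_tempdir()
  writeDicomSeries(VoxelVolume(array(0, c(4, 4, 1))), one)
  # keep only the single slice
  expect_error(readDicomSeries(one), "single slice")

  six <- VoxelVolume(array(0, c(4, 4, 6)), spacing = c(1, 1, 1.5))
  gap <- withr::local_tempdir()
  writeDicomSeries(six, gap)
  file.remove(file.path(gap, "slice_0003.dcm"))   # one 1.5 mm step becomes 3.0
  expect_error(readDicomSeries(gap), "3\\.0000 mm")

  mixed <- withr::local_tempdir()
  writeDicomSeries(vol, mixed)
  other <- withr::local_tempdir()
  writeDicomSeries(vol, other)
  file.copy(file.path(other, "slice_0001.dcm"),
            file.path(mixed, "slice_9999.dcm"))
  expect_error(readDicomSeries(mixed), "series")

  expect_error(writeDicomSeries(VoxelVolume(array(NaN, c(4, 4, 2))),
                                withr::local_tempdir()), "non-finite")
  expect_error(writeDicomSeries(VoxelVolume(array(1e6, c(4, 4, 2))),
                                withr::local_tempdir()), "16-bit")
})

test_that("missing rescale tags are an error", {
  # hand-build two slices without RescaleSlope/Intercept
  dir <- withr::local_tempdir()
  for (k in 1:2) {
    pix <- writeBin(integer(16), raw(), size = 2, endian = "little")
    meta <- c(
      osteoplan:::.dcmElement(0x0002, 0x0010, "UI",
        osteoplan:::.dcmString("1.2.840.10008.1.2.1", uid = TRUE)))
    meta <- c(osteoplan:::.dcmElement(0x0002, 0x0000, "UL",
                                      osteoplan:::.raw32(length(meta))), meta)
    body <- c(
      osteoplan:::.dcmElement(0x0020, 0x000E, "UI",
        osteoplan:::.dcmString("1.2.3.4", uid = TRUE)),
      osteoplan:::.dcmElement(0x0020, 0x0032, "DS",
        osteoplan:::.dcmString(sprintf("0\\0\\%d", k))),
      osteoplan:::.dcmElement(0x0020, 0x0037, "DS",
        osteoplan:::.dcmString("1\\0\\0\\0\\1\\0")),
      osteoplan:::.dcmElement(0x0028, 0x0010, "US", osteoplan:::.raw16(4)),
      osteoplan:::.dcmElement(0x0028, 0x0011, "US", osteoplan:::.raw16(4)),
      osteoplan:::.dcmElement(0x0028, 0x0030, "DS",
        osteoplan:::.dcmString("1\\1")),
      osteoplan:::.dcmElement(0x7FE0, 0x0010, "OW", pix))
    con <- file(file.path(dir, sprintf("s%d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  expect_error(readDicomSeries(dir), "Rescale")
})

test_that("pydicom independently parses a written series", {
  vol <- VoxelVolume(array(seq(-500, 499, length.out = 8 * 8 * 3), c(8, 8, 3)),
                     spacing = c(0.5, 0.6, 2), origin = c(1, 2, 3))
  dir <- withr::local_tempdir()
  writeDicomSeries(vol, dir)
  script <- paste(
    "import pydicom, sys, json",
    sprintf("ds = pydicom.dcmread('%s')", file.path(dir, "slice_0002.dcm")),
    "hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "print(json.dumps({'shape': list(hu.shape),",
    "  'ps': [float(x) for x in ds.PixelSpacing],",
    "  'ipp': [float(x) for x in ds.ImagePositionPatient],",
    "  'sum': float(hu.sum())}))", sep = "\n")
  out <- system2("python", args = c("-c", shQuote(script)), stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$shape, c(8, 8))                       # rows, cols
  expect_equal(res$ps, c(0.6, 0.5))                      # row, col spacing
  expect_equal(res$ipp, c(1, 2, 5))                      # slice 2 at z0 + sz
  expect_equal(res$sum, sum(round(voxelData(vol)[, , 2])))
})

test_that("the NIfTI alias honours the VoxelVolume contract", {
  arr <- array(rnorm(4 * 5 * 6, 100, 50), c(4, 5, 6))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(0.5, 0.6, 2)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- readNiftiVolume(f)
  expect_equal(spacing(v), c(0.5, 0.6, 2), tolerance = 1e-6)
  expect_identical(voxelData(v), arr)
  expect_lt(max(abs(crossprod(direction(v)) - diag(3))), 1e-6)
})

test_that("voxel/world mapping is affine, invertible, and center-based", {
  th <- 0.3
  R <- rotZ(20)
  vol <- VoxelVolume(array(0, c(8, 7, 6)), spacing = c(0.4, 0.5, 1.5),
                     origin = c(5, -3, 12), direction = R)
  set.seed(4)
  ijk <- matrix(runif(30, 0, 5), ncol = 3)
  back <- worldToVoxel(vol, voxelToWorld(vol, ijk))
  expect_lt(max(abs(back - ijk)), 1e-9)
  expect_equal(as.numeric(voxelToWorld(vol, c(0, 0, 0))), c(5, -3, 12))
})

test_that("container validity catches bad geometry", {
  expect_error(VoxelVolume(array(0, c(2, 2)), spacing = c(1, 1, 1)), "3-D")
  expect_error(VoxelVolume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(VoxelVolume(array(0, c(2, 2, 2)),
                           direction = matrix(1, 3, 3)), "orthonormal")
  vol <- VoxelVolume(array(0, c(3, 3, 3)))
  expect_error(SegmentationMask(array(TRUE, c(2, 3, 3)), vol), "shape")
})
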