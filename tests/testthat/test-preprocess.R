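test_that("minimum filter matches a brute-force window minimum", {
  set.seed(21)
  arr <- array(rnorm(9 * 9 * 3, 200, 500), c(9, 9, 3))
  vol <- VoxelVolume(arr, spacing = c(0.4, 0.4, 1.5))
  out <- voxelData(minimumFilter(vol, 3))
  expect_identical(out, bruteMinFilter(arr, 3))
  out5 <- voxelData(minimumFilter(vol, 5))
  expect_identical(out5, bruteMinFilter(arr, 5))
})

test_that("minimum filter removes isolated metal spikes and keeps constants", {
  arr <- array(0, c(7, 7, 2))
  arr[4, 4, 1] <- 3000
  vol <- VoxelVolume(arr)
  expect_equal(voxelData(minimumFilter(vol, 3))[4, 4, 1], 0)
  const <- VoxelVolume(array(300, c(5, 5, 2)))
  expect_identical(voxelData(minimumFilter(const, 3)), voxelData(const))
  expect_error(minimumFilter(vol, 4), "odd")
})

test_that("minimum filter is monotone and contractive", {
  set.seed(22)
  a <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  b <- a + abs(rnorm(length(a)))          # b >= a pointwise
  fa <- voxelData(minimumFilter(VoxelVolume(a)))
  fb <- voxelData(minimumFilter(VoxelVolume(b)))
  expect_true(all(fa <= a))
  expect_true(all(fa <= fb))
})

test_that("Lanczos resampling hits the target spacing and preserves DC", {
  set.seed(23)
  vol <- VoxelVolume(array(rnorm(10 * 11 * 6, 0, 300), c(10, 11, 6)),
                     spacing = c(0.4, 0.4, 1.5), origin = c(3, -2, 10))
  out <- resampleLanczos(vol)
  expect_identical(spacing(out), c(0.4, 0.4, 0.4))
  const <- resampleLanczos(VoxelVolume(array(123, c(5, 5, 5)),
                                       spacing = c(0.4, 0.4, 1.5)))
  expect_lt(max(abs(voxelData(const) - 123)), 1e-9)
  expect_error(resampleLanczos(vol, targetSpacing = c(0.4, -1, 0.4)),
               "positive")
})

test_that("Lanczos samples equal the direct windowed-sinc sum", {
  set.seed(24)
  arr <- array(rnorm(12 * 10 * 8, 100, 200), c(12, 10, 8))
  spIn <- c(0.4, 0.4, 1.5)
  spOut <- c(0.4, 0.4, 0.4)
  out <- voxelData(resampleLanczos(VoxelVolume(arr, spacing = spIn)))
  for (m in list(c(3, 4, 7), c(5, 2, 11), c(0, 0, 0), c(11, 9, 2))) {
    direct <- lanczosDirectSample(arr, spIn, spOut, m)
    expect_lt(abs(out[m[1] + 1, m[2] + 1, m[3] + 1] - direct), 1e-9)
  }
})

test_that("resampling an isotropic volume at its own spacing is the identity", {
  set.seed(25)
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  vol <- VoxelVolume(arr, spacing = c(0.4, 0.4, 0.4))
  out <- resampleLanczos(vol, c(0.4, 0.4, 0.4))
  expect_identical(dim(out), dim(vol))
  expect_lt(max(abs(voxelData(out) - arr)), 1e-6)
})

test_that("resampling preserves the bounding box within one output voxel", {
  vol <- VoxelVolume(array(0, c(10, 12, 7)), spacing = c(0.4, 0.4, 1.5),
                     origin = c(1, 2, 3))
  out <- resampleLanczos(vol)
  expect_identical(origin(out), origin(vol))
  endIn <- voxelToWorld(vol, dim(vol) - 1)
  endOut <- voxelToWorld(out, dim(out) - 1)
  expect_true(all(abs(endIn - endOut) <= spacing(out) + 1e-9))
})
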