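test_that("dual-threshold mask counts exactly the in-band voxels", {
  set.seed(31)
  arr <- array(sample(c(-1000, 50, 3000), 6 * 6 * 6, replace = TRUE),
               c(6, 6, 6))
  idx <- sample(length(arr), 40)
  arr[idx] <- 1200
  vol <- VoxelVolume(arr)
  m <- thresholdMask(vol, 200, 1700)
  expect_identical(sum(maskData(m)), 40L)
  expect_false(any(maskData(thresholdMask(vol, 5000))))   # above maximum
  expect_error(thresholdMask(vol, 1700, 200), "below")
})

test_that("threshold mask is monotone in the lower threshold", {
  set.seed(32)
  vol <- VoxelVolume(array(rnorm(5^3, 500, 400), c(5, 5, 5)))
  lo <- thresholdMask(vol, 200)
  hi <- thresholdMask(vol, 600)
  expect_true(all(maskData(hi) <= maskData(lo)))
})

test_that("region growing keeps exactly the seeded component", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[7:9, 7:9, 7:9] <- TRUE
  sm <- SegmentationMask(m, VoxelVolume(array(0, c(10, 10, 10))))
  g <- regionGrow(sm, c(2, 2, 2))
  expect_identical(sum(maskData(g)), 27L)
  expect_true(all(maskData(g)[2:4, 2:4, 2:4]))
  full <- SegmentationMask(array(TRUE, c(4, 4, 4)), VoxelVolume(array(0, c(4, 4, 4))))
  expect_identical(maskData(regionGrow(full, c(1, 1, 1))), maskData(full))
  expect_error(regionGrow(sm, c(5.2, 5.2, 5.2)), "no seed lies in a true voxel")
  expect_error(regionGrow(sm, c(50, 0, 0)), "outside")
})

test_that("6- vs 26-connectivity differ exactly on diagonal contacts", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE       # diagonal neighbour only
  sm <- SegmentationMask(m, VoxelVolume(array(0, c(4, 4, 4))))
  expect_identical(sum(maskData(regionGrow(sm, c(1, 1, 1), 6))), 1L)
  expect_identical(sum(maskData(regionGrow(sm, c(1, 1, 1), 26))), 2L)
})

test_that("region growing equals an independent BFS flood fill", {
  set.seed(33)
  for (rep in 1:6) {
    d <- sample(5:20, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.45, d)
    seedIdx <- which(m, arr.ind = TRUE)
    if (nrow(seedIdx) == 0) next
    s <- seedIdx[sample(nrow(seedIdx), 1), , drop = FALSE]
    conn <- sample(c(6, 26), 1)
    sm <- SegmentationMask(m, VoxelVolume(array(0, d)))
    got <- maskData(regionGrow(sm, s - 1, conn))   # spacing 1, origin 0
    want <- bfsFloodFill(m, s, conn)
    expect_identical(got, want)
  }
})

test_that("a plane through the grid midline bisects an all-true mask", {
  vol <- VoxelVolume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
  mask <- SegmentationMask(array(TRUE, c(10, 10, 10)), vol)
  # centers at x = 0..9; midplane between layers 5 and 6 is x = 4.5
  plan <- ResectionPlan(planes = list(list(point = c(4.5, 0, 0),
                                           normal = c(1, 0, 0))))
  kept <- applyResectionPlan(mask, plan, "inside")
  expect_identical(sum(maskData(kept)), 500L)
})

test_that("complementary keep modes partition the mask; trivial cases hold", {
  ph <- smallPhantom()
  mask <- thresholdMask(ph$volume, 200)
  plan <- rightCutPlan()
  inside <- applyResectionPlan(mask, plan, "inside")
  outside <- applyResectionPlan(mask, plan, "outside")
  expect_identical(maskData(inside) | maskData(outside), maskData(mask))
  expect_false(any(maskData(inside) & maskData(outside)))

  big <- ResectionPlan(planes = list(list(point = c(1000, 0, 0),
                                          normal = c(1, 0, 0))))
  expect_identical(maskData(applyResectionPlan(mask, big, "inside")),
                   maskData(mask))
  emptyMask <- SegmentationMask(array(FALSE, dim(mask)), mask)
  expect_false(any(maskData(applyResectionPlan(emptyMask, plan, "inside"))))
})

test_that("swept closed curves select voxel centers by the even-odd rule", {
  vol <- VoxelVolume(array(0, c(10, 10, 6)), spacing = c(1, 1, 1))
  mask <- SegmentationMask(array(TRUE, dim(vol)), vol)
  sq <- rbind(c(1.5, 1.5, 0), c(6.5, 1.5, 0), c(6.5, 6.5, 0),
              c(1.5, 6.5, 0), c(1.5, 1.5, 0))
  plan <- ResectionPlan(curves = list(list(points = sq, axis = "z",
                                           range = c(1, 3), label = "region")))
  kept <- applyResectionPlan(mask, plan, "inside")
  # 5 x 5 centers (x,y in 2..6) over 3 slices (z in 1..3)
  expect_identical(sum(maskData(kept)), 75L)
})

test_that("plan validity rejects open and self-intersecting curves", {
  open <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 2, 0))
  expect_error(ResectionPlan(curves = list(list(points = open, axis = "z",
                                                range = c(0, 1)))), "open")
  bow <- rbind(c(0, 0, 0), c(2, 2, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 0))
  expect_error(ResectionPlan(curves = list(list(points = bow, axis = "z",
                                                range = c(0, 1)))),
               "self-intersect")
  expect_error(ResectionPlan(planes = list(list(point = c(0, 0, 0),
                                                normal = c(0, 0, 0)))),
               "zero")
})

test_that("resection plans round-trip through JSON", {
  sq <- rbind(c(1.5, 1.5, 0), c(6.5, 1.5, 0), c(6.5, 6.5, 0),
              c(1.5, 6.5, 0), c(1.5, 1.5, 0))
  plan <- ResectionPlan(
    curves = list(list(points = sq, axis = "z", range = c(1, 3),
                       label = "right")),
    planes = list(list(point = c(1, 2, 3), normal = c(0, 1, 0),
                       label = "left")))
  f <- withr::local_tempfile(fileext = ".json")
  writeResectionPlan(plan, f)
  back <- readResectionPlan(f)
  expect_equal(back@curves[[1]]$points, plan@curves[[1]]$points)
  expect_equal(back@curves[[1]]$range, plan@curves[[1]]$range)
  expect_equal(back@planes[[1]]$normal, plan@planes[[1]]$normal)
  expect_identical(back@planes[[1]]$label, "left")
})

test_that("largest-component selection drops satellite clutter", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:9, 2:9, 2:9] <- TRUE
  m[11, 11, 11] <- TRUE
  sm <- SegmentationMask(m, VoxelVolume(array(0, c(12, 12, 12))))
  out <- largestComponent(sm)
  expect_identical(sum(maskData(out)), 512L)
  expect_false(maskData(out)[11, 11, 11])
})
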