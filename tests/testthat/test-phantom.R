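test_that("noiseless plate-free phantom HU stay within [air, bone]", {
  ph <- smallPhantom()
  hu <- voxelData(ph$volume)
  expect_gte(min(hu), -1000)
  expect_lte(max(hu), 1200)
})

test_that("equal seeds give bit-identical volumes", {
  spec <- smallSpec(noiseSigma = 10, seed = 123)
  a <- generatePhantom(spec, groundTruth = FALSE)$volume
  b <- generatePhantom(spec, groundTruth = FALSE)$volume
  expect_identical(voxelData(a), voxelData(b))
  c <- generatePhantom(smallSpec(noiseSigma = 10, seed = 124),
                       groundTruth = FALSE)$volume
  expect_false(identical(voxelData(a), voxelData(c)))
})

test_that("bone-label volume agrees with the ground-truth mesh within 5%", {
  ph <- smallPhantom()
  labelVol <- sum(maskData(ph$labels$bone)) * prod(spacing(ph$volume))
  meshVol <- meshMetrics(ph$groundTruth)@volume
  expect_lt(abs(labelVol - meshVol) / meshVol, 0.05)
  expect_true(meshMetrics(ph$groundTruth)@watertight)
})

test_that("thresholding the crisp noiseless phantom recovers the bone label", {
  ph <- generatePhantom(smallSpec(pvBlurSigma = 0, noiseSigma = 0),
                        groundTruth = FALSE)
  mask <- thresholdMask(ph$volume, 200)
  seed <- voxelToWorld(ph$volume,
                       which(maskData(ph$labels$bone), arr.ind = TRUE)[1, ] - 1)
  grown <- regionGrow(mask, seed)
  expect_identical(maskData(grown), maskData(ph$labels$bone))
})

test_that("the upper threshold plus region growing excludes the plate", {
  ph <- generatePhantom(smallSpec(plate = TRUE, noiseSigma = 10, seed = 5),
                        groundTruth = FALSE)
  mask <- thresholdMask(ph$volume, 200, 1700)
  boneIdx <- which(maskData(ph$labels$bone), arr.ind = TRUE)
  seed <- voxelToWorld(ph$volume,
                       boneIdx[which.max(boneIdx[, 3]), ] - 1)
  grown <- regionGrow(mask, seed)
  plate <- maskData(ph$labels$plate)
  expect_gt(sum(plate), 1000)
  keptPlate <- sum(maskData(grown) & plate) / sum(plate)
  expect_lte(keptPlate, 0.01)
  # and the bone itself is still substantially recovered
  expect_gt(sum(maskData(grown) & maskData(ph$labels$bone)) /
              sum(maskData(ph$labels$bone)), 0.8)
})

test_that("voxelizing a cube counts the right number of interior voxels", {
  # generic offset: no cube face coincides with a voxel-center plane
  cube <- osteoplan:::unitCubeMesh(10, center = c(0.13, 0.07, 0.19))
  vol <- voxelizeMesh(cube, spacing = 0.4, blurSigma = 0)
  inside <- sum(voxelData(vol) > (1200 + 40) / 2)
  expect_lt(abs(inside - 1000 / 0.4^3) / (1000 / 0.4^3), 0.02)
  flat <- voxelizeMesh(cube, huInside = 40, huOutside = 40)
  expect_identical(range(voxelData(flat)), c(40, 40))
  open <- TriMesh(vertices(cube), faces(cube)[-1, ])
  expect_error(voxelizeMesh(open), "watertight")
})

test_that("voxelize/extract round trip recovers a 10 mm sphere to < 0.05 mm", {
  sph <- osteoplan:::icosphereMesh(10, subdiv = 4)
  vol <- voxelizeMesh(sph, spacing = 0.4)
  mesh <- extractIsosurface(vol, (1200 + 40) / 2)
  rad <- sqrt(rowSums(vertices(mesh)^2))
  expect_lt(max(abs(rad - 10)), 0.05)
})

test_that("plan-bounded resected volume matches the analytic solid within 3%", {
  ph <- smallPhantom()
  vol <- smallVolumeIso()
  plan <- rightCutPlan()
  midHU <- (1200 + 40) / 2
  ms <- makeModelSet(vol, plan = plan, isoHU = midHU, templateVoxel = 0.3)
  geom <- osteoplan:::phantomGeometry(smallSpec())
  h <- 0.1
  gx <- seq(10, 25, by = h); gy <- seq(-5, 29, by = h); gz <- seq(-5, 21, by = h)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  analytic <- sum(osteoplan:::phantomSDF(geom, pts) <= 0) * h^3
  expect_lt(abs(ms@manifest$vResect - analytic) / analytic, 0.03)
})

test_that("phantom datasets are complete, reloadable, and deterministic", {
  spec <- smallSpec()
  d1 <- withr::local_tempdir()
  files <- writePhantomDataset(spec, d1)
  expect_true(dir.exists(files$dicom))
  nz <- dim(generatePhantom(spec, groundTruth = FALSE)$volume)[3]
  expect_length(list.files(files$dicom), nz)
  back <- readDicomSeries(files$dicom)
  expect_identical(dim(back), dim(smallPhantom()$volume))
  d2 <- withr::local_tempdir()
  files2 <- writePhantomDataset(spec, d2)
  expect_identical(unname(tools::md5sum(files$groundTruth)),
                   unname(tools::md5sum(files2$groundTruth)))
  reloaded <- osteoplan:::specFromList(
    jsonlite::fromJSON(files$spec, simplifyVector = TRUE))
  expect_equal(osteoplan:::specAsList(reloaded), osteoplan:::specAsList(spec))
  labs <- jsonlite::fromJSON(files$labels)
  expect_identical(sum(labs$bone$lengths[labs$bone$values]),
                   sum(maskData(smallPhantom()$labels$bone)))
})

test_that("phantom specs reject impossible HU orderings", {
  expect_error(PhantomSpec(huSoft = 300), "huSoft")
  expect_error(PhantomSpec(huBone = 100), "huBone|huSoft")
  expect_error(PhantomSpec(plate = TRUE, huMetal = 1500), "plate")
  expect_error(PhantomSpec(spacing = c(0, 1, 1)), "spacing")
})
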