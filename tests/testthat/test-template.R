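test_that("mirroring is an involution and an isometry", {
  mesh <- asymmetricMesh()
  pl <- SymmetryPlane(c(1, 2, 3), c(1, 1, 0))
  back <- mirrorMesh(mirrorMesh(mesh, pl), pl)
  expect_lt(max(abs(vertices(back) - vertices(mesh))), 1e-9)
  m0 <- meshMetrics(mesh)
  m1 <- meshMetrics(mirrorMesh(mesh, pl))
  expect_lt(abs(m1@volume - m0@volume) / m0@volume, 1e-9)
  expect_lt(abs(m1@area - m0@area) / m0@area, 1e-9)
  expect_true(m1@watertight)
})

test_that("a vertex at p + 2n reflects to p - 2n", {
  p <- c(4, -1, 2)
  n <- osteoplan:::unitv(c(1, 2, 2))
  tri <- TriMesh(rbind(p + 2 * n, p + 2 * n + c(0.1, 0, 0), p + 2 * n + c(0, 0.1, 0)),
                 matrix(c(1L, 2L, 3L), 1))
  out <- mirrorMesh(tri, SymmetryPlane(p, n))
  expect_lt(max(abs(vertices(out)[1, ] - (p - 2 * n))), 1e-9)
})

test_that("a plane-symmetric surface mirrors onto itself", {
  sph <- osteoplan:::icosphereMesh(8, center = c(0, 5, 5), subdiv = 3)
  pl <- SymmetryPlane(c(0, 0, 0), c(1, 0, 0))
  rep <- deviationMap(mirrorMesh(sph, pl), sph, samplesPerMm2 = 2)
  expect_lt(max(abs(distances(rep))), 1e-6)
})

test_that("the template of a symmetric solid reproduces it within the boolean voxel", {
  sph <- osteoplan:::icosphereMesh(8, center = c(0, 5, 5), subdiv = 3)
  pl <- SymmetryPlane(c(0, 5, 5), c(1, 0, 0))
  tmpl <- buildReconstructionTemplate(sph, pl, voxel = 0.3)
  mt <- meshMetrics(tmpl)
  expect_true(mt@watertight)
  expect_identical(mt@components, 1L)
  rep <- deviationMap(tmpl, sph, samplesPerMm2 = 2)
  expect_lt(max(abs(distances(rep))), 0.3)
})

test_that("the template restores a deleted condyle from the healthy side", {
  # disjoint solids: overlapping shells would break both the volume sum
  # and the parity classification
  mid <- osteoplan:::icosphereMesh(8, subdiv = 3)
  right <- osteoplan:::icosphereMesh(5, center = c(14, 0, 0), subdiv = 3)
  left <- osteoplan:::icosphereMesh(5, center = c(-14, 0, 0), subdiv = 3)
  V <- rbind(vertices(mid), vertices(right), vertices(left))
  F <- rbind(faces(mid), faces(right) + nrow(vertices(mid)),
             faces(left) + nrow(vertices(mid)) + nrow(vertices(right)))
  full <- TriMesh(V, F)
  Vd <- rbind(vertices(mid), vertices(right))
  defect <- TriMesh(Vd, rbind(faces(mid), faces(right) + nrow(vertices(mid))))
  pl <- SymmetryPlane(c(0, 0, 0), c(1, 0, 0))
  tmpl <- buildReconstructionTemplate(defect, pl, healthySide = 1,
                                      voxel = 0.25)
  vFull <- meshMetrics(full)@volume
  expect_lt(abs(meshMetrics(tmpl)@volume - vFull) / vFull, 0.01)
  expect_true(meshMetrics(tmpl)@watertight)
})

test_that("a plane outside the bounding box cannot build a template", {
  sph <- osteoplan:::icosphereMesh(5, subdiv = 2)
  expect_error(buildReconstructionTemplate(sph, SymmetryPlane(c(50, 0, 0),
                                                              c(1, 0, 0))),
               "does not intersect")
})

test_that("groove engraving removes the swept-wedge volume", {
  sph <- osteoplan:::icosphereMesh(8, subdiv = 4)
  plan <- ResectionPlan(planes = list(list(point = c(0, 0, 0),
                                           normal = c(0, 0, 1),
                                           label = "equator")))
  expect_identical(markResectionSites(sph, plan, grooveDepth = 0), sph)
  g <- markResectionSites(sph, plan, voxel = 0.15)
  expect_identical(attr(g, "grooves"), "equator")
  base <- markResectionSites(sph, plan, grooveDepth = 1e-9, voxel = 0.15)
  removed <- meshMetrics(base)@volume - meshMetrics(g)@volume
  expect_gt(removed, 0)
  expect_true(meshMetrics(g)@watertight)
  # independent estimate: integrate the wedge inside the analytic sphere
  h <- 0.02
  xy <- seq(-8.2, 8.2, by = 0.05)
  zz <- seq(-0.45, 0.45, by = h)
  gpts <- expand.grid(x = xy, y = xy, z = zz)
  psi <- 8 - sqrt(gpts$x^2 + gpts$y^2 + gpts$z^2)     # penetration depth
  dd <- 0.6 * pmax(0, 1 - 2 * abs(gpts$z) / 0.8)
  wedge <- sum(psi > 0 & psi <= dd) * 0.05 * 0.05 * h
  expect_lt(abs(removed - wedge) / wedge, 0.08)
})

test_that("a cutter that misses the surface is reported by label", {
  sph <- osteoplan:::icosphereMesh(5, subdiv = 3)
  plan <- ResectionPlan(planes = list(list(point = c(0, 0, 30),
                                           normal = c(0, 0, 1),
                                           label = "floating")))
  expect_error(markResectionSites(sph, plan, voxel = 0.3), "floating")
})

test_that("the phantom model set yields four watertight print models", {
  vol <- smallVolumeIso()
  plan <- rightCutPlan()
  ms <- makeModelSet(vol, plan = plan, templateVoxel = 0.3)
  for (nm in c("modelA", "modelB", "modelC", "modelD")) {
    m <- slot(ms, nm)
    expect_s4_class(m, "TriMesh")
    mt <- meshMetrics(m)
    expect_true(mt@watertight)
    expect_gt(mt@volume, 0)
  }
  expect_identical(ms@manifest$grooves, "right")
  expect_lte(ms@manifest$vResect, ms@manifest$metrics$A$volume)
  expect_gt(ms@manifest$vResect, 0)
  expect_identical(ms@manifest$metrics$D, ms@manifest$metrics$C)
})

test_that("an empty plan still yields models A and B, with a warning", {
  vol <- smallVolumeIso()
  expect_warning(ms <- makeModelSet(vol, templateVoxel = 0.3),
                 "C/D skipped")
  expect_s4_class(ms@modelA, "TriMesh")
  expect_s4_class(ms@modelB, "TriMesh")
  expect_null(ms@modelC)
  expect_null(ms@modelD)
})
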