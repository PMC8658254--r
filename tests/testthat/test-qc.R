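test_that("self-alignment is the identity with sub-micron residual", {
  mesh <- asymmetricMesh()
  tf <- bestFitAlign(mesh, mesh)
  expect_lt(attr(tf, "rms"), 1e-9)
  expect_true(attr(tf, "converged"))
  expect_lt(max(abs(rotation(tf) - diag(3))), 1e-9)
  expect_lt(max(abs(translation(tf))), 1e-9)
})

test_that("a known 5 degree / 3.7 mm pose is recovered to 0.1 deg / 0.01 mm", {
  mesh <- asymmetricMesh()
  R0 <- rotZ(5)
  t0 <- c(2, -1, 3)
  moved <- applyTransform(mesh, RigidTransform(R0, t0))
  tf <- bestFitAlign(moved, mesh, samples = 3000)
  Rres <- rotation(tf) %*% R0
  angErr <- acos(pmin(1, (sum(diag(Rres)) - 1) / 2)) * 180 / pi
  tErr <- sqrt(sum((as.numeric(rotation(tf) %*% t0) + translation(tf))^2))
  expect_lt(angErr, 0.1)
  expect_lt(tErr, 0.01)
  expect_true(attr(tf, "converged"))   # RMS change fell below 0.001 mm
  expect_true(validObject(tf))
})

test_that("alignment is pose-invariant for moderate perturbations", {
  mesh <- asymmetricMesh()
  set.seed(41)
  res <- vapply(1:3, function(i) {
    ang <- runif(1, -10, 10)
    tr <- runif(3, -10, 10)
    moved <- applyTransform(mesh, RigidTransform(rotZ(ang), tr))
    attr(bestFitAlign(moved, mesh), "rms")
  }, 0)
  expect_lt(max(res), 1e-6)
  expect_lt(diff(range(res)), 1e-6)
})

flatSquare <- function(z = 0, half = 10) {
  TriMesh(rbind(c(-half, -half, z), c(half, -half, z),
                c(half, half, z), c(-half, half, z)),
          rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

test_that("identical meshes deviate by exactly zero", {
  mesh <- osteoplan:::icosphereMesh(6, subdiv = 2)
  rep <- deviationMap(mesh, mesh)
  expect_lt(max(abs(distances(rep))), 1e-12)
  expect_identical(fractionWithin(rep), 1)
})

test_that("a +1 mm offset plane reads mean +1, rms 1, and is antisymmetric", {
  nominal <- flatSquare(0)
  measured <- flatSquare(1)
  rep <- deviationMap(measured, nominal, samplesPerMm2 = 2)
  s <- deviationStats(rep)
  expect_equal(s$mean, 1, tolerance = 1e-9)
  expect_equal(s$rms, 1, tolerance = 1e-9)
  back <- deviationMap(nominal, measured, samplesPerMm2 = 2)
  expect_equal(deviationStats(back)$mean, -1, tolerance = 1e-9)
})

test_that("sign convention: a larger concentric sphere is all positive", {
  inner <- osteoplan:::icosphereMesh(10, subdiv = 3)
  outer <- osteoplan:::icosphereMesh(10.5, subdiv = 3)
  rep <- deviationMap(outer, inner, samplesPerMm2 = 2)
  expect_true(all(distances(rep) > 0))
  expect_equal(deviationStats(rep)$mean, 0.5, tolerance = 0.01)
})

test_that("tolerance checks straddle the 0.15 / 0.25 mm bounds correctly", {
  zero <- deviationMap(flatSquare(0), flatSquare(0))
  chk <- toleranceCheck(zero, 0.15)
  expect_true(chk$pass)
  expect_identical(chk$fractionWithin, 1)
  off <- deviationMap(flatSquare(0.2), flatSquare(0), samplesPerMm2 = 2)
  expect_false(toleranceCheck(off, 0.15)$pass)
  expect_true(toleranceCheck(off, 0.25)$pass)
})

test_that("fraction within tolerance is monotone in the tolerance", {
  set.seed(42)
  sph <- osteoplan:::icosphereMesh(8, subdiv = 2)
  bumpy <- TriMesh(vertices(sph) * (1 + runif(nrow(vertices(sph)), 0, 0.03)),
                   faces(sph))
  rep <- deviationMap(bumpy, sph, samplesPerMm2 = 2)
  fr <- vapply(seq(0, 0.4, by = 0.05),
               function(tol) toleranceCheck(rep, tol)$fractionWithin, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("rigid transforms validate orthonormality and handedness", {
  expect_error(RigidTransform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(RigidTransform(refl), "proper")
  tf <- RigidTransform(rotZ(30), c(1, 2, 3))
  p <- matrix(c(1, 0, 0), 1)
  expect_equal(as.numeric(applyTransform(p, tf)),
               as.numeric(rotZ(30) %*% c(1, 0, 0) + c(1, 2, 3)))
})

test_that("deviation reports respect their statistical invariants", {
  set.seed(43)
  sph <- osteoplan:::icosphereMesh(8, subdiv = 2)
  shifted <- applyTransform(sph, RigidTransform(diag(3), c(0.1, 0, 0)))
  rep <- deviationMap(shifted, sph, samplesPerMm2 = 2)
  s <- deviationStats(rep)
  expect_gte(s$rms^2 + 1e-12, s$mean^2)
  expect_gte(s$max, s$mean)
  expect_gte(s$mean, s$min)
  expect_gte(fractionWithin(rep), 0)
  expect_lte(fractionWithin(rep), 1)
})
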