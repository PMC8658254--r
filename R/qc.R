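#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 vector (mm).
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Apply a rigid transform
#'
#' @param x a \linkS4class{TriMesh} or an n x 3 point matrix.
#' @param transform a \linkS4class{RigidTransform}, applied as
#'   \code{R x + t}.
#' @return The transformed mesh or points.
#' @export
applyTransform <- function(x, transform) {
  stopifnot(is(transform, "RigidTransform"))
  if (is(x, "TriMesh"))
    return(TriMesh(applyTransform(vertices(x), transform), faces(x)))
  sweep(rbindVec(x) %*% t(transform@rotation), 2, transform@translation, `+`)
}

# area-weighted uniform surface sampling (n points) under a fixed seed
sampleSurface <- function(mesh, n, seed = NULL) {
  u <- withSeed(seed, matrix(runif(3 * n), ncol = 3))
  cpp_sample_surface(vertices(mesh), faces(mesh), u)
}

.kabsch <- function(P, X) {
  pbar <- colMeans(P); xbar <- colMeans(X)
  H <- crossprod(sweep(P, 2, pbar, `-`), sweep(X, 2, xbar, `-`))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(xbar - R %*% pbar))
}

.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + .skew(w))
  K <- .skew(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.skew <- function(w) {
  matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
}

# one linearized point-to-plane update: minimize sum(((Q + w x Q + dt) - cp) . n)^2
.pointToPlaneStep <- function(Q, cp, n) {
  r <- rowSums((Q - cp) * n)
  A <- cbind(Q[, 2] * n[, 3] - Q[, 3] * n[, 2],
             Q[, 3] * n[, 1] - Q[, 1] * n[, 3],
             Q[, 1] * n[, 2] - Q[, 2] * n[, 1],
             n)
  x <- tryCatch(qr.solve(qr(A), -r), error = function(e) rep(0, 6))
  list(R = .rodrigues(x[1:3]), t = x[4:6])
}

.faceNormals <- function(mesh) {
  V <- vertices(mesh); F <- faces(mesh)
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Best-fit rigid alignment (iterative closest point)
#'
#' Iterative closest point with closest-point correspondences: the moving
#' mesh is sampled uniformly by area, each sample is matched to its closest
#' point on the fixed surface (uniform-grid spatial index with pseudonormal
#' sign handling), and the rigid update each iteration minimizes the
#' point-to-plane residual (distances projected on the nominal surface
#' normals, the minimizer industrial inspection best-fits use, which
#' converges far faster than the point-to-point update near the optimum; a
#' Kabsch point-to-point step is the fallback if the linearized solve is
#' degenerate). Iterations stop when the RMS change between successive
#' iterations falls below \code{tol} (default 0.001 mm, the convergence
#' accuracy of the inspection-software best-fit this mirrors) or
#' \code{maxIter} is reached. The initial pose is chosen from identity,
#' centroid-matching and principal-axes candidates by lowest starting RMS.
#'
#' @param moving,fixed non-empty \linkS4class{TriMesh}es of the same object.
#' @param tol convergence tolerance on the inter-iteration RMS change (mm).
#' @param maxIter iteration cap.
#' @param samples number of surface samples of the moving mesh.
#' @param seed RNG seed for the surface sampling (reproducibility).
#' @return A \linkS4class{RigidTransform} mapping moving onto fixed, with
#'   attributes \code{rms} (mm), \code{iterations} and \code{converged}.
#' @export
bestFitAlign <- function(moving, fixed, tol = 0.001, maxIter = 200,
                         samples = 2000, seed = 1) {
  stopifnot(is(moving, "TriMesh"), is(fixed, "TriMesh"))
  if (nrow(faces(moving)) == 0L || nrow(faces(fixed)) == 0L)
    stop("empty mesh")
  P <- sampleSurface(moving, samples, seed = seed)
  Vf <- vertices(fixed); Ff <- faces(fixed)
  Nf <- .faceNormals(fixed)
  fixedIndex <- cpp_mesh_index(Vf, Ff)
  nProbe <- min(500L, nrow(P))
  probe <- P[seq_len(nProbe), , drop = FALSE]
  Xf <- sampleSurface(fixed, nProbe, seed = if (is.null(seed)) NULL else seed + 1)
  cands <- list(list(R = diag(3), t = c(0, 0, 0)),
                list(R = diag(3), t = colMeans(Xf) - colMeans(probe)))
  pc <- tryCatch(prcomp(P)$rotation, error = function(e) NULL)
  fc <- tryCatch(prcomp(Xf)$rotation, error = function(e) NULL)
  if (!is.null(pc) && !is.null(fc)) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      Rf <- fc %*% diag(c(s1, s2, 1)) %*% t(pc)
      if (det(Rf) < 0) Rf <- fc %*% diag(c(s1, s2, -1)) %*% t(pc)
      cands[[length(cands) + 1]] <-
        list(R = Rf, t = colMeans(Xf) - as.numeric(Rf %*% colMeans(probe)))
    }
  }
  rms0 <- vapply(cands, function(cd) {
    Q <- sweep(probe %*% t(cd$R), 2, cd$t, `+`)
    sqrt(mean(cpp_mesh_index_query(fixedIndex, Q)$distance^2))
  }, 0)
  best <- cands[[which.min(rms0)]]
  R <- best$R; tv <- best$t
  rmsPrev <- Inf
  rms <- NA_real_
  rising <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    Q <- sweep(P %*% t(R), 2, tv, `+`)
    cc <- cpp_mesh_index_query(fixedIndex, Q)
    rms <- sqrt(mean(cc$distance^2))
    if (is.finite(rmsPrev)) {
      if (abs(rmsPrev - rms) < tol) { converged <- TRUE; break }
      rising <- if (rms > rmsPrev + 1e-12) rising + 1L else 0L
      if (rising >= 10L)
        stop("ICP diverging (RMS rising for 10 iterations); provide a better initial pose")
    }
    step <- .pointToPlaneStep(Q, cc$closest, Nf[cc$face, , drop = FALSE])
    if (all(step$t == 0) && max(abs(step$R - diag(3))) == 0) {
      fit <- .kabsch(P, cc$closest)
      R <- fit$R; tv <- fit$t
    } else {
      R <- step$R %*% R
      tv <- as.numeric(step$R %*% tv) + step$t
    }
    rmsPrev <- rms
  }
  out <- RigidTransform(R, tv)
  attr(out, "rms") <- rms
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Signed deviation map between a measured and a nominal surface
#'
#' The measured mesh is transformed, sampled uniformly by area
#' (\code{samplesPerMm2} samples per mm^2), and each sample's signed
#' distance to the nominal surface is computed (positive = outside the
#' nominal outward normal at the closest point). Summary statistics and the
#' fraction of samples within the tolerance band are reported; this is the
#' numerical content of an inspection-software 3-D deviation map.
#'
#' @param measured,nominal \linkS4class{TriMesh}es.
#' @param transform optional \linkS4class{RigidTransform} (e.g. from
#'   \code{\link{bestFitAlign}}); identity if NULL.
#' @param samplesPerMm2 sampling density (default 4).
#' @param tolerance tolerance band half-width in mm (default 0.15, the shape
#'   tolerance the printed models are held to).
#' @param seed RNG seed for sampling.
#' @param maxSamples cap on the sample count.
#' @return A \linkS4class{DeviationReport}.
#' @export
deviationMap <- function(measured, nominal, transform = NULL,
                         samplesPerMm2 = 4, tolerance = 0.15, seed = 1,
                         maxSamples = 200000) {
  stopifnot(is(measured, "TriMesh"), is(nominal, "TriMesh"))
  if (nrow(faces(nominal)) == 0L) stop("degenerate nominal mesh")
  if (is.null(transform)) transform <- RigidTransform()
  moved <- applyTransform(measured, transform)
  area <- cpp_mesh_vol_area(vertices(moved), faces(moved))[2]
  n <- min(maxSamples, max(200L, as.integer(round(area * samplesPerMm2))))
  S <- sampleSurface(moved, n, seed = seed)
  d <- cpp_signed_distance(vertices(nominal), faces(nominal), S)$distance
  stats <- list(min = min(d), max = max(d), mean = mean(d),
                rms = sqrt(mean(d^2)),
                p95_abs = unname(quantile(abs(d), 0.95)))
  new("DeviationReport", transform = transform, distances = d, samples = S,
      stats = stats, tolerance = tolerance,
      fractionWithin = mean(abs(d) <= tolerance))
}

#' Check a deviation report against a tolerance
#'
#' Pass requires every sample within the band: \code{max |d| <= tol}. The
#' within-band fraction is recomputed at the given tolerance, so a report
#' made at the model tolerance (0.15 mm) can be re-checked at the clinical
#' planning bound (0.25 mm).
#'
#' @param report a \linkS4class{DeviationReport}.
#' @param tol tolerance half-width in mm.
#' @return list(pass, fractionWithin, maxAbs).
#' @export
toleranceCheck <- function(report, tol = report@tolerance) {
  stopifnot(is(report, "DeviationReport"))
  d <- report@distances
  list(pass = max(abs(d)) <= tol, fractionWithin = mean(abs(d) <= tol),
       maxAbs = max(abs(d)))
}
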