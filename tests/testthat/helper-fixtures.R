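# Shared fixtures and independent oracles. Expensive fixtures are memoized
# for the duration of the test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# compact mandible-like phantom spec used across test files
smallSpec <- function(...) {
  args <- list(arcWidth = 40, arcDepth = 24, tubeRadius = 4,
               ramusHeight = 16, ramusRadius = 3, condyleRadius = 4.5,
               noiseSigma = 0, gtResolution = 0.25, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(PhantomSpec, args)
}

smallPhantom <- function() memo("smallPhantom", generatePhantom(smallSpec()))

smallVolumeIso <- function() memo("smallVolumeIso", {
  resampleLanczos(smallPhantom()$volume)
})

# asymmetric compound mesh (three spheres): no rotational symmetry, so a
# rigid pose is fully observable
asymmetricMesh <- function() memo("asymmetricMesh", {
  a <- osteoplan:::icosphereMesh(10, subdiv = 3)
  b <- osteoplan:::icosphereMesh(5, center = c(13, 0, 0), subdiv = 3)
  c <- osteoplan:::icosphereMesh(3, center = c(0, 12, 2), subdiv = 3)
  V <- rbind(vertices(a), vertices(b), vertices(c))
  F <- rbind(faces(a), faces(b) + nrow(vertices(a)),
             faces(c) + nrow(vertices(a)) + nrow(vertices(b)))
  TriMesh(V, F)
})

rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# brute-force per-slice window minimum (independent of the implementation)
bruteMinFilter <- function(arr, w) {
  d <- dim(arr)
  h <- w %/% 2
  out <- arr
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        ii <- max(1, i - h):min(d[1], i + h)
        jj <- max(1, j - h):min(d[2], j + h)
        out[i, j, k] <- min(arr[ii, jj, k])
      }
  out
}

# breadth-first flood fill on a logical array from 1-based seed voxels
bfsFloodFill <- function(mask, seeds, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  out <- array(FALSE, d)
  queue <- seeds[mask[seeds], , drop = FALSE]
  out[queue] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      qm <- matrix(q, 1)
      if (mask[qm] && !out[qm]) {
        out[qm] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  out
}

# direct separable windowed-sinc sum for one output sample, with per-axis
# weight renormalization and clamp-to-edge indexing
lanczosDirectSample <- function(arr, spacingIn, spacingOut, m, a = 3) {
  d <- dim(arr)
  axW <- vector("list", 3)
  axK <- vector("list", 3)
  for (ax in 1:3) {
    u <- m[ax] * spacingOut[ax] / spacingIn[ax]
    ks <- (floor(u) - a + 1):(floor(u) + a)
    w <- vapply(ks, function(k) {
      t <- u - k
      if (abs(t) >= a) return(0)
      s1 <- if (t == 0) 1 else sin(pi * t) / (pi * t)
      s2 <- if (t == 0) 1 else sin(pi * t / a) / (pi * t / a)
      s1 * s2
    }, 0)
    axW[[ax]] <- w / sum(w)
    axK[[ax]] <- pmin(pmax(ks, 0), d[ax] - 1) + 1
  }
  acc <- 0
  for (i3 in seq_along(axK[[3]]))
    for (i2 in seq_along(axK[[2]]))
      for (i1 in seq_along(axK[[1]]))
        acc <- acc + axW[[1]][i1] * axW[[2]][i2] * axW[[3]][i3] *
          arr[axK[[1]][i1], axK[[2]][i2], axK[[3]][i3]]
  acc
}

# single-plane resection plan cutting the right side of the small phantom
rightCutPlan <- function(x0 = 10) {
  ResectionPlan(planes = list(list(point = c(x0, 0, 0),
                                   normal = c(-1, 0, 0), label = "right")))
}
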