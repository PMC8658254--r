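# small geometry helpers shared across modules

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector where a direction was expected")
  v / n
}

# O(n^2) proper segment-intersection test for a closed 2-D polygon given
# without the repeated last point; shared endpoints of adjacent segments are
# not intersections
.polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (.segmentsCross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

.segmentsCross <- function(p1, p2, q1, q2) {
  d1 <- .orient2d(q1, q2, p1)
  d2 <- .orient2d(q1, q2, p2)
  d3 <- .orient2d(p1, p2, q1)
  d4 <- .orient2d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# orthonormal frame with e1 = n; columns e1, e2, e3, det +1
planeBasis <- function(n) {
  e1 <- unitv(n)
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- unitv(ref - sum(ref * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}
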