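#' Construct a resection plan
#'
#' @param curves list of cutting curves, each
#'   \code{list(points, axis, range, label)}: \code{points} a closed n x 3
#'   polyline in patient mm (first row equals the last), \code{axis} the
#'   sweep axis ("x", "y" or "z"; curves are drawn on 2-D slices and swept
#'   along the slice axis), \code{range} the mm interval along that axis,
#'   \code{label} e.g. "right"/"left".
#' @param planes list of cutting planes, each
#'   \code{list(point, normal, label)}; the kept ("inside") side is where
#'   \code{(x - point) . normal <= 0}. Normals are normalized here; a zero
#'   normal is an error.
#' @return A \linkS4class{ResectionPlan}.
#' @export
ResectionPlan <- function(curves = list(), planes = list()) {
  curves <- lapply(curves, function(cv) {
    cv$points <- as.matrix(cv$points)
    if (is.null(cv$label)) cv$label <- "region"
    cv$range <- as.numeric(cv$range)
    cv
  })
  planes <- lapply(planes, function(pl) {
    pl$normal <- unitv(as.numeric(pl$normal))
    pl$point <- as.numeric(pl$point)
    if (is.null(pl$label)) pl$label <- "region"
    pl
  })
  new("ResectionPlan", curves = curves, planes = planes)
}

setMethod("show", "ResectionPlan", function(object) {
  cat(sprintf("ResectionPlan: %d curve(s), %d plane(s)\n",
              length(object@curves), length(object@planes)))
})

planIsEmpty <- function(plan) {
  is.null(plan) ||
    (length(plan@curves) == 0L && length(plan@planes) == 0L)
}

# Signed inside-positive field (mm) of the plan region at world points:
# union of swept-curve interiors intersected with plane half-spaces.
# Zero on the boundary, so `>= 0` gives boundary-inclusive membership.
planRegionField <- function(plan, pts) {
  pts <- rbindVec(pts)
  f <- NULL
  if (length(plan@curves)) {
    fc <- rep(-Inf, nrow(pts))
    for (cv in plan@curves) {
      ax <- match(cv$axis, c("x", "y", "z"))
      t <- pts[, ax]
      slab <- pmin(t - cv$range[1], cv$range[2] - t)
      poly <- cv$points[, -ax, drop = FALSE]
      p2 <- pts[, -ax, drop = FALSE]
      inside <- cpp_points_in_polygon(p2, poly[-nrow(poly), , drop = FALSE])
      dpoly <- cpp_dist_to_polyline2d(p2, poly)
      inplane <- ifelse(inside, dpoly, -dpoly)
      fc <- pmax(fc, pmin(inplane, slab))
    }
    f <- fc
  }
  for (pl in plan@planes) {
    fp <- -(sweep(pts, 2, pl$point, `-`) %*% pl$normal)[, 1]
    f <- if (is.null(f)) fp else pmin(f, fp)
  }
  if (is.null(f)) stop("resection plan is empty")
  f
}

#' Clip a segmentation mask with a resection plan
#'
#' Separates resected from retained bone: voxels whose centers fall inside
#' the plan region (within the swept closed curves and on the kept side of
#' every cutting plane) are retained with \code{keep = "inside"}, or removed
#' with \code{keep = "outside"}. Boundary voxel centers count as inside, so
#' the two keep modes partition the input mask exactly.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param plan a non-empty \linkS4class{ResectionPlan}.
#' @param keep "inside" or "outside".
#' @return A \linkS4class{SegmentationMask}, a subset of the input.
#' @export
applyResectionPlan <- function(mask, plan, keep = c("inside", "outside")) {
  stopifnot(is(mask, "SegmentationMask"), is(plan, "ResectionPlan"))
  keep <- match.arg(keep)
  if (planIsEmpty(plan)) stop("resection plan is empty")
  validObject(plan)
  d <- dim(mask)
  m <- maskData(mask)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- m[, , k]
    if (!any(sl)) next
    f <- planRegionField(plan, slabWorldCoords(mask, k - 1))
    region <- matrix(f >= 0, d[1], d[2])
    out[, , k] <- if (keep == "inside") sl & region else sl & !region
  }
  SegmentationMask(out, mask)
}

#' Read/write a resection plan as JSON
#'
#' Plan files carry \code{curves} (point arrays in patient mm, sweep axis,
#' mm range, label) and \code{planes} (point, normal, label).
#'
#' @param path JSON file path.
#' @param plan a \linkS4class{ResectionPlan}.
#' @return \code{readResectionPlan}: a \linkS4class{ResectionPlan};
#'   \code{writeResectionPlan}: the path, invisibly.
#' @export
readResectionPlan <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  curves <- lapply(x$curves, function(cv) {
    pts <- cv$points
    pts <- if (is.matrix(pts)) pts else do.call(rbind, lapply(pts, as.numeric))
    list(points = pts, axis = cv$axis,
         range = as.numeric(unlist(cv$range)), label = cv$label)
  })
  planes <- lapply(x$planes, function(pl)
    list(point = as.numeric(unlist(pl$point)),
         normal = as.numeric(unlist(pl$normal)), label = pl$label))
  ResectionPlan(curves = curves, planes = planes)
}

#' @rdname readResectionPlan
#' @export
writeResectionPlan <- function(plan, path) {
  stopifnot(is(plan, "ResectionPlan"))
  x <- list(
    curves = lapply(plan@curves, function(cv)
      list(points = apply(cv$points, 1, as.numeric, simplify = FALSE),
           axis = cv$axis, range = cv$range, label = cv$label)),
    planes = lapply(plan@planes, function(pl)
      list(point = pl$point, normal = pl$normal, label = pl$label)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
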