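# Minimal single-frame CT DICOM series I/O (explicit/implicit VR little
# endian, uncompressed). Covers exactly the geometry and rescale tags the
# modelling chain needs; not a general DICOM toolkit.

.uidRoot <- "1.2.826.0.1.3680043.10.424."
.osteoplanState <- new.env(parent = emptyenv())
.osteoplanState$seriesCounter <- 0L

.shortVRs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
               "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
               "US")

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32 <- function(raw, pos) {
  as.integer(raw[pos]) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}
.raw16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.raw32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcmString <- function(x, uid = FALSE) {
  r <- charToRaw(x)
  if (length(r) %% 2 == 1) r <- c(r, if (uid) as.raw(0) else charToRaw(" "))
  r
}

.dcmElement <- function(group, element, vr, value) {
  tag <- c(.raw16(group), .raw16(element))
  if (vr %in% .shortVRs) {
    c(tag, charToRaw(vr), .raw16(length(value)), value)
  } else {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), .raw32(length(value)), value)
  }
}

.ds <- function(x) paste(vapply(x, function(v) sprintf("%.10g", v), ""),
                         collapse = "\\")

#' Write a voxel volume as a DICOM CT series
#'
#' One explicit-VR little-endian file per slice with consistent geometry
#' tags (ImagePositionPatient, ImageOrientationPatient, PixelSpacing) and a
#' rescale pair chosen so the HU values are recovered on read (slope 1,
#' intercept 0, signed 16-bit storage, values rounded to integer HU).
#'
#' @param volume a \linkS4class{VoxelVolume}; HU must be finite and within
#'   the signed 16-bit range.
#' @param path output directory (created if needed).
#' @return Invisibly, the written file paths in slice order.
#' @export
writeDicomSeries <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  hu <- voxelData(volume)
  if (any(!is.finite(hu)))
    stop("volume contains non-finite HU values; cannot write DICOM")
  if (min(hu) < -32768 || max(hu) > 32767)
    stop("HU values outside the signed 16-bit storable range")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume)
  sp <- spacing(volume)
  D <- direction(volume)
  .osteoplanState$seriesCounter <- .osteoplanState$seriesCounter + 1L
  studyUID <- paste0(.uidRoot, "1.1")
  seriesUID <- paste0(.uidRoot, "2.", .osteoplanState$seriesCounter)
  sopClass <- "1.2.840.10008.5.1.4.1.1.2"   # CT Image Storage
  tsUID <- "1.2.840.10008.1.2.1"            # explicit VR little endian
  iop <- .ds(c(D[, 1], D[, 2]))
  pixSpacing <- .ds(c(sp[2], sp[1]))        # row spacing first, then column
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    sopUID <- paste0(seriesUID, ".", k)
    ipp <- voxelToWorld(volume, c(0, 0, k - 1))[1, ]
    slice <- hu[, , k]
    stored <- as.integer(round(as.vector(slice)))   # i fastest == column fastest
    pix <- writeBin(stored, raw(), size = 2, endian = "little")
    meta <- c(
      .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcmElement(0x0002, 0x0002, "UI", .dcmString(sopClass, uid = TRUE)),
      .dcmElement(0x0002, 0x0003, "UI", .dcmString(sopUID, uid = TRUE)),
      .dcmElement(0x0002, 0x0010, "UI", .dcmString(tsUID, uid = TRUE)),
      .dcmElement(0x0002, 0x0012, "UI", .dcmString(paste0(.uidRoot, "0.1"),
                                                   uid = TRUE)))
    meta <- c(.dcmElement(0x0002, 0x0000, "UL", .raw32(length(meta))), meta)
    body <- c(
      .dcmElement(0x0008, 0x0016, "UI", .dcmString(sopClass, uid = TRUE)),
      .dcmElement(0x0008, 0x0018, "UI", .dcmString(sopUID, uid = TRUE)),
      .dcmElement(0x0008, 0x0060, "CS", .dcmString("CT")),
      .dcmElement(0x0020, 0x000D, "UI", .dcmString(studyUID, uid = TRUE)),
      .dcmElement(0x0020, 0x000E, "UI", .dcmString(seriesUID, uid = TRUE)),
      .dcmElement(0x0020, 0x0013, "IS", .dcmString(as.character(k))),
      .dcmElement(0x0020, 0x0032, "DS", .dcmString(.ds(ipp))),
      .dcmElement(0x0020, 0x0037, "DS", .dcmString(iop)),
      .dcmElement(0x0028, 0x0002, "US", .raw16(1)),
      .dcmElement(0x0028, 0x0004, "CS", .dcmString("MONOCHROME2")),
      .dcmElement(0x0028, 0x0010, "US", .raw16(d[2])),   # Rows = ny
      .dcmElement(0x0028, 0x0011, "US", .raw16(d[1])),   # Columns = nx
      .dcmElement(0x0028, 0x0030, "DS", .dcmString(pixSpacing)),
      .dcmElement(0x0018, 0x0050, "DS", .dcmString(.ds(sp[3]))),
      .dcmElement(0x0028, 0x0100, "US", .raw16(16)),
      .dcmElement(0x0028, 0x0101, "US", .raw16(16)),
      .dcmElement(0x0028, 0x0102, "US", .raw16(15)),
      .dcmElement(0x0028, 0x0103, "US", .raw16(1)),
      .dcmElement(0x0028, 0x1052, "DS", .dcmString(.ds(0))),
      .dcmElement(0x0028, 0x1053, "DS", .dcmString(.ds(1))),
      .dcmElement(0x7FE0, 0x0010, "OW", pix))
    f <- file.path(path, sprintf("slice_%04d.dcm", k))
    con <- file(f, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    files[k] <- f
  }
  invisible(files)
}

# parse one DICOM file, returning a named list of the tags we use
.readDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", path))
  pos <- 133L
  ts <- NULL
  out <- list()
  explicitMeta <- TRUE
  repeat {
    if (pos + 8L > length(raw)) break
    group <- .u16(raw, pos)
    element <- .u16(raw, pos + 2L)
    inMeta <- group == 0x0002
    explicit <- if (inMeta) TRUE else !identical(ts, "1.2.840.10008.1.2")
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .shortVRs) {
        len <- .u16(raw, pos + 6L)
        vstart <- pos + 8L
      } else {
        len <- .u32(raw, pos + 8L)
        vstart <- pos + 12L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, pos + 4L)
      vstart <- pos + 8L
    }
    val <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr, value = val)
    if (inMeta && element == 0x0010)
      ts <- trimws(rawToChar(val[val != as.raw(0)]))
    pos <- vstart + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop(sprintf("unsupported transfer syntax '%s' in '%s'", ts, path))
  out$..ts <- ts
  out$..path <- path
  out
}

.tagString <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v$value[v$value != as.raw(0)]))
}
.tagDS <- function(el, key) {
  s <- .tagString(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.tagUS <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  .u16(v$value, 1L)
}

#' Read a DICOM CT series as a VoxelVolume
#'
#' Reads every DICOM file in a directory, checks that they form exactly one
#' CT series with uniform in-plane spacing and a uniform slice step, sorts
#' the slices along the stack normal, and returns HU values
#' (slope * stored + intercept). The slice spacing is derived from the
#' inter-slice distance of ImagePositionPatient, not from the SliceThickness
#' tag, because acquired and reconstructed slice widths differ.
#'
#' @param path directory containing one CT series.
#' @return A \linkS4class{VoxelVolume} in HU.
#' @export
readDicomSeries <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such directory: '%s'", path))
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop(sprintf("no files in '%s'", path))
  slices <- lapply(sort(files), .readDicomFile)
  if (length(slices) == 1L)
    stop("directory contains a single slice; cannot establish slice spacing")
  uids <- vapply(slices, .tagString, "", key = "0020,000E")
  if (length(unique(uids)) != 1L)
    stop(sprintf("directory mixes %d series (SeriesInstanceUID not unique)",
                 length(unique(uids))))
  iop <- .tagDS(slices[[1]], "0020,0037")
  ps <- .tagDS(slices[[1]], "0028,0030")
  if (is.null(iop) || is.null(ps))
    stop("missing geometry tags (ImageOrientationPatient / PixelSpacing)")
  for (s in slices[-1]) {
    if (max(abs(.tagDS(s, "0028,0030") - ps)) > 1e-6)
      stop("non-uniform in-plane pixel spacing across the series")
    if (max(abs(.tagDS(s, "0020,0037") - iop)) > 1e-6)
      stop("inconsistent slice orientation across the series")
  }
  rowdir <- iop[1:3]
  coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  ipps <- t(vapply(slices, .tagDS, numeric(3), key = "0020,0032"))
  proj <- as.vector(ipps %*% normal)
  ord <- order(proj)
  slices <- slices[ord]
  ipps <- ipps[ord, , drop = FALSE]
  proj <- proj[ord]
  steps <- diff(proj)
  med <- stats::median(steps)
  bad <- which(abs(steps - med) > 1e-3)
  if (length(bad))
    stop(sprintf(paste0("non-uniform slice step: gap between sorted slices ",
                        "%d and %d is %.4f mm (expected %.4f mm)"),
                 bad[1], bad[1] + 1L, steps[bad[1]], med))
  slope <- .tagDS(slices[[1]], "0028,1053")
  intercept <- .tagDS(slices[[1]], "0028,1052")
  if (is.null(slope) || is.null(intercept))
    stop("missing RescaleSlope/RescaleIntercept; cannot recover HU")
  rows <- .tagUS(slices[[1]], "0028,0010")
  cols <- .tagUS(slices[[1]], "0028,0011")
  signed <- isTRUE(.tagUS(slices[[1]], "0028,0103") == 1L)
  nz <- length(slices)
  data <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    pix <- slices[[k]][["7FE0,0010"]]
    if (is.null(pix)) stop("slice without PixelData")
    stored <- readBin(pix$value, "integer", n = rows * cols, size = 2,
                      signed = signed, endian = "little")
    data[, , k] <- slope * stored + intercept
  }
  # PixelSpacing is (row spacing, column spacing) = (sy, sx)
  VoxelVolume(data, spacing = c(ps[2], ps[1], mean(steps)),
              origin = ipps[1, ],
              direction = cbind(rowdir, coldir, normal, deparse.level = 0))
}

#' Read a NIfTI-1 volume as a VoxelVolume
#'
#' Convenience alias with the same container contract as
#' \code{\link{readDicomSeries}}; the NIfTI RAS frame is converted to the
#' package's DICOM-native LPS frame.
#'
#' @param path a .nii or .nii.gz file.
#' @return A \linkS4class{VoxelVolume}.
#' @export
readNiftiVolume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("readNiftiVolume requires the RNifti package")
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  m[1:2, ] <- -m[1:2, ]          # RAS -> LPS
  A <- m[1:3, 1:3]
  sp <- sqrt(colSums(A^2))
  VoxelVolume(array(as.numeric(img), dim(img)[1:3]), spacing = sp,
              origin = m[1:3, 4], direction = sweep(A, 2, sp, `/`))
}
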