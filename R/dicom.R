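# Minimal single-frame CT DICOM I/O (Explicit VR Little Endian only).
# Covers exactly the header fields the pipeline consumes: Rows, Columns,
# PixelSpacing, SliceThickness, RescaleSlope/Intercept, InstanceNumber,
# ImagePositionPatient/SliceLocation and PixelData. One file per axial slice.

.UID_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
.UID_ROOT <- "1.2.826.0.1.3680043.10.1462"  # deterministic synthetic root

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# one data element in Explicit VR LE; value must already be a raw vector
.dcm_element <- function(group, element, vr, value) {
  if (length(value) %% 2L == 1L) {  # values must have even length
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value <- c(value, pad)
  }
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), .u32(length(value)), value)
  } else {
    c(head, .u16(length(value)), value)
  }
}

.dcm_str <- function(group, element, vr, s) {
  .dcm_element(group, element, vr, charToRaw(as.character(s)))
}
.dcm_us <- function(group, element, x) {
  .dcm_element(group, element, "US", .u16(x))
}
# decimal string with enough digits for a tolerance-bounded round trip
.ds <- function(x) paste(formatC(x, format = "g", digits = 10), collapse = "\\")

#' Write a CT DICOM series
#'
#' Writes one single-frame DICOM file per slice (Explicit VR Little Endian)
#' into `directory`, encoding the geometry and HU calibration carried by the
#' [VolumeGrid] metadata. Stored pixel values are
#' `(HU - rescale_intercept) / rescale_slope`, rounded and written as signed
#' 16-bit integers, so [readDicomSeries()] reproduces the voxel array
#' exactly for integer-valued HU volumes. File names encode the slice index
#' (`slice_0007.dcm`) and are lexically sortable.
#'
#' @param volume a [VolumeGrid].
#' @param directory output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @seealso [readDicomSeries()]
#' @examples
#' dir <- file.path(tempdir(), "dcm-example")
#' v <- volumeGrid(array(c(-1000, 0, 1200, 50), c(2, 2, 1)))
#' writeDicomSeries(v, dir)
#' identical(voxels(readDicomSeries(dir)), voxels(v))
#' @export
writeDicomSeries <- function(volume, directory) {
  stopifnot(is(volume, "VolumeGrid"))
  validObject(volume)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .stopf("cannot create directory '%s'", directory)
  }
  m <- sliceMeta(volume)
  v <- voxels(volume)
  files <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    mi <- m[i, ]
    z <- mi$slice_index * mi$slice_thickness
    uid <- paste(.UID_ROOT, mi$rows, mi$cols, mi$slice_index + 1L, sep = ".")
    stored <- .round_half_away((v[, , i] - mi$rescale_intercept) / mi$rescale_slope)
    if (any(stored < -32768 | stored > 32767)) {
      .stopf("slice %d: stored values exceed the signed 16-bit range",
             mi$slice_index)
    }
    pix <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")

    meta_elems <- c(
      .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      .dcm_str(0x0002, 0x0002, "UI", .UID_CT_STORAGE),
      .dcm_str(0x0002, 0x0003, "UI", uid),
      .dcm_str(0x0002, 0x0010, "UI", .UID_TS_EXPLICIT_LE))
    dataset <- c(
      .dcm_str(0x0008, 0x0016, "UI", .UID_CT_STORAGE),
      .dcm_str(0x0008, 0x0018, "UI", uid),
      .dcm_str(0x0008, 0x0060, "CS", "CT"),
      .dcm_str(0x0018, 0x0050, "DS", .ds(mi$slice_thickness)),
      .dcm_str(0x0020, 0x0013, "IS", as.character(mi$slice_index + 1L)),
      .dcm_str(0x0020, 0x0032, "DS", .ds(c(0, 0, z))),
      .dcm_str(0x0020, 0x1041, "DS", .ds(z)),
      .dcm_us(0x0028, 0x0002, 1L),
      .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_us(0x0028, 0x0010, mi$rows),
      .dcm_us(0x0028, 0x0011, mi$cols),
      # DICOM PixelSpacing is row spacing (Y) then column spacing (X)
      .dcm_str(0x0028, 0x0030, "DS", .ds(c(mi$pixel_spacing_y, mi$pixel_spacing_x))),
      .dcm_us(0x0028, 0x0100, 16L),
      .dcm_us(0x0028, 0x0101, 16L),
      .dcm_us(0x0028, 0x0102, 15L),
      .dcm_us(0x0028, 0x0103, 1L),
      .dcm_str(0x0028, 0x1052, "DS", .ds(mi$rescale_intercept)),
      .dcm_str(0x0028, 0x1053, "DS", .ds(mi$rescale_slope)),
      .dcm_element(0x7FE0, 0x0010, "OW", pix))
    body <- c(
      .dcm_element(0x0002, 0x0000, "UL", .u32(length(meta_elems))),
      meta_elems, dataset)

    path <- file.path(directory, sprintf("slice_%04d.dcm", mi$slice_index))
    con <- file(path, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), body), con)
    close(con)
    files[i] <- path
  }
  invisible(files)
}

# parse one DICOM file into a list of the tags the pipeline needs
.read_dcm_file <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  pos <- 1L
  if (length(bytes) >= 132L && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  rd_u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                                 signed = FALSE, endian = "little")
  rd_u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                                 endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  while (pos + 7L <= length(bytes)) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      .stopf("incomplete header: '%s' is not Explicit VR Little Endian",
             basename(path))
    }
    if (vr %in% long_vrs) {
      len <- rd_u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L); vstart <- pos + 8L
    }
    value <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw()
    tag <- sprintf("%04x,%04x", group, element)
    out[[tag]] <- list(vr = vr, value = value)
    pos <- vstart + len
    if (tag == "7fe0,0010") break
  }
  out
}

.tag_str <- function(el) trimws(rawToChar(el$value[el$value != as.raw(0L)]))
.tag_ds <- function(el) as.numeric(strsplit(.tag_str(el), "\\\\")[[1L]])
.tag_us <- function(el) readBin(el$value, "integer", size = 2L, signed = FALSE,
                                endian = "little")

#' Read a CT DICOM series
#'
#' Reads every `.dcm` file in `directory` (one axial slice per file,
#' Explicit VR Little Endian), rescales stored values to Hounsfield units
#' via `stored * RescaleSlope + RescaleIntercept`, and returns the slices
#' ordered by position along the scan axis (ImagePositionPatient z, falling
#' back to SliceLocation, then InstanceNumber).
#'
#' @param directory path containing the series.
#' @return a [VolumeGrid].
#' @section Errors:
#' An empty directory raises "no series found"; slices disagreeing on
#' rows/columns/spacing/thickness raise "heterogeneous series"; absent
#' PixelSpacing or SliceThickness raises "incomplete header". Absent rescale
#' tags are tolerated with a warning (slope 1, intercept 0).
#' @seealso [writeDicomSeries()]
#' @export
readDicomSeries <- function(directory) {
  if (!dir.exists(directory)) .stopf("no series found in '%s'", directory)
  paths <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(paths)) .stopf("no series found in '%s'", directory)

  slices <- lapply(paths, function(p) {
    el <- .read_dcm_file(p)
    need <- c("0028,0010", "0028,0011", "7fe0,0010")
    if (!all(need %in% names(el))) {
      .stopf("incomplete header: '%s' lacks image dimensions or pixel data",
             basename(p))
    }
    if (!all(c("0028,0030", "0018,0050") %in% names(el))) {
      .stopf("incomplete header: '%s' lacks PixelSpacing or SliceThickness",
             basename(p))
    }
    rows <- .tag_us(el[["0028,0010"]]); cols <- .tag_us(el[["0028,0011"]])
    sp <- .tag_ds(el[["0028,0030"]])  # row (Y) spacing, then column (X)
    thick <- .tag_ds(el[["0018,0050"]])[1L]
    if (is.null(el[["0028,1053"]]) || is.null(el[["0028,1052"]])) {
      .warnf("'%s': rescale tags absent, assuming slope 1, intercept 0",
             basename(p))
      slope <- 1; intercept <- 0
    } else {
      slope <- .tag_ds(el[["0028,1053"]])[1L]
      intercept <- .tag_ds(el[["0028,1052"]])[1L]
    }
    signed <- !is.null(el[["0028,0103"]]) && .tag_us(el[["0028,0103"]]) == 1L
    stored <- readBin(el[["7fe0,0010"]]$value, "integer",
                      n = rows * cols, size = 2L, signed = signed,
                      endian = "little")
    hu <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE) * slope + intercept
    zpos <- if (!is.null(el[["0020,0032"]])) .tag_ds(el[["0020,0032"]])[3L]
            else if (!is.null(el[["0020,1041"]])) .tag_ds(el[["0020,1041"]])[1L]
            else NA_real_
    inst <- if (!is.null(el[["0020,0013"]])) as.integer(.tag_str(el[["0020,0013"]]))
            else NA_integer_
    list(hu = hu, rows = rows, cols = cols, sx = sp[2L], sy = sp[1L],
         thick = thick, slope = slope, intercept = intercept,
         zpos = zpos, inst = inst)
  })

  # sort by slice position, fall back to instance number
  zs <- vapply(slices, function(s) s$zpos, numeric(1L))
  inst <- vapply(slices, function(s) as.numeric(s$inst), numeric(1L))
  ord <- if (!anyNA(zs)) order(zs) else if (!anyNA(inst)) order(inst) else
    seq_along(slices)
  slices <- slices[ord]

  same <- function(f) length(unique(vapply(slices, f, numeric(1L)))) == 1L
  if (!same(function(s) s$rows) || !same(function(s) s$cols) ||
      !same(function(s) s$sx) || !same(function(s) s$sy) ||
      !same(function(s) s$thick)) {
    .stopf("heterogeneous series: slices disagree on geometry")
  }

  s1 <- slices[[1L]]
  vox <- array(0, c(s1$rows, s1$cols, length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$hu
  idx <- vapply(slices, function(s) s$inst, integer(1L))
  idx <- if (anyNA(idx)) seq_along(slices) - 1L else idx - 1L
  volumeGrid(vox, pixel_spacing = c(s1$sx, s1$sy), slice_thickness = s1$thick,
             slice_index = idx, rescale_slope = s1$slope,
             rescale_intercept = s1$intercept)
}

# map one HU slice into [0, 1] under a display window (linear, clamped)
.window_slice <- function(slice, window) {
  w <- (slice - window[1L]) / (window[2L] - window[1L])
  w[w < 0] <- 0
  w[w > 1] <- 1
  w
}

#' Convert a CT volume to 8-bit PNG slices
#'
#' Writes one 8-bit greyscale PNG per slice under a linear display window:
#' HU at or below `window[1]` map to 0, at or above `window[2]` to 255, with
#' round-half-away-from-zero quantization in between (so a slice at the
#' window midpoint renders as 128). File names encode the slice index and
#' sort lexically in slice order.
#'
#' @param volume a [VolumeGrid].
#' @param directory output directory (created if missing).
#' @param window length-2 HU interval; the CT display window. The default
#'   spans air to dense cortical bone.
#' @return invisibly, the vector of files written.
#' @export
volumeToPng <- function(volume, directory, window = c(-1000, 2000)) {
  stopifnot(is(volume, "VolumeGrid"))
  if (window[1L] >= window[2L]) .stopf("degenerate window: lower must be < upper")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .stopf("cannot create directory '%s'", directory)
  }
  m <- sliceMeta(volume)
  v <- voxels(volume)
  files <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    g8 <- .round_half_away(.window_slice(v[, , i], window) * 255)
    path <- file.path(directory, sprintf("slice_%04d.png", m$slice_index[i]))
    png::writePNG(g8 / 255, path)
    files[i] <- path
  }
  invisible(files)
}
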