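#' @useDynLib fracture3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.meta_cols <- c("rows", "cols", "pixel_spacing_x", "pixel_spacing_y",
                "slice_thickness", "slice_index", "rescale_slope",
                "rescale_intercept")

.box_cols <- c("slice_index", "x_start", "y_start", "x_extent", "y_extent",
               "label", "score")

#' CT volume with per-slice acquisition metadata
#'
#' A `VolumeGrid` holds a calibrated CT volume as a 3-D array of Hounsfield
#' units (HU) indexed `(row, col, slice)` together with one metadata record
#' per slice. Rows run down the image (image Y), columns run right (image X),
#' and slices are ordered by ascending `slice_index` (0-based position along
#' the scan axis). All slices of a series share the in-plane pixel spacing
#' (mm/pixel) and slice thickness (mm); voxel values are already rescaled to
#' HU (`stored_value * rescale_slope + rescale_intercept`).
#'
#' @slot voxels numeric 3-D array of HU values, dimension `(rows, cols, slices)`.
#' @slot meta `data.frame` with one row per slice and columns `rows`, `cols`,
#'   `pixel_spacing_x`, `pixel_spacing_y`, `slice_thickness`, `slice_index`,
#'   `rescale_slope`, `rescale_intercept`.
#' @seealso [readDicomSeries()], [writeDicomSeries()], [generatePhantom()]
#' @export
setClass("VolumeGrid", representation(voxels = "array", meta = "data.frame"))

setValidity("VolumeGrid", function(object) {
  v <- object@voxels
  m <- object@meta
  if (length(dim(v)) != 3L) return("voxels must be a 3-D array")
  if (!all(.meta_cols %in% names(m))) {
    return(paste("meta must contain columns:", paste(.meta_cols, collapse = ", ")))
  }
  if (nrow(m) != dim(v)[3L]) return("one meta row per slice required")
  if (any(m$rows < 1L) || any(m$cols < 1L)) return("rows/cols must be >= 1")
  if (any(m$rows != dim(v)[1L]) || any(m$cols != dim(v)[2L])) {
    return("meta rows/cols must match voxel array dimensions")
  }
  if (any(m$pixel_spacing_x <= 0) || any(m$pixel_spacing_y <= 0)) {
    return("pixel spacing must be positive")
  }
  if (any(m$slice_thickness <= 0)) return("slice thickness must be positive")
  if (length(unique(m$pixel_spacing_x)) != 1L ||
      length(unique(m$pixel_spacing_y)) != 1L ||
      length(unique(m$slice_thickness)) != 1L) {
    return("heterogeneous series: spacing/thickness differ across slices")
  }
  if (any(m$slice_index < 0L)) return("slice_index must be >= 0")
  if (anyDuplicated(m$slice_index)) return("slice_index must be unique")
  if (is.unsorted(m$slice_index, strictly = TRUE)) {
    return("slices must be in ascending slice_index order")
  }
  TRUE
})

#' Per-slice 2-D bounding boxes
#'
#' A `BoxSet` stores axis-aligned fracture bounding boxes in the 4-tuple
#' convention `(x_start, y_start, x_extent, y_extent)`: the pixel column and
#' row of the top-left corner plus the horizontal and vertical extents in
#' pixels. Coordinates are 0-based and half-open: a box covers pixel columns
#' `[x_start, x_start + x_extent)` and rows `[y_start, y_start + y_extent)`,
#' so its area is exactly `x_extent * y_extent` pixels. Ground-truth boxes
#' carry `score = NA`; detector output carries a confidence score in [0, 1].
#'
#' @slot boxes `data.frame` with columns `slice_index`, `x_start`, `y_start`,
#'   `x_extent`, `y_extent`, `label`, `score`.
#' @seealso [boxSet()], [boxesToMatrix()], [boxToCuboid()]
#' @export
setClass("BoxSet", representation(boxes = "data.frame"))

setValidity("BoxSet", function(object) {
  b <- object@boxes
  if (!all(.box_cols %in% names(b))) {
    return(paste("boxes must contain columns:", paste(.box_cols, collapse = ", ")))
  }
  if (nrow(b) == 0L) return(TRUE)
  if (any(b$x_extent < 1L) || any(b$y_extent < 1L)) return("box extents must be >= 1")
  if (any(b$x_start < 0L) || any(b$y_start < 0L)) return("box starts must be >= 0")
  if (any(b$slice_index < 0L)) return("slice_index must be >= 0")
  sc <- b$score[!is.na(b$score)]
  if (length(sc) && (any(sc < 0) || any(sc > 1))) return("scores must lie in [0, 1]")
  TRUE
})

#' The 4-by-N bounding-box matrix
#'
#' Boxes in matrix storage: column i holds box i's
#' `(x_start, y_start, x_extent, y_extent)` 4-tuple, with parallel vectors
#' for slice index, label and (optional) score. Losslessly interconvertible
#' with [BoxSet] via [boxesToMatrix()] / [matrixToBoxes()].
#'
#' @slot mat numeric 4-by-N matrix with rows `x_start`, `y_start`,
#'   `x_extent`, `y_extent`.
#' @slot slice_index integer vector of length N.
#' @slot label character vector of length N.
#' @slot score numeric vector of length N (`NA` for ground truth).
#' @export
setClass("BoxMatrix", representation(mat = "matrix", slice_index = "integer",
                                     label = "character", score = "numeric"))

setValidity("BoxMatrix", function(object) {
  if (nrow(object@mat) != 4L) return("matrix must have 4 rows")
  n <- ncol(object@mat)
  if (length(object@slice_index) != n || length(object@label) != n ||
      length(object@score) != n) {
    return("parallel vectors must match the number of matrix columns")
  }
  TRUE
})

#' Binary bone mask
#'
#' The result of Hounsfield-unit thresholding: a 0/1 array aligned voxel-for-
#' voxel with its source [VolumeGrid], plus the HU interval that produced it
#' and the voxel spacing needed to interpret it physically.
#'
#' @slot mask integer 3-D array of 0/1 values, same shape as the source volume.
#' @slot hu_range numeric length-2, the closed HU interval used.
#' @slot spacing numeric length-3 `(pixel_spacing_x, pixel_spacing_y,
#'   slice_thickness)` in mm.
#' @slot provenance character id of the source volume (see [volumeId()]).
#' @seealso [thresholdBone()], [extractSurface()]
#' @export
setClass("BoneMask", representation(mask = "array", hu_range = "numeric",
                                    spacing = "numeric",
                                    provenance = "character"))

setValidity("BoneMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3-D array")
  if (!all(object@mask %in% c(0L, 1L))) return("mask values must be 0 or 1")
  if (length(object@hu_range) != 2L || object@hu_range[1] >= object@hu_range[2]) {
    return("hu_range must be an increasing length-2 interval")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be 3 positive values")
  }
  TRUE
})

#' Triangulated bone surface
#'
#' Triangle mesh in millimetre coordinates: vertex `(x, y, z)` equals voxel
#' index times spacing (x along image columns, y along image rows, z along
#' slices). Faces are 1-based vertex index triples, oriented outward.
#'
#' @slot vertices numeric n-by-3 matrix of mm coordinates.
#' @slot faces integer m-by-3 matrix of vertex indices.
#' @slot provenance character id of the source volume.
#' @seealso [extractSurface()], [capMesh()], [meshVolume()], [isWatertight()]
#' @export
setClass("BoneMesh", representation(vertices = "matrix", faces = "matrix",
                                    provenance = "character"))

setValidity("BoneMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices))) {
    return("face indices out of range")
  }
  TRUE
})

#' 3-D fracture mask
#'
#' The union of per-slice bounding boxes lifted into physical space: each box
#' becomes an axis-aligned cuboid whose z-slab is the half-open interval
#' `[k * t, (k + 1) * t)` for slice `k` with thickness `t`. Cuboids whose
#' pixel boxes overlap in-plane and whose slices lie within `merge_gap`
#' slices of each other are grouped into connected components (the "red
#' mask" pieces). A voxelized union aligned with the source grid is attached
#' on demand.
#'
#' @slot cuboids `data.frame` with mm columns `origin_x`, `origin_y`,
#'   `origin_z`, `dx`, `dy`, `dz`, the source pixel box (`x_start`, `y_start`,
#'   `x_extent`, `y_extent`, `slice_index`), `score` and `component`.
#' @slot voxels integer 0/1 array (possibly 0-length until voxelized).
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot provenance character id of the source volume.
#' @seealso [stackMask()], [voxelizeMask()], [overlayScene()]
#' @export
setClass("FractureMask3D", representation(cuboids = "data.frame",
                                          voxels = "array",
                                          spacing = "numeric",
                                          provenance = "character"))

setValidity("FractureMask3D", function(object) {
  cu <- object@cuboids
  need <- c("origin_x", "origin_y", "origin_z", "dx", "dy", "dz",
            "x_start", "y_start", "x_extent", "y_extent", "slice_index",
            "score", "component")
  if (!all(need %in% names(cu))) {
    return(paste("cuboids must contain columns:", paste(need, collapse = ", ")))
  }
  if (nrow(cu) && any(cu$dx <= 0 | cu$dy <= 0 | cu$dz <= 0)) {
    return("cuboid extents must be positive")
  }
  TRUE
})
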