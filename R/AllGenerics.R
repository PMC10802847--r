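#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `voxels()` returns the HU (or 0/1) array, `sliceMeta()` the per-slice
#' metadata table, `pixelSpacing()` the in-plane mm/pixel pair,
#' `sliceThickness()` the slice thickness in mm, `nSlices()` the slice
#' count, `boxes()` the box table, `nBoxes()` the box count,
#' `meshVertices()`/`meshFaces()` the mesh arrays and `cuboids()` the lifted
#' 3-D boxes.
#'
#' @param x a [VolumeGrid], [BoneMask], [BoxSet], [BoneMesh] or
#'   [FractureMask3D] as appropriate.
#' @return the slot contents described above.
#' @name accessors
#' @examples
#' vol <- generatePhantom(phantomSpec(shape = c(48, 48, 6), radius_outer = 14,
#'                                    radius_inner = 9))$volume
#' nSlices(vol)
#' sliceThickness(vol)
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("sliceMeta", function(x) standardGeneric("sliceMeta"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))
#' @rdname accessors
#' @export
setGeneric("nBoxes", function(x) standardGeneric("nBoxes"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("cuboids", function(x) standardGeneric("cuboids"))

#' @rdname accessors
setMethod("voxels", "VolumeGrid", function(x) x@voxels)
#' @rdname accessors
setMethod("voxels", "BoneMask", function(x) x@mask)
#' @rdname accessors
setMethod("voxels", "FractureMask3D", function(x) x@voxels)
#' @rdname accessors
setMethod("sliceMeta", "VolumeGrid", function(x) x@meta)
#' @rdname accessors
setMethod("pixelSpacing", "VolumeGrid", function(x) {
  c(x = x@meta$pixel_spacing_x[1L], y = x@meta$pixel_spacing_y[1L])
})
#' @rdname accessors
setMethod("sliceThickness", "VolumeGrid", function(x) x@meta$slice_thickness[1L])
#' @rdname accessors
setMethod("nSlices", "VolumeGrid", function(x) dim(x@voxels)[3L])
#' @rdname accessors
setMethod("boxes", "BoxSet", function(x) x@boxes)
#' @rdname accessors
setMethod("nBoxes", "BoxSet", function(x) nrow(x@boxes))
#' @rdname accessors
setMethod("meshVertices", "BoneMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("meshFaces", "BoneMesh", function(x) x@faces)
#' @rdname accessors
setMethod("cuboids", "FractureMask3D", function(x) x@cuboids)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@voxels)
  m <- object@meta
  cat(sprintf("VolumeGrid: %d x %d pixels, %d slice(s)\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  pixel spacing %.4g x %.4g mm, slice thickness %.4g mm\n",
              m$pixel_spacing_x[1L], m$pixel_spacing_y[1L], m$slice_thickness[1L]))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(object@voxels), max(object@voxels)))
})

setMethod("show", "BoxSet", function(object) {
  b <- object@boxes
  cat(sprintf("BoxSet: %d box(es) on %d slice(s)\n",
              nrow(b), length(unique(b$slice_index))))
  if (nrow(b)) {
    kind <- if (all(is.na(b$score))) "ground truth" else "scored detections"
    cat(sprintf("  %s; labels: %s\n", kind,
                paste(unique(b$label), collapse = ", ")))
  }
})

setMethod("show", "BoxMatrix", function(object) {
  cat(sprintf("BoxMatrix: 4 x %d\n", ncol(object@mat)))
})

setMethod("show", "BoneMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BoneMask: %d x %d x %d, %d foreground voxel(s), HU [%g, %g]\n",
              d[1L], d[2L], d[3L], sum(object@mask), object@hu_range[1L],
              object@hu_range[2L]))
})

setMethod("show", "BoneMesh", function(object) {
  cat(sprintf("BoneMesh: %d vertices, %d faces%s\n", nrow(object@vertices),
              nrow(object@faces),
              if (isWatertight(object)) " (watertight)" else ""))
})

setMethod("show", "FractureMask3D", function(object) {
  cu <- object@cuboids
  cat(sprintf("FractureMask3D: %d cuboid(s) in %d component(s)%s\n",
              nrow(cu), if (nrow(cu)) length(unique(cu$component)) else 0L,
              if (length(object@voxels)) " [voxelized]" else ""))
})
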