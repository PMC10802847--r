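# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded operations never perturb the global stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# round half away from zero (fixed rounding rule for PNG windowing)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf <- function(fmt, ...) message(sprintf(fmt, ...))

# deterministic content hash (FNV-1a over the serialized object, hex string);
# used for provenance records so runs are self-describing without extra deps
.hash_obj <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2L))
  h1 <- 0; h2 <- 5381
  for (b in raw) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 33 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Construct a VolumeGrid
#'
#' Build a [VolumeGrid] from an HU array and shared acquisition geometry.
#'
#' @param voxels numeric 3-D array of HU values indexed `(row, col, slice)`.
#' @param pixel_spacing length-2 numeric, mm/pixel along image X and Y.
#' @param slice_thickness slice thickness in mm.
#' @param slice_index integer vector of 0-based slice positions (default
#'   `0:(nslices-1)`).
#' @param rescale_slope,rescale_intercept HU calibration recorded in the
#'   metadata (the voxel array itself is always already in HU).
#' @return a validated [VolumeGrid].
#' @examples
#' v <- volumeGrid(array(-1000, c(8, 8, 2)), pixel_spacing = c(0.8, 0.8),
#'                 slice_thickness = 1)
#' nSlices(v)
#' @export
volumeGrid <- function(voxels, pixel_spacing = c(1, 1), slice_thickness = 1,
                       slice_index = NULL, rescale_slope = 1,
                       rescale_intercept = -1024) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "double"
  pixel_spacing <- unname(pixel_spacing)
  ns <- dim(voxels)[3L]
  if (is.null(slice_index)) slice_index <- seq_len(ns) - 1L
  if (length(slice_index) != ns) {
    .stopf("slice_index length (%d) must match slice count (%d)",
           length(slice_index), ns)
  }
  meta <- data.frame(
    rows = dim(voxels)[1L], cols = dim(voxels)[2L],
    pixel_spacing_x = pixel_spacing[1L], pixel_spacing_y = pixel_spacing[2L],
    slice_thickness = slice_thickness,
    slice_index = as.integer(slice_index),
    rescale_slope = rescale_slope, rescale_intercept = rescale_intercept)
  new("VolumeGrid", voxels = voxels, meta = meta)
}

#' Construct a BoxSet
#'
#' Assemble per-slice 2-D bounding boxes in the 4-tuple convention
#' (0-based, half-open pixel intervals; see [BoxSet]).
#'
#' @param slice_index integer vector, 0-based slice of each box.
#' @param x_start,y_start 0-based pixel column/row of the top-left corner.
#' @param x_extent,y_extent box extents in pixels (>= 1).
#' @param label class label (recycled); the pipeline uses the single class
#'   `"fracture"`.
#' @param score optional confidence in [0, 1]; `NA` marks ground truth.
#' @return a validated [BoxSet].
#' @examples
#' b <- boxSet(slice_index = 0, x_start = 10, y_start = 20,
#'             x_extent = 30, y_extent = 40)
#' nBoxes(b)
#' @export
boxSet <- function(slice_index = integer(), x_start = integer(),
                   y_start = integer(), x_extent = integer(),
                   y_extent = integer(), label = "fracture", score = NA_real_) {
  n <- length(slice_index)
  b <- data.frame(
    slice_index = as.integer(slice_index),
    x_start = as.integer(x_start), y_start = as.integer(y_start),
    x_extent = as.integer(x_extent), y_extent = as.integer(y_extent),
    label = rep_len(as.character(label), n),
    score = rep_len(as.numeric(score), n))
  new("BoxSet", boxes = b)
}

# concatenate BoxSets
.bind_boxes <- function(...) {
  parts <- Filter(function(b) nBoxes(b) > 0L, list(...))
  if (!length(parts)) return(boxSet())
  new("BoxSet", boxes = do.call(rbind, lapply(parts, boxes)))
}
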