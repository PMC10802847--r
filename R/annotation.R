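# Bounding-box data model: the 4-by-N storage matrix, training-time
# augmentations (horizontal flip, random 1-1.3x scaling, random X/Y shifts),
# and a plain-text TSV interchange format.

#' Convert boxes to/from the 4-by-N matrix form
#'
#' `boxesToMatrix()` packs a [BoxSet] into a [BoxMatrix]: column i holds box
#' i's `(x_start, y_start, x_extent, y_extent)` 4-tuple with parallel slice
#' index, label and score vectors. `matrixToBoxes()` is its exact inverse.
#'
#' @param bxs a [BoxSet].
#' @return `boxesToMatrix()`: a [BoxMatrix]; `matrixToBoxes()`: a [BoxSet].
#' @examples
#' b <- boxSet(slice_index = 0, x_start = 10, y_start = 20,
#'             x_extent = 30, y_extent = 40)
#' boxesToMatrix(b)@mat
#' @export
boxesToMatrix <- function(bxs) {
  stopifnot(is(bxs, "BoxSet"))
  b <- boxes(bxs)
  m <- t(as.matrix(b[, c("x_start", "y_start", "x_extent", "y_extent")]))
  dimnames(m) <- list(c("x_start", "y_start", "x_extent", "y_extent"), NULL)
  new("BoxMatrix", mat = m, slice_index = as.integer(b$slice_index),
      label = as.character(b$label), score = as.numeric(b$score))
}

#' @param bm a [BoxMatrix].
#' @rdname boxesToMatrix
#' @export
matrixToBoxes <- function(bm) {
  stopifnot(is(bm, "BoxMatrix"))
  m <- bm@mat
  boxSet(slice_index = bm@slice_index, x_start = m[1L, ], y_start = m[2L, ],
         x_extent = m[3L, ], y_extent = m[4L, ], label = bm@label,
         score = bm@score)
}

# clamp transformed boxes to the image and drop the ones pushed fully
# outside (with a message, so silent label loss never happens)
.clamp_boxes <- function(b, width, height) {
  if (!nrow(b)) return(b)
  x1 <- pmax(b$x_start, 0L)
  y1 <- pmax(b$y_start, 0L)
  x2 <- pmin(b$x_start + b$x_extent, width)
  y2 <- pmin(b$y_start + b$y_extent, height)
  keep <- x2 - x1 >= 1L & y2 - y1 >= 1L
  if (any(!keep)) {
    .msgf("dropped %d box(es) pushed fully outside the image", sum(!keep))
  }
  b <- b[keep, , drop = FALSE]
  b$x_start <- as.integer(x1[keep]); b$y_start <- as.integer(y1[keep])
  b$x_extent <- as.integer(x2[keep] - x1[keep])
  b$y_extent <- as.integer(y2[keep] - y1[keep])
  b
}

#' Flip/scale augmentation for a slice and its boxes
#'
#' Applies one affine training augmentation drawn from
#' \{identity, horizontal flip\} x \{scale s ~ Uniform(1, 1.3)\}: the slice
#' may be mirrored along the X axis (never the Y axis) and scaled about the
#' image centre, re-cropped to the original size with background fill.
#' Boxes are transformed with the pixels: under a pure flip
#' `x_start' = W - x_start - x_extent`; under scale s both box corners map
#' through `c + s * (x - c)` about the image-centre `c`, so extents scale by
#' s within one pixel of rounding. Boxes pushed outside are clamped, and
#' dropped (with a message) only when fully outside.
#'
#' @param image numeric matrix, one slice (HU or [0, 1] grey).
#' @param bxs a [BoxSet] with boxes on this slice.
#' @param seed integer seed used to draw the transform.
#' @param flip,scale optional overrides forcing a specific transform
#'   (`flip = FALSE, scale = 1` gives the identity).
#' @param fill background fill for pixels exposed by down-scaling
#'   (-1000 HU, i.e. air; use 0 for PNG-scale images).
#' @return list with `image`, `boxes` and `params` (the transform drawn).
#' @seealso [augmentShift()]
#' @export
augmentFlipScale <- function(image, bxs, seed = 1L, flip = NULL, scale = NULL,
                             fill = -1000) {
  stopifnot(is.matrix(image), is(bxs, "BoxSet"))
  drawn <- .with_seed(seed, list(flip = stats::runif(1) < 0.5,
                                 scale = stats::runif(1, 1, 1.3)))
  if (is.null(flip)) flip <- drawn$flip
  if (is.null(scale)) scale <- drawn$scale
  h <- nrow(image); w <- ncol(image)
  b <- boxes(bxs)

  if (scale != 1) {
    cx <- w / 2; cy <- h / 2
    # destination pixel centres pulled back through the inverse transform
    src_c <- floor(cx + ((seq_len(w) - 0.5) - cx) / scale) + 1L
    src_r <- floor(cy + ((seq_len(h) - 0.5) - cy) / scale) + 1L
    ok_c <- src_c >= 1L & src_c <= w
    ok_r <- src_r >= 1L & src_r <= h
    out <- matrix(fill, h, w)
    out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
    image <- out
    if (nrow(b)) {
      x1 <- .round_half_away(cx + scale * (b$x_start - cx))
      x2 <- .round_half_away(cx + scale * (b$x_start + b$x_extent - cx))
      y1 <- .round_half_away(cy + scale * (b$y_start - cy))
      y2 <- .round_half_away(cy + scale * (b$y_start + b$y_extent - cy))
      b$x_start <- as.integer(x1); b$x_extent <- as.integer(x2 - x1)
      b$y_start <- as.integer(y1); b$y_extent <- as.integer(y2 - y1)
    }
  }
  if (flip) {
    image <- image[, rev(seq_len(w)), drop = FALSE]
    if (nrow(b)) b$x_start <- w - b$x_start - b$x_extent
  }
  b <- .clamp_boxes(b, w, h)
  list(image = image, boxes = new("BoxSet", boxes = b),
       params = list(flip = flip, scale = scale))
}

#' Random-shift augmentation
#'
#' Produces `n_copies` independently shifted copies of a slice and its
#' boxes: integer shifts along X and Y drawn uniformly from
#' `[-max_shift, max_shift]`, vacated pixels filled with background, boxes
#' translated and clamped (dropped with a message only if fully outside).
#'
#' @inheritParams augmentFlipScale
#' @param n_copies number of augmented copies (>= 1); 10 reproduces a
#'   tenfold augmentation.
#' @param max_shift maximum absolute shift in pixels; must be smaller than
#'   both image dimensions.
#' @return a list of `n_copies` lists, each with `image`, `boxes`, `shift`.
#' @export
augmentShift <- function(image, bxs, n_copies = 10L, max_shift = 20L,
                         seed = 1L, fill = -1000) {
  stopifnot(is.matrix(image), is(bxs, "BoxSet"))
  if (n_copies < 1L) .stopf("n_copies must be >= 1")
  max_shift <- as.integer(max_shift)
  h <- nrow(image); w <- ncol(image)
  if (max_shift >= min(h, w)) {
    .stopf("max_shift (%d) must be smaller than the image (%d x %d)",
           max_shift, h, w)
  }
  shifts <- .with_seed(seed, matrix(
    sample.int(2L * max_shift + 1L, 2L * n_copies, replace = TRUE) -
      max_shift - 1L, ncol = 2L))
  lapply(seq_len(n_copies), function(i) {
    dxy <- shifts[i, ]
    out <- matrix(fill, h, w)
    src_c <- seq_len(w) - dxy[1L]
    src_r <- seq_len(h) - dxy[2L]
    ok_c <- src_c >= 1L & src_c <= w
    ok_r <- src_r >= 1L & src_r <= h
    out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
    b <- boxes(bxs)
    if (nrow(b)) {
      b$x_start <- b$x_start + dxy[1L]
      b$y_start <- b$y_start + dxy[2L]
    }
    list(image = out, boxes = new("BoxSet", boxes = .clamp_boxes(b, w, h)),
         shift = c(x = dxy[1L], y = dxy[2L]))
  })
}

.BOX_HEADER <- "# fracture3d boxes: 0-based pixel coordinates, half-open extents"
.BOX_COLS_LINE <- "slice_index\tx_start\ty_start\tx_extent\ty_extent\tlabel\tscore"

#' Read and write the plain-text box table
#'
#' Tab-separated interchange format, one box per line
#' (`slice_index, x_start, y_start, x_extent, y_extent, label, score`),
#' 0-based pixel coordinates as declared in the file's header line. The
#' score field is optional on input and `NA` for ground truth. The round
#' trip is lossless.
#'
#' @param bxs a [BoxSet].
#' @param path file path.
#' @return `writeBoxes()`: invisibly, `path`; `readBoxes()`: a [BoxSet].
#' @export
writeBoxes <- function(bxs, path) {
  stopifnot(is(bxs, "BoxSet"))
  b <- boxes(bxs)
  lines <- c(.BOX_HEADER, .BOX_COLS_LINE)
  if (nrow(b)) {
    lines <- c(lines, sprintf(
      "%d\t%d\t%d\t%d\t%d\t%s\t%s", b$slice_index, b$x_start, b$y_start,
      b$x_extent, b$y_extent, b$label,
      ifelse(is.na(b$score), "NA", formatC(b$score, format = "g", digits = 17))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeBoxes
#' @export
readBoxes <- function(path) {
  if (!file.exists(path)) .stopf("box file '%s' not found", path)
  lines <- readLines(path)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#") ||
        startsWith(ln, "slice_index")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (!length(f) %in% c(6L, 7L)) {
      .stopf("parse error at line %d of '%s': expected 6 or 7 fields, got %d",
             i, path, length(f))
    }
    nums <- suppressWarnings(as.integer(f[1:5]))
    if (anyNA(nums)) {
      .stopf("parse error at line %d of '%s': non-integer coordinate", i, path)
    }
    score <- if (length(f) == 7L) suppressWarnings(as.numeric(f[7L])) else NA_real_
    recs[[length(recs) + 1L]] <- data.frame(
      slice_index = nums[1L], x_start = nums[2L], y_start = nums[3L],
      x_extent = nums[4L], y_extent = nums[5L], label = f[6L], score = score)
  }
  if (!length(recs)) return(boxSet())
  new("BoxSet", boxes = do.call(rbind, recs))
}
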