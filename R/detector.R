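# Pluggable per-slice fracture detectors. The rule-based detector finds
# interruptions of the cortical ring deterministically and is the
# desk-scale stand-in for the trained network; the network itself lives in
# yolo.R.

#' Detector configuration
#'
#' Shared configuration for both detector kinds. The rule detector
#' parameters describe the cortical-ring scan; the network parameters
#' mirror the training recipe: initial learning rate 0.001 halved every 20
#' epochs, at most 50 epochs, minibatch 4, ADAM.
#'
#' @param kind `"rule"` or `"yolov4"`.
#' @param score_threshold minimum detection confidence kept, in [0, 1].
#' @param input_size network input side in pixels (must be divisible by
#'   32). 512 matches a 256 x 256 first-block feature map.
#' @param hu_band HU interval delimiting cortical bone for the rule
#'   detector.
#' @param min_gap_px smallest cortical interruption reported, as arc length
#'   in pixels.
#' @param ring_min_pixels slices with fewer foreground pixels are skipped.
#' @param window CT display window applied before the network sees a slice.
#' @param nms_iou IoU above which overlapping detections are suppressed.
#' @param num_classes number of object classes (1: "fracture").
#' @param anchors optional 9 x 2 matrix of anchor (width, height) priors in
#'   input pixels; defaults to the standard 9-anchor layout scaled to
#'   `input_size`.
#' @param initial_lr,drop_period,drop_factor,max_epochs,minibatch,optimizer
#'   training schedule parameters.
#' @return a list of class `DetectorConfig`.
#' @export
detectorConfig <- function(kind = c("rule", "yolov4"),
                           score_threshold = 0.1,
                           input_size = 512L,
                           hu_band = c(1150, 1250),
                           min_gap_px = 5,
                           ring_min_pixels = 30L,
                           window = c(-1000, 2000),
                           nms_iou = 0.5,
                           num_classes = 1L,
                           anchors = NULL,
                           initial_lr = 0.001, drop_period = 20L,
                           drop_factor = 0.5, max_epochs = 50L,
                           minibatch = 4L, optimizer = "adam") {
  kind <- match.arg(kind)
  if (score_threshold < 0 || score_threshold > 1) {
    .stopf("score_threshold must lie in [0, 1]")
  }
  if (input_size %% 32L != 0L) .stopf("input_size must be divisible by 32")
  if (any(c(initial_lr, drop_period, drop_factor, max_epochs, minibatch) <= 0)) {
    .stopf("training configuration values must be positive")
  }
  if (is.null(anchors)) {
    base <- rbind(c(12, 16), c(19, 36), c(40, 28),
                  c(36, 75), c(76, 55), c(72, 146),
                  c(142, 110), c(192, 243), c(459, 401))
    anchors <- base * input_size / 608
  }
  structure(list(kind = kind, score_threshold = score_threshold,
                 input_size = as.integer(input_size), hu_band = hu_band,
                 min_gap_px = min_gap_px,
                 ring_min_pixels = as.integer(ring_min_pixels),
                 window = window, nms_iou = nms_iou,
                 num_classes = as.integer(num_classes), anchors = anchors,
                 initial_lr = initial_lr, drop_period = as.integer(drop_period),
                 drop_factor = drop_factor, max_epochs = as.integer(max_epochs),
                 minibatch = as.integer(minibatch), optimizer = optimizer),
            class = "DetectorConfig")
}

# least-squares (Kasa) circle fit; robust to an interrupted ring because
# every shell pixel contributes, not only a symmetric subset
.fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- solve(crossprod(A), crossprod(A, b))
  c(cx = sol[1L], cy = sol[2L])
}

#' Rule-based cortical-gap detector
#'
#' Deterministic per-slice fracture detector: thresholds the volume to the
#' cortical band, fits a circle to each slice's shell pixels, bins the
#' pixels by polar angle around the fitted centre (about one bin per pixel
#' of circumference), and reports every angular run of empty bins whose arc
#' length reaches `min_gap_px` as an interruption of the cortical ring. The
#' emitted box is the tight bounding box of the annulus sector spanned by
#' the gap; the score is the gap's fraction of the circumference.
#'
#' @param volume a [VolumeGrid].
#' @param config a [detectorConfig()] (rule parameters are used).
#' @return a scored [BoxSet] (possibly empty).
#' @export
detectRule <- function(volume, config = detectorConfig("rule")) {
  stopifnot(is(volume, "VolumeGrid"))
  mask <- voxels(thresholdBone(volume, config$hu_band[1L], config$hu_band[2L]))
  d <- dim(mask)
  X <- matrix(seq_len(d[2L]) - 1L, d[1L], d[2L], byrow = TRUE)
  Y <- matrix(seq_len(d[1L]) - 1L, d[1L], d[2L])
  out <- list()
  for (k in seq_len(d[3L])) {
    sl <- mask[, , k] == 1L
    n_fg <- sum(sl)
    if (n_fg < config$ring_min_pixels) next
    px <- X[sl]; py <- Y[sl]
    ctr <- .fit_circle(px, py)
    dx <- px - ctr[1L]; dy <- py - ctr[2L]
    r <- sqrt(dx^2 + dy^2)
    r_mid <- stats::median(r)
    circumference <- 2 * pi * r_mid
    nbins <- max(60L, ceiling(circumference))
    theta <- atan2(dy, dx) %% (2 * pi)
    occ <- tabulate(pmin(floor(theta / (2 * pi) * nbins) + 1L, nbins), nbins)
    if (all(occ > 0L)) next

    # maximal circular runs of empty bins
    empty <- occ == 0L
    runs <- rle(empty)
    starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
    gaps <- data.frame(start = starts[runs$values],
                       len = runs$lengths[runs$values])
    if (nrow(gaps) > 1L && empty[1L] && empty[nbins]) {  # wrap-around run
      first <- 1L; last <- nrow(gaps)
      gaps$start[first] <- gaps$start[last]
      gaps$len[first] <- gaps$len[first] + gaps$len[last]
      gaps <- gaps[-last, , drop = FALSE]
    }
    bin_w <- 2 * pi / nbins
    slice_dx <- X - ctr[1L]; slice_dy <- Y - ctr[2L]
    slice_r <- sqrt(slice_dx^2 + slice_dy^2)
    slice_bin <- pmin(floor((atan2(slice_dy, slice_dx) %% (2 * pi)) / bin_w) + 1L,
                      nbins)
    r_lo <- min(r); r_hi <- max(r)
    for (gi in seq_len(nrow(gaps))) {
      arc_px <- gaps$len[gi] * bin_w * r_mid
      if (arc_px < config$min_gap_px) next
      gap_bins <- ((gaps$start[gi] - 1L) + seq_len(gaps$len[gi]) - 1L) %% nbins + 1L
      region <- slice_r >= r_lo - 0.5 & slice_r <= r_hi + 0.5 &
        slice_bin %in% gap_bins
      if (!any(region)) next
      idx <- which(region, arr.ind = TRUE)
      score <- min(1, gaps$len[gi] / nbins)
      if (score < config$score_threshold) next
      out[[length(out) + 1L]] <- data.frame(
        slice_index = k - 1L,
        x_start = min(idx[, 2L]) - 1L, y_start = min(idx[, 1L]) - 1L,
        x_extent = max(idx[, 2L]) - min(idx[, 2L]) + 1L,
        y_extent = max(idx[, 1L]) - min(idx[, 1L]) + 1L,
        label = "fracture", score = score)
    }
  }
  if (!length(out)) return(boxSet())
  new("BoxSet", boxes = do.call(rbind, out))
}
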