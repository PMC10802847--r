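# Object-detection evaluation: intersection over union, greedy one-to-one
# matching, precision = TP/(TP+FP), recall = TP/(TP+FN), PR curves swept
# over the score threshold, average precision, and IoU summary statistics.
# TN is tracked for completeness only; it is ill-defined for detection and
# enters no metric.

#' Precision-recall curve
#'
#' Result of sweeping the detector score threshold: one (threshold, recall,
#' precision) point per distinct score, recall non-decreasing along the
#' sweep, plus the average precision summarising the curve.
#'
#' @slot points `data.frame` with columns `threshold`, `recall`, `precision`.
#' @slot average_precision number in [0, 1].
#' @slot method `"all"` (area under the monotone precision envelope) or
#'   `"11point"` (mean interpolated precision at recalls 0, 0.1, ..., 1).
#' @seealso [prCurve()]
#' @export
setClass("PRCurve", representation(points = "data.frame",
                                   average_precision = "numeric",
                                   method = "character"))

setValidity("PRCurve", function(object) {
  p <- object@points
  if (!all(c("threshold", "recall", "precision") %in% names(p))) {
    return("points needs threshold/recall/precision columns")
  }
  if (any(p$recall < 0 | p$recall > 1 | p$precision < 0 | p$precision > 1)) {
    return("precision and recall must lie in [0, 1]")
  }
  if (is.unsorted(p$recall)) return("recall must be non-decreasing")
  if (object@average_precision < 0 || object@average_precision > 1) {
    return("average precision must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d threshold point(s), AP = %.4f (%s interpolation)\n",
              nrow(object@points), object@average_precision, object@method))
})

#' IoU summary statistics
#'
#' @slot ious per-match IoU values in [0, 1].
#' @slot mean sample mean.
#' @slot sd sample standard deviation (n - 1 denominator; 0 with a warning
#'   for a single observation).
#' @export
setClass("IoUStats", representation(ious = "numeric", mean = "numeric",
                                    sd = "numeric"))

setMethod("show", "IoUStats", function(object) {
  cat(sprintf("IoUStats: n = %d, mean = %.4f, sd = %.4f\n",
              length(object@ious), object@mean, object@sd))
})

#' Intersection over union of two pixel boxes
#'
#' Boxes use the half-open 4-tuple convention, so areas are exact covered
#' pixel counts: `|a intersect b| / |a union b|`.
#'
#' @param a,b numeric length-4 vectors `(x_start, y_start, x_extent,
#'   y_extent)`; both boxes must lie on the same slice.
#' @return a ratio in [0, 1]; 1 exactly for identical boxes.
#' @examples
#' boxIou(c(0, 0, 10, 10), c(5, 5, 10, 10))  # 25 / 175
#' @export
boxIou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[3L] < 1 || a[4L] < 1 || b[3L] < 1 || b[4L] < 1) {
    .stopf("zero-extent box")
  }
  ix <- max(0, min(a[1L] + a[3L], b[1L] + b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[2L] + a[4L], b[2L] + b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  inter / (a[3L] * a[4L] + b[3L] * b[4L] - inter)
}

.box_tuple <- function(df, i) {
  c(df$x_start[i], df$y_start[i], df$x_extent[i], df$y_extent[i])
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching per slice: each prediction, taken in
#' descending score order, claims the still-unmatched ground-truth box of
#' highest IoU, provided that IoU reaches `iou_min` (default 0.5, the
#' conventional compliance threshold). Unclaimed predictions count as false
#' positives, unclaimed ground truths as false negatives.
#'
#' @param gt ground-truth [BoxSet].
#' @param pred scored [BoxSet] of detections.
#' @param iou_min minimum IoU for a valid match.
#' @return list with `counts` (named `tp`, `fp`, `fn`, `tn`; `tn` is always
#'   0) and `ious` (IoU of each matched pair).
#' @export
matchDetections <- function(gt, pred, iou_min = 0.5) {
  stopifnot(is(gt, "BoxSet"), is(pred, "BoxSet"))
  g <- boxes(gt); p <- boxes(pred)
  tp <- 0L; fp <- 0L
  ious <- numeric()
  for (k in unique(c(g$slice_index, p$slice_index))) {
    gs <- g[g$slice_index == k, , drop = FALSE]
    ps <- p[p$slice_index == k, , drop = FALSE]
    ps <- ps[order(-ps$score), , drop = FALSE]  # stable: ties keep input order
    taken <- rep(FALSE, nrow(gs))
    for (i in seq_len(nrow(ps))) {
      best <- 0; best_j <- 0L
      for (j in seq_len(nrow(gs))) {
        if (taken[j]) next
        v <- boxIou(.box_tuple(ps, i), .box_tuple(gs, j))
        if (v > best) { best <- v; best_j <- j }
      }
      if (best_j > 0L && best >= iou_min) {
        taken[best_j] <- TRUE
        tp <- tp + 1L
        ious <- c(ious, best)
      } else {
        fp <- fp + 1L
      }
    }
  }
  fn <- nrow(g) - tp
  list(counts = c(tp = tp, fp = fp, fn = fn, tn = 0L), ious = ious)
}

#' Precision and recall from confusion counts
#'
#' `precisionOf()` returns `tp / (tp + fp)`, `recallOf()` returns
#' `tp / (tp + fn)`. The degenerate cases (no predictions, no ground truth)
#' are defined as 1 — nothing was asserted, nothing was wrong — and
#' reported with a message.
#'
#' @param counts named vector with `tp`, `fp`, `fn` (as from
#'   [matchDetections()]).
#' @return a ratio in [0, 1].
#' @export
precisionOf <- function(counts) {
  if (counts[["tp"]] + counts[["fp"]] == 0) {
    .msgf("no predictions: precision defined as 1")
    return(1)
  }
  counts[["tp"]] / (counts[["tp"]] + counts[["fp"]])
}

#' @rdname precisionOf
#' @export
recallOf <- function(counts) {
  if (counts[["tp"]] + counts[["fn"]] == 0) {
    .msgf("no ground truth: recall defined as 1")
    return(1)
  }
  counts[["tp"]] / (counts[["tp"]] + counts[["fn"]])
}

#' Precision-recall curve and average precision
#'
#' Sweeps the score threshold over every distinct prediction score in
#' descending order, recomputing the greedy matching at each, and
#' summarises the curve as average precision: either the area under the
#' monotone precision envelope over recall (`method = "all"`, the default)
#' or the 11-point interpolation at recalls 0, 0.1, ..., 1.
#'
#' @inheritParams matchDetections
#' @param method AP interpolation rule, `"all"` or `"11point"`.
#' @return a [PRCurve].
#' @export
prCurve <- function(gt, pred, iou_min = 0.5, method = c("all", "11point")) {
  method <- match.arg(method)
  p <- boxes(pred)
  if (anyNA(p$score)) .stopf("predictions must carry scores")
  if (!nrow(p)) {
    return(new("PRCurve",
               points = data.frame(threshold = NA_real_, recall = 0,
                                   precision = 1),
               average_precision = 0, method = method))
  }
  thresholds <- sort(unique(p$score), decreasing = TRUE)
  pts <- lapply(thresholds, function(thr) {
    sub <- new("BoxSet", boxes = p[p$score >= thr, , drop = FALSE])
    m <- matchDetections(gt, sub, iou_min)
    data.frame(threshold = thr,
               recall = suppressMessages(recallOf(m$counts)),
               precision = suppressMessages(precisionOf(m$counts)))
  })
  pts <- do.call(rbind, pts)
  ap <- .average_precision(pts$recall, pts$precision, method)
  new("PRCurve", points = pts, average_precision = ap, method = method)
}

.average_precision <- function(recall, precision, method) {
  ord <- order(recall)
  r <- recall[ord]; p <- precision[ord]
  if (method == "11point") {
    mean(vapply(seq(0, 1, 0.1), function(r0) {
      sel <- r >= r0 - 1e-12
      if (any(sel)) max(p[sel]) else 0
    }, numeric(1L)))
  } else {
    env <- rev(cummax(rev(p)))  # monotone precision envelope
    sum(diff(c(0, r)) * env)
  }
}

#' Summarise matched IoU values
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' IoUs of matched detection/ground-truth pairs. A single observation
#' yields sd 0 with a warning rather than an error, so small runs do not
#' abort.
#'
#' @param ious numeric vector of matched IoU values (length >= 1).
#' @return an [IoUStats].
#' @export
iouStats <- function(ious) {
  if (!length(ious)) .stopf("no matched pairs: IoU statistics undefined")
  if (any(ious < 0 | ious > 1)) .stopf("IoU values must lie in [0, 1]")
  s <- if (length(ious) == 1L) {
    .warnf("single observation: sd reported as 0")
    0
  } else {
    stats::sd(ious)
  }
  new("IoUStats", ious = as.numeric(ious), mean = mean(ious), sd = s)
}

#' Assemble and write a metrics report
#'
#' Aggregates counts, precision/recall, the PR curve with its average
#' precision, and IoU statistics into a single list, serialisable as JSON.
#'
#' @inheritParams matchDetections
#' @param ap_method AP interpolation rule passed to [prCurve()].
#' @return a list with elements `counts`, `precision`, `recall`, `pr`
#'   (threshold table), `average_precision`, `iou_mean`, `iou_sd`, `n_matched`.
#' @export
metricsReport <- function(gt, pred, iou_min = 0.5, ap_method = "all") {
  m <- matchDetections(gt, pred, iou_min)
  pr <- if (any(!is.na(boxes(pred)$score))) {
    prCurve(gt, pred, iou_min, ap_method)
  } else {
    new("PRCurve", points = data.frame(threshold = NA_real_, recall = 0,
                                       precision = 1),
        average_precision = 0, method = ap_method)
  }
  st <- if (length(m$ious)) suppressWarnings(iouStats(m$ious)) else NULL
  list(counts = as.list(m$counts),
       precision = suppressMessages(precisionOf(m$counts)),
       recall = suppressMessages(recallOf(m$counts)),
       pr = pr@points,
       average_precision = pr@average_precision,
       iou_mean = if (is.null(st)) NA_real_ else st@mean,
       iou_sd = if (is.null(st)) NA_real_ else st@sd,
       n_matched = length(m$ious))
}

#' @param report a list from [metricsReport()].
#' @param path output JSON file.
#' @rdname metricsReport
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Plot a precision-recall curve
#'
#' Draws the swept (recall, precision) points on the current device, or
#' saves them to a PNG/SVG file if `path` is given.
#'
#' @param pr a [PRCurve].
#' @param path optional output file ending in `.png` or `.svg`.
#' @return invisibly, `path` (or `NULL` when drawing to the current device).
#' @export
plotPrCurve <- function(pr, path = NULL) {
  stopifnot(is(pr, "PRCurve"))
  draw <- function() {
    p <- pr@points
    graphics::plot(c(0, p$recall), c(1, p$precision), type = "s",
                   xlim = c(0, 1), ylim = c(0, 1.02), xaxs = "i", yaxs = "i",
                   xlab = "Recall", ylab = "Precision",
                   main = sprintf("PR curve (AP = %.3f)", pr@average_precision),
                   col = "steelblue", lwd = 2)
    graphics::points(p$recall, p$precision, pch = 19, col = "steelblue")
  }
  if (is.null(path)) {
    draw()
    return(invisible(NULL))
  }
  if (grepl("\\.svg$", path)) {
    grDevices::svg(path, width = 6, height = 6)
  } else {
    grDevices::png(path, width = 600, height = 600)
  }
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}
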