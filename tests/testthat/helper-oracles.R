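# Independent brute-force oracles for the evaluation module: IoU by
# materialising pixel grids and counting, matching by a naive scan over a
# pixel-counted IoU matrix, and average precision by explicit threshold
# enumeration with a hand-rolled envelope integral. These deliberately share
# no code with the package implementations.

iou_pixel_oracle <- function(a, b) {
  w <- max(a[1] + a[3], b[1] + b[3])
  h <- max(a[2] + a[4], b[2] + b[4])
  ga <- matrix(FALSE, h, w)
  gb <- matrix(FALSE, h, w)
  ga[(a[2] + 1):(a[2] + a[4]), (a[1] + 1):(a[1] + a[3])] <- TRUE
  gb[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])] <- TRUE
  sum(ga & gb) / sum(ga | gb)
}

tuple_of <- function(df, i) c(df$x_start[i], df$y_start[i], df$x_extent[i],
                              df$y_extent[i])

# naive re-implementation of the greedy score-then-IoU protocol
match_oracle <- function(gt_df, pred_df, iou_min = 0.5) {
  tp <- 0L; fp <- 0L
  ious <- numeric()
  for (k in unique(c(gt_df$slice_index, pred_df$slice_index))) {
    g <- gt_df[gt_df$slice_index == k, , drop = FALSE]
    p <- pred_df[pred_df$slice_index == k, , drop = FALSE]
    p <- p[order(-p$score), , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    if (nrow(p)) for (i in seq_len(nrow(p))) {
      vals <- rep(-1, nrow(g))
      if (nrow(g)) for (j in seq_len(nrow(g))) {
        if (!used[j]) vals[j] <- iou_pixel_oracle(tuple_of(p, i), tuple_of(g, j))
      }
      j_best <- if (length(vals)) which.max(vals) else 0L
      if (length(vals) && vals[j_best] >= iou_min) {
        used[j_best] <- TRUE
        tp <- tp + 1L
        ious <- c(ious, vals[j_best])
      } else {
        fp <- fp + 1L
      }
    }
  }
  list(tp = tp, fp = fp, fn = nrow(gt_df) - tp, ious = ious)
}

# best achievable TP count over all one-to-one assignments (per slice,
# exhaustive over injections; instances are kept to <= 4 boxes per slice)
optimal_tp_oracle <- function(gt_df, pred_df, iou_min = 0.5) {
  total <- 0L
  for (k in unique(c(gt_df$slice_index, pred_df$slice_index))) {
    g <- gt_df[gt_df$slice_index == k, , drop = FALSE]
    p <- pred_df[pred_df$slice_index == k, , drop = FALSE]
    if (!nrow(g) || !nrow(p)) next
    valid <- matrix(FALSE, nrow(p), nrow(g))
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(g))) {
      valid[i, j] <- iou_pixel_oracle(tuple_of(p, i), tuple_of(g, j)) >= iou_min
    }
    best <- 0L
    recurse <- function(i, used, count) {
      if (i > nrow(p)) { best <<- max(best, count); return(invisible()) }
      recurse(i + 1L, used, count)
      for (j in seq_len(nrow(g))) {
        if (!used[j] && valid[i, j]) recurse(i + 1L, replace(used, j, TRUE),
                                             count + 1L)
      }
    }
    recurse(1L, rep(FALSE, nrow(g)), 0L)
    total <- total + best
  }
  total
}

ap_oracle <- function(gt_df, pred_df, iou_min = 0.5) {
  thr <- sort(unique(pred_df$score), decreasing = TRUE)
  rec <- numeric(); prec <- numeric()
  for (t in thr) {
    sub <- pred_df[pred_df$score >= t, , drop = FALSE]
    m <- match_oracle(gt_df, sub, iou_min)
    rec <- c(rec, if (m$tp + m$fn == 0) 1 else m$tp / (m$tp + m$fn))
    prec <- c(prec, if (m$tp + m$fp == 0) 1 else m$tp / (m$tp + m$fp))
  }
  ord <- order(rec)
  rec <- rec[ord]; prec <- prec[ord]
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    ap <- ap + (rec[i] - prev_r) * max(prec[i:length(prec)])
    prev_r <- rec[i]
  }
  ap
}

# random detection instance: boxes on a small pixel grid with a few slices
random_instance <- function(seed, max_per_slice = 4L) {
  set.seed(seed)
  mk <- function(n, scored) {
    if (!n) {
      return(data.frame(slice_index = integer(), x_start = integer(),
                        y_start = integer(), x_extent = integer(),
                        y_extent = integer(), label = character(),
                        score = numeric()))
    }
    data.frame(slice_index = sample(0:2, n, replace = TRUE),
               x_start = sample(0:40, n, replace = TRUE),
               y_start = sample(0:40, n, replace = TRUE),
               x_extent = sample(1:20, n, replace = TRUE),
               y_extent = sample(1:20, n, replace = TRUE),
               label = "fracture",
               score = if (scored) round(runif(n), 3) else NA_real_)
  }
  list(gt = mk(sample(0:max_per_slice, 1L) + sample(0:4, 1L), FALSE),
       pred = mk(sample(0:max_per_slice, 1L) + sample(0:4, 1L), TRUE))
}

as_boxset <- function(df) new("BoxSet", boxes = df)

# small fractured phantom shared by several test files
small_fracture_phantom <- function(seed = 1L, noise_sd = 0) {
  generatePhantom(phantomSpec(
    shape = c(96L, 96L, 12L), radius_outer = 18, radius_inner = 12,
    noise_sd = noise_sd, seed = seed,
    fractures = list(list(slices = c(4L, 7L), type = "gap",
                          angle = 30, width = 75))))
}
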