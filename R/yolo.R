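# One-stage detector scaffold: CSPDarknet-53 backbone (five CSP blocks of
# 1, 2, 8, 8, 4 units; convolution -> batch normalization -> mish inside
# each block), SPP + PAN neck, and a three-scale head emitting bounding
# box, object score and class score maps. The forward pass is real (dense
# convolutions via im2col/GEMM); the toy training loop updates the final
# head convolutions with analytic gradients under ADAM and the stepped
# learning-rate schedule.

.mk_conv <- function(k, cin, cout, stride = 1L, act = "mish", bn = TRUE) {
  list(w = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout), stride = as.integer(stride),
       pad = (k - 1L) %/% 2L, act = act, bn = bn,
       gamma = rep(1, cout), beta = numeric(cout),
       mean = numeric(cout), var = rep(1, cout))
}

.mish <- function(x) {
  sp <- x
  i <- x < 20
  sp[i] <- log1p(exp(x[i]))
  x * tanh(sp)
}

.apply_conv <- function(x, ly) {
  y <- .conv2d_cpp(x, ly$w, ly$b, ly$stride, ly$pad)
  if (ly$bn) {
    hw <- dim(y)[1L] * dim(y)[2L]
    sc <- ly$gamma / sqrt(ly$var + 1e-5)
    y <- y * rep(sc, each = hw) + rep(ly$beta - ly$mean * sc, each = hw)
  }
  switch(ly$act,
         mish = .mish(y),
         leaky = pmax(y, 0.1 * y),
         linear = y)
}

.cat_ch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  array(unlist(xs, use.names = FALSE),
        c(d[1L], d[2L], sum(vapply(xs, function(x) dim(x)[3L], integer(1L)))))
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

.conv_seq <- function(x, layers) {
  for (ly in layers) x <- .apply_conv(x, ly)
  x
}

.CSP_CHANNELS <- c(128L, 128L, 256L, 512L, 1024L)
.CSP_UNITS <- c(1L, 2L, 8L, 8L, 4L)

#' Expected backbone feature-map shapes
#'
#' The contract of the five CSP blocks: spatial size halves at each block
#' (so block i of an S x S input is S/2^i on a side) with output channels
#' 128, 128, 256, 512, 1024 and 1, 2, 8, 8, 4 internal units.
#'
#' @param input_size input side length in pixels (divisible by 32).
#' @return `data.frame` with columns `block`, `units`, `out_rows`,
#'   `out_cols`, `out_channels`.
#' @export
backboneShapes <- function(input_size = 512L) {
  if (input_size %% 32L != 0L) .stopf("input_size must be divisible by 32")
  data.frame(block = 1:5, units = .CSP_UNITS,
             out_rows = as.integer(input_size / 2^(1:5)),
             out_cols = as.integer(input_size / 2^(1:5)),
             out_channels = .CSP_CHANNELS)
}

#' Build the one-stage detector network
#'
#' Constructs the CSPDarknet-53 backbone, SPP + PAN neck and three-scale
#' head with seeded random weights (He initialisation; batch normalisation
#' starts as the identity). Each CSP block downsamples by 2 via a strided
#' convolution, splits the feature map into two 1x1-projected halves, runs
#' its residual units on one half, and merges by channel concatenation plus
#' a 1x1 convolution. The SPP pools the deepest map at kernel sizes 5, 9
#' and 13; the PAN adds a bottom-up path so low-level localisation features
#' reach the coarse scales. Heads emit `3 * (5 + num_classes)` channels:
#' box offsets, object score and class scores for 3 anchors per cell.
#'
#' @param config a [detectorConfig()] (uses `input_size`, `num_classes`).
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `YoloNetwork` (a nested weight list).
#' @seealso [forwardYolo()], [trainYolo()], [detectYolo()]
#' @export
buildYolo <- function(config = detectorConfig("yolov4"), seed = 1L) {
  if (config$input_size %% 32L != 0L) .stopf("input_size must be divisible by 32")
  nc <- config$num_classes
  out_ch <- 3L * (5L + nc)
  .with_seed(seed, {
    stages <- list()
    cin <- 32L
    for (i in 1:5) {
      co <- .CSP_CHANNELS[i]
      half <- co %/% 2L
      stages[[i]] <- list(
        down = .mk_conv(3L, cin, co, stride = 2L),
        split1 = .mk_conv(1L, co, half),
        split2 = .mk_conv(1L, co, half),
        units = lapply(seq_len(.CSP_UNITS[i]), function(u) {
          list(c1 = .mk_conv(1L, half, half), c2 = .mk_conv(3L, half, half))
        }),
        merge = .mk_conv(1L, half * 2L, co))
      cin <- co
    }
    neck <- list(
      pre_spp = list(.mk_conv(1L, 1024L, 512L, act = "leaky"),
                     .mk_conv(3L, 512L, 1024L, act = "leaky"),
                     .mk_conv(1L, 1024L, 512L, act = "leaky")),
      post_spp = list(.mk_conv(1L, 2048L, 512L, act = "leaky"),
                      .mk_conv(3L, 512L, 1024L, act = "leaky"),
                      .mk_conv(1L, 1024L, 512L, act = "leaky")),
      up5 = .mk_conv(1L, 512L, 256L, act = "leaky"),
      lat4 = .mk_conv(1L, 512L, 256L, act = "leaky"),
      set4 = list(.mk_conv(1L, 512L, 256L, act = "leaky"),
                  .mk_conv(3L, 256L, 512L, act = "leaky"),
                  .mk_conv(1L, 512L, 256L, act = "leaky"),
                  .mk_conv(3L, 256L, 512L, act = "leaky"),
                  .mk_conv(1L, 512L, 256L, act = "leaky")),
      up4 = .mk_conv(1L, 256L, 128L, act = "leaky"),
      lat3 = .mk_conv(1L, 256L, 128L, act = "leaky"),
      set3 = list(.mk_conv(1L, 256L, 128L, act = "leaky"),
                  .mk_conv(3L, 128L, 256L, act = "leaky"),
                  .mk_conv(1L, 256L, 128L, act = "leaky"),
                  .mk_conv(3L, 128L, 256L, act = "leaky"),
                  .mk_conv(1L, 256L, 128L, act = "leaky")),
      down3 = .mk_conv(3L, 128L, 256L, stride = 2L, act = "leaky"),
      set4b = list(.mk_conv(1L, 512L, 256L, act = "leaky"),
                   .mk_conv(3L, 256L, 512L, act = "leaky"),
                   .mk_conv(1L, 512L, 256L, act = "leaky"),
                   .mk_conv(3L, 256L, 512L, act = "leaky"),
                   .mk_conv(1L, 512L, 256L, act = "leaky")),
      down4 = .mk_conv(3L, 256L, 512L, stride = 2L, act = "leaky"),
      set5b = list(.mk_conv(1L, 1024L, 512L, act = "leaky"),
                   .mk_conv(3L, 512L, 1024L, act = "leaky"),
                   .mk_conv(1L, 1024L, 512L, act = "leaky"),
                   .mk_conv(3L, 512L, 1024L, act = "leaky"),
                   .mk_conv(1L, 1024L, 512L, act = "leaky")))
    heads <- list(
      p3 = list(pre = .mk_conv(3L, 128L, 256L, act = "leaky"),
                out = .mk_conv(1L, 256L, out_ch, act = "linear", bn = FALSE)),
      p4 = list(pre = .mk_conv(3L, 256L, 512L, act = "leaky"),
                out = .mk_conv(1L, 512L, out_ch, act = "linear", bn = FALSE)),
      p5 = list(pre = .mk_conv(3L, 512L, 1024L, act = "leaky"),
                out = .mk_conv(1L, 1024L, out_ch, act = "linear", bn = FALSE)))
    structure(list(config = config,
                   stem = .mk_conv(3L, 3L, 32L),
                   stages = stages, neck = neck, heads = heads),
              class = "YoloNetwork")
  })
}

.csp_forward <- function(x, st) {
  xd <- .apply_conv(x, st$down)
  p1 <- .apply_conv(xd, st$split1)
  p2 <- .apply_conv(xd, st$split2)
  for (u in st$units) p2 <- p2 + .apply_conv(.apply_conv(p2, u$c1), u$c2)
  .apply_conv(.cat_ch(p1, p2), st$merge)
}

#' Run the detector forward pass
#'
#' Propagates an `(S, S, 3)` input through the network. `what = "backbone"`
#' stops after the five CSP blocks (their feature maps are returned as
#' `csp`); `"features"` additionally runs the neck and the pre-output head
#' convolutions (used by the training loop); `"full"` also applies the
#' final 1x1 head convolutions and returns the three raw head maps.
#'
#' @param net a `YoloNetwork` from [buildYolo()].
#' @param input numeric `(S, S, 3)` array with `S` divisible by 32.
#' @param what `"backbone"`, `"features"` or `"full"`.
#' @return list with `csp` (five arrays) and, depending on `what`,
#'   `features` and `raw` (lists of three arrays for strides 8, 16, 32).
#' @export
forwardYolo <- function(net, input, what = c("full", "features", "backbone")) {
  what <- match.arg(what)
  d <- dim(input)
  if (length(d) != 3L || d[3L] != 3L) .stopf("input must be (S, S, 3)")
  if (d[1L] %% 32L != 0L || d[2L] %% 32L != 0L) {
    .stopf("input size must be divisible by 32")
  }
  x <- .apply_conv(input, net$stem)
  csp <- vector("list", 5L)
  for (i in 1:5) {
    x <- .csp_forward(x, net$stages[[i]])
    csp[[i]] <- x
  }
  if (what == "backbone") return(list(csp = csp))

  nk <- net$neck
  x5 <- .conv_seq(csp[[5L]], nk$pre_spp)
  spp <- .cat_ch(x5,
                 .maxpool2d_cpp(x5, 5L, 1L, 2L),
                 .maxpool2d_cpp(x5, 9L, 1L, 4L),
                 .maxpool2d_cpp(x5, 13L, 1L, 6L))
  p5 <- .conv_seq(spp, nk$post_spp)
  p4 <- .conv_seq(.cat_ch(.apply_conv(csp[[4L]], nk$lat4),
                          .upsample2(.apply_conv(p5, nk$up5))), nk$set4)
  p3 <- .conv_seq(.cat_ch(.apply_conv(csp[[3L]], nk$lat3),
                          .upsample2(.apply_conv(p4, nk$up4))), nk$set3)
  n4 <- .conv_seq(.cat_ch(.apply_conv(p3, nk$down3), p4), nk$set4b)
  n5 <- .conv_seq(.cat_ch(.apply_conv(n4, nk$down4), p5), nk$set5b)

  feats <- list(.apply_conv(p3, net$heads$p3$pre),
                .apply_conv(n4, net$heads$p4$pre),
                .apply_conv(n5, net$heads$p5$pre))
  if (what == "features") return(list(csp = csp, features = feats))
  raw <- list(.apply_conv(feats[[1L]], net$heads$p3$out),
              .apply_conv(feats[[2L]], net$heads$p4$out),
              .apply_conv(feats[[3L]], net$heads$p5$out))
  list(csp = csp, features = feats, raw = raw)
}

#' Stepped learning-rate schedule
#'
#' `lr(epoch) = initial_lr * drop_factor^floor(epoch / drop_period)` with
#' 0-based epochs: 0.001 for epochs 0-19, 0.0005 for 20-39, 0.00025 for
#' 40-49 under the defaults.
#'
#' @param epoch 0-based epoch number (vectorised).
#' @param initial_lr starting learning rate.
#' @param drop_period epochs between drops.
#' @param drop_factor multiplicative drop.
#' @return the learning rate(s).
#' @export
lrSchedule <- function(epoch, initial_lr = 0.001, drop_period = 20L,
                       drop_factor = 0.5) {
  initial_lr * drop_factor^floor(epoch / drop_period)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# build per-scale regression/objectness targets for one image's boxes
.yolo_targets <- function(b, net_dim, grids, anchors, input_size, nc) {
  lapply(seq_along(grids), function(s) {
    g <- grids[s]
    stride <- input_size / g
    tgt <- array(0, c(g, g, 3L * (5L + nc)))
    posmask <- array(0, c(g, g, 3L * (5L + nc)))
    if (nrow(b)) {
      for (i in seq_len(nrow(b))) {
        cx <- (b$x_start[i] + b$x_extent[i] / 2)
        cy <- (b$y_start[i] + b$y_extent[i] / 2)
        bw <- b$x_extent[i]; bh <- b$y_extent[i]
        # anchor with best shape match (IoU of centred boxes)
        ious <- vapply(seq_len(nrow(anchors)), function(a) {
          iw <- min(bw, anchors[a, 1L]); ih <- min(bh, anchors[a, 2L])
          iw * ih / (bw * bh + anchors[a, 1L] * anchors[a, 2L] - iw * ih)
        }, numeric(1L))
        best <- which.max(ious)
        if (ceiling(best / 3) != s) next  # belongs to another scale
        a <- (best - 1L) %% 3L
        col <- min(g - 1L, max(0L, floor(cx / stride)))
        row <- min(g - 1L, max(0L, floor(cy / stride)))
        off <- a * (5L + nc)
        frac_x <- min(0.99, max(0.01, cx / stride - col))
        frac_y <- min(0.99, max(0.01, cy / stride - row))
        tgt[row + 1L, col + 1L, off + 1L] <- stats::qlogis(frac_x)
        tgt[row + 1L, col + 1L, off + 2L] <- stats::qlogis(frac_y)
        tgt[row + 1L, col + 1L, off + 3L] <- log(max(bw, 1) / anchors[best, 1L])
        tgt[row + 1L, col + 1L, off + 4L] <- log(max(bh, 1) / anchors[best, 2L])
        tgt[row + 1L, col + 1L, off + 5L] <- 1          # objectness
        tgt[row + 1L, col + 1L, off + 5L + seq_len(nc)] <- 1
        posmask[row + 1L, col + 1L, off + seq_len(4L + nc + 1L)] <- 1
      }
    }
    list(tgt = tgt, pos = posmask)
  })
}

# loss and gradient of the raw head map z against targets; obj/cls use
# sigmoid cross-entropy, box offsets use MSE on the raw parameters
.head_loss_grad <- function(z, tgt, pos, nc) {
  per <- 5L + nc
  d <- dim(z)
  ch <- seq_len(d[3L])
  is_obj <- ((ch - 1L) %% per) == 4L
  is_cls <- ((ch - 1L) %% per) >= 5L
  is_box <- !is_obj & !is_cls
  n_all <- d[1L] * d[2L] * 3L
  n_pos <- max(1, sum(pos[, , is_obj]))

  dz <- array(0, d)
  loss <- 0
  # objectness: BCE over every cell/anchor
  zo <- z[, , is_obj, drop = FALSE]
  yo <- tgt[, , is_obj, drop = FALSE]
  po <- .sigmoid(zo)
  eps <- 1e-9
  loss <- loss + sum(-(yo * log(po + eps) + (1 - yo) * log(1 - po + eps))) / n_all
  dz[, , is_obj] <- (po - yo) / n_all
  # box offsets: MSE at positive cells
  zb <- z[, , is_box, drop = FALSE]
  yb <- tgt[, , is_box, drop = FALSE]
  mb <- pos[, , is_box, drop = FALSE]
  loss <- loss + sum(mb * (zb - yb)^2) / n_pos
  dz[, , is_box] <- 2 * mb * (zb - yb) / n_pos
  # class score: BCE at positive cells
  zc <- z[, , is_cls, drop = FALSE]
  yc <- tgt[, , is_cls, drop = FALSE]
  mc <- pos[, , is_cls, drop = FALSE]
  pc <- .sigmoid(zc)
  loss <- loss +
    sum(mc * -(yc * log(pc + eps) + (1 - yc) * log(1 - pc + eps))) / n_pos
  dz[, , is_cls] <- mc * (pc - yc) / n_pos
  list(loss = loss, dz = dz)
}

#' Toy training loop for the detector head
#'
#' Trains the network on `(image, boxes)` pairs under the configured
#' schedule: ADAM, initial learning rate 0.001 halved every 20 epochs, at
#' most 50 epochs, minibatch 4. The backbone and neck stay frozen at their
#' seeded initialisation and their feature maps are cached per image, so
#' each iteration updates only the final 1x1 head convolutions — their
#' gradients are exact (the raw head maps are linear in those weights).
#' This is a transfer-learning-style loop sized for toy datasets; its
#' contract is a decreasing loss trace, not a clinically trained detector.
#'
#' @param net a `YoloNetwork`.
#' @param dataset list of `list(image = matrix in [0, 1], boxes = BoxSet)`;
#'   images must be square with side `config$input_size`.
#' @param config a [detectorConfig()].
#' @param epochs number of epochs (default `config$max_epochs`).
#' @param val optional validation dataset in the same format.
#' @param seed seed for minibatch shuffling.
#' @return list with `network` (updated), `trace` (`data.frame` with one
#'   row per iteration: `iteration`, `epoch`, `lr`, `loss`) and
#'   `val_trace` (per-epoch validation loss, if `val` given).
#' @export
trainYolo <- function(net, dataset, config = net$config,
                      epochs = config$max_epochs, val = NULL, seed = 1L) {
  if (!length(dataset)) .stopf("empty dataset")
  nc <- config$num_classes
  S <- config$input_size
  grids <- as.integer(S / c(8L, 16L, 32L))

  feats <- lapply(dataset, function(case) {
    stopifnot(all(dim(case$image) == S))
    inp <- array(rep(case$image, 3L), c(S, S, 3L))
    forwardYolo(net, inp, "features")$features
  })
  targets <- lapply(dataset, function(case) {
    .yolo_targets(boxes(case$boxes), S, grids, config$anchors, S, nc)
  })
  val_feats <- lapply(val, function(case) {
    inp <- array(rep(case$image, 3L), c(S, S, 3L))
    forwardYolo(net, inp, "features")$features
  })
  val_targets <- lapply(val, function(case) {
    .yolo_targets(boxes(case$boxes), S, grids, config$anchors, S, nc)
  })

  head_names <- c("p3", "p4", "p5")
  adam <- lapply(head_names, function(h) {
    w <- net$heads[[h]]$out$w
    list(mw = array(0, dim(w)), vw = array(0, dim(w)),
         mb = numeric(length(net$heads[[h]]$out$b)),
         vb = numeric(length(net$heads[[h]]$out$b)), t = 0L)
  })
  names(adam) <- head_names

  loss_of <- function(fts, tgts) {
    total <- 0
    for (s in 1:3) {
      z <- .apply_conv(fts[[s]], net$heads[[head_names[s]]]$out)
      total <- total +
        .head_loss_grad(z, tgts[[s]]$tgt, tgts[[s]]$pos, nc)$loss
    }
    total
  }

  trace <- list()
  val_trace <- list()
  iter <- 0L
  n <- length(dataset)
  for (epoch in seq_len(epochs) - 1L) {
    lr <- lrSchedule(epoch, config$initial_lr, config$drop_period,
                     config$drop_factor)
    ord <- .with_seed(seed + epoch, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$minibatch))
    for (batch in batches) {
      iter <- iter + 1L
      batch_loss <- 0
      grads <- lapply(head_names, function(h) {
        w <- net$heads[[h]]$out$w
        list(dw = array(0, dim(w)), db = numeric(dim(w)[4L]))
      })
      names(grads) <- head_names
      for (bi in batch) {
        for (s in 1:3) {
          h <- head_names[s]
          f <- feats[[bi]][[s]]
          z <- .apply_conv(f, net$heads[[h]]$out)
          lg <- .head_loss_grad(z, targets[[bi]][[s]]$tgt,
                                targets[[bi]][[s]]$pos, nc)
          batch_loss <- batch_loss + lg$loss
          hw <- dim(f)[1L] * dim(f)[2L]
          fm <- matrix(f, hw, dim(f)[3L])
          dzm <- matrix(lg$dz, hw, dim(lg$dz)[3L])
          dw <- crossprod(fm, dzm) / length(batch)
          grads[[h]]$dw <- grads[[h]]$dw +
            array(dw, dim(net$heads[[h]]$out$w))
          grads[[h]]$db <- grads[[h]]$db + colSums(dzm) / length(batch)
        }
      }
      batch_loss <- batch_loss / length(batch)
      for (h in head_names) {  # ADAM step
        st <- adam[[h]]
        st$t <- st$t + 1L
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        st$mw <- b1 * st$mw + (1 - b1) * grads[[h]]$dw
        st$vw <- b2 * st$vw + (1 - b2) * grads[[h]]$dw^2
        st$mb <- b1 * st$mb + (1 - b1) * grads[[h]]$db
        st$vb <- b2 * st$vb + (1 - b2) * grads[[h]]$db^2
        mhat <- st$mw / (1 - b1^st$t); vhat <- st$vw / (1 - b2^st$t)
        net$heads[[h]]$out$w <- net$heads[[h]]$out$w -
          lr * mhat / (sqrt(vhat) + eps)
        mbh <- st$mb / (1 - b1^st$t); vbh <- st$vb / (1 - b2^st$t)
        net$heads[[h]]$out$b <- net$heads[[h]]$out$b -
          lr * mbh / (sqrt(vbh) + eps)
        adam[[h]] <- st
      }
      trace[[iter]] <- data.frame(iteration = iter, epoch = epoch, lr = lr,
                                  loss = batch_loss)
    }
    if (length(val)) {
      vl <- mean(vapply(seq_along(val), function(i) {
        loss_of(val_feats[[i]], val_targets[[i]])
      }, numeric(1L)))
      val_trace[[epoch + 1L]] <- data.frame(epoch = epoch, val_loss = vl)
    }
  }
  list(network = net, trace = do.call(rbind, trace),
       val_trace = if (length(val_trace)) do.call(rbind, val_trace) else NULL)
}

# nearest-neighbour resize of a matrix to (h, w)
.resize_nn <- function(img, h, w) {
  sr <- pmin(nrow(img), floor((seq_len(h) - 0.5) * nrow(img) / h) + 1L)
  sc <- pmin(ncol(img), floor((seq_len(w) - 0.5) * ncol(img) / w) + 1L)
  img[sr, sc, drop = FALSE]
}

# greedy non-maximum suppression within one slice
.nms <- function(b, iou_max) {
  keep <- logical(nrow(b))
  ord <- order(-b$score)
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (boxIou(.box_tuple(b, i), .box_tuple(b, j)) > iou_max) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  b[keep, , drop = FALSE]
}

#' Detect fractures with the network
#'
#' Windows each slice to [0, 1], resizes it to the network input size,
#' runs the forward pass, decodes the three head maps (sigmoid cell
#' offsets, exponential anchor scaling, objectness times class score),
#' keeps detections at or above the score threshold, applies greedy
#' non-maximum suppression, and rescales boxes to original pixel
#' coordinates.
#'
#' @param net a `YoloNetwork` (trained or randomly initialised).
#' @param volume a [VolumeGrid].
#' @param config a [detectorConfig()].
#' @return a scored [BoxSet] (possibly empty).
#' @export
detectYolo <- function(net, volume, config = net$config) {
  stopifnot(is(volume, "VolumeGrid"))
  S <- config$input_size
  nc <- config$num_classes
  v <- voxels(volume)
  m <- sliceMeta(volume)
  out <- list()
  for (k in seq_len(dim(v)[3L])) {
    img <- .resize_nn(.window_slice(v[, , k], config$window), S, S)
    fw <- forwardYolo(net, array(rep(img, 3L), c(S, S, 3L)), "full")
    dets <- list()
    for (s in 1:3) {
      z <- fw$raw[[s]]
      g <- dim(z)[1L]
      stride <- S / g
      CX <- matrix(seq_len(g) - 1L, g, g, byrow = TRUE)
      CY <- matrix(seq_len(g) - 1L, g, g)
      for (a in 0:2) {
        off <- a * (5L + nc)
        anchor <- config$anchors[(s - 1L) * 3L + a + 1L, ]
        # confidences live in the open interval (0, 1): saturated logits must
        # not defeat the threshold bound at 1
        score <- pmin(.sigmoid(z[, , off + 5L]) *
          apply(.sigmoid(z[, , off + 5L + seq_len(nc), drop = FALSE]), c(1, 2), max),
          1 - 1e-12)
        sel <- which(score >= config$score_threshold, arr.ind = TRUE)
        if (!nrow(sel)) next
        for (r in seq_len(nrow(sel))) {
          i <- sel[r, 1L]; j <- sel[r, 2L]
          bx <- (CX[i, j] + .sigmoid(z[i, j, off + 1L])) * stride
          by <- (CY[i, j] + .sigmoid(z[i, j, off + 2L])) * stride
          bw <- anchor[1L] * exp(min(z[i, j, off + 3L], 8))
          bh <- anchor[2L] * exp(min(z[i, j, off + 4L], 8))
          dets[[length(dets) + 1L]] <- data.frame(
            slice_index = k - 1L,
            x_start = (bx - bw / 2) * m$cols[1L] / S,
            y_start = (by - bh / 2) * m$rows[1L] / S,
            x_extent = bw * m$cols[1L] / S,
            y_extent = bh * m$rows[1L] / S,
            label = "fracture", score = score[i, j])
        }
      }
    }
    if (!length(dets)) next
    b <- do.call(rbind, dets)
    b$x_start <- as.integer(.round_half_away(b$x_start))
    b$y_start <- as.integer(.round_half_away(b$y_start))
    b$x_extent <- pmax(1L, as.integer(.round_half_away(b$x_extent)))
    b$y_extent <- pmax(1L, as.integer(.round_half_away(b$y_extent)))
    b <- .clamp_boxes(b, m$cols[1L], m$rows[1L])
    if (nrow(b)) out[[length(out) + 1L]] <- .nms(b, config$nms_iou)
  }
  if (!length(out)) return(boxSet())
  new("BoxSet", boxes = do.call(rbind, out))
}

#' Serialize and restore a network
#'
#' Weights go to `<prefix>.rds` (the package's numeric-array container)
#' with a JSON sidecar `<prefix>.json` describing the architecture.
#'
#' @param net a `YoloNetwork`.
#' @param prefix output path prefix.
#' @return `saveYolo()`: invisibly, the two paths; `loadYolo()`: the network.
#' @export
saveYolo <- function(net, prefix) {
  rds <- paste0(prefix, ".rds")
  js <- paste0(prefix, ".json")
  saveRDS(net, rds)
  side <- list(architecture = "CSPDarknet-53 + SPP/PAN + 3-scale head",
               input_size = net$config$input_size,
               csp_units = .CSP_UNITS, csp_channels = .CSP_CHANNELS,
               num_classes = net$config$num_classes,
               anchors = net$config$anchors)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(rds, js))
}

#' @rdname saveYolo
#' @export
loadYolo <- function(prefix) readRDS(paste0(prefix, ".rds"))
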