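test_that("an intact cortical ring produces no detections", {
  ph <- generatePhantom(phantomSpec(shape = c(96, 96, 8), radius_outer = 18,
                                    radius_inner = 12, noise_sd = 0))
  expect_identical(nBoxes(detectRule(ph$volume)), 0L)
})

test_that("a gap fracture is found on every fractured slice at IoU >= 0.5", {
  ph <- small_fracture_phantom(seed = 6)
  det <- detectRule(ph$volume)
  db <- boxes(det)
  tb <- boxes(ph$truth)
  expect_setequal(unique(db$slice_index), tb$slice_index)
  for (k in tb$slice_index) {
    on_slice <- db[db$slice_index == k, ]
    expect_identical(nrow(on_slice), 1L)
    expect_gte(boxIou(unlist(on_slice[1, 2:5]),
                      unlist(tb[tb$slice_index == k, 2:5])), 0.5)
  }
  expect_true(all(db$score > 0 & db$score <= 1))
})

test_that("the rule detector is deterministic and ignores sub-band noise", {
  ph <- small_fracture_phantom(seed = 7)
  d1 <- detectRule(ph$volume)
  d2 <- detectRule(ph$volume)
  expect_identical(boxes(d1), boxes(d2))
  # perturb HU only where it cannot cross the 1150-1250 band
  v <- voxels(ph$volume)
  pert <- v
  pert[v < 1000] <- pert[v < 1000] + 40
  vol2 <- volumeGrid(pert, pixel_spacing = pixelSpacing(ph$volume),
                     slice_thickness = sliceThickness(ph$volume))
  expect_identical(boxes(detectRule(vol2)), boxes(d1))
})

test_that("backbone feature maps scale proportionally with the input size", {
  cfg <- detectorConfig("yolov4", input_size = 256)
  net <- buildYolo(cfg, seed = 4)
  set.seed(4)
  fw <- forwardYolo(net, array(runif(256 * 256 * 3), c(256, 256, 3)),
                    "backbone")
  dims <- t(vapply(fw$csp, dim, integer(3)))
  expect_identical(dims[, 1], as.integer(256 / 2^(1:5)))
  expect_identical(dims[, 2], as.integer(256 / 2^(1:5)))
  expect_identical(dims[, 3], c(128L, 128L, 256L, 512L, 1024L))
  expect_identical(backboneShapes(256)$out_rows, as.integer(256 / 2^(1:5)))
  expect_error(detectorConfig("yolov4", input_size = 100), "divisible by 32")
  expect_error(forwardYolo(net, array(0, c(100, 100, 3))), "divisible by 32")
})

test_that("the learning-rate schedule is a right-continuous step function", {
  expect_equal(lrSchedule(0), 0.001)
  expect_equal(lrSchedule(19), 0.001)
  expect_equal(lrSchedule(20), 0.0005)
  expect_equal(lrSchedule(25), 0.0005)
  expect_equal(lrSchedule(39), 0.0005)
  expect_equal(lrSchedule(40), 0.00025)
  expect_equal(lrSchedule(45), 0.00025)
  expect_equal(lrSchedule(0:49), 0.001 * 0.5^floor(0:49 / 20))
})

test_that("toy training runs the schedule and the loss decreases", {
  cfg <- detectorConfig("yolov4", input_size = 64)
  net <- buildYolo(cfg, seed = 2)
  ph <- generatePhantom(phantomSpec(shape = c(64, 64, 8), radius_outer = 18,
                                    radius_inner = 12, noise_sd = 0,
                                    pixel_spacing = c(1, 1),
    fractures = list(list(slices = c(2, 6), type = "gap", angle = 45,
                          width = 80))))
  v <- voxels(ph$volume)
  tb <- boxes(ph$truth)
  ds <- lapply(1:8, function(k) {
    list(image = fracture3d:::.window_slice(v[, , k], c(-1000, 2000)),
         boxes = as_boxset(tb[tb$slice_index == k - 1, , drop = FALSE]))
  })
  tr <- trainYolo(net, ds, cfg, epochs = 2, seed = 3)
  expect_identical(nrow(tr$trace), as.integer(ceiling(8 / 4) * 2))  # iterations
  expect_lt(tail(tr$trace$loss, 1), tr$trace$loss[1])
  expect_equal(unique(tr$trace$lr), 0.001)
  expect_error(trainYolo(net, list(), cfg), "empty dataset")
})

test_that("network detections respect the score threshold contract", {
  ph <- generatePhantom(phantomSpec(shape = c(64, 64, 4), radius_outer = 16,
                                    radius_inner = 11, noise_sd = 0))
  cfg1 <- detectorConfig("yolov4", input_size = 64, score_threshold = 1.0)
  net <- buildYolo(cfg1, seed = 1)
  expect_identical(nBoxes(detectYolo(net, ph$volume, cfg1)), 0L)
  cfg2 <- detectorConfig("yolov4", input_size = 64, score_threshold = 0.4)
  det <- detectYolo(net, ph$volume, cfg2)  # untrained: any valid output
  b <- boxes(det)
  if (nrow(b)) {
    expect_true(all(b$score >= 0.4 & b$score <= 1))
    expect_true(all(b$x_extent >= 1 & b$y_extent >= 1))
    expect_true(all(b$x_start >= 0 & b$x_start + b$x_extent <= 64))
  }
  expect_s4_class(det, "BoxSet")
})

test_that("decoded boxes rescale and lift consistently (commutativity)", {
  # a box decoded at network scale then rescaled by r and lifted must equal
  # the same box lifted directly with spacing scaled by r
  r <- 4  # original image 256, network input 64
  vol_orig <- volumeGrid(array(0, c(256, 256, 3)), pixel_spacing = c(0.5, 0.5),
                         slice_thickness = 2)
  vol_net <- volumeGrid(array(0, c(64, 64, 3)), pixel_spacing = c(0.5 * r, 0.5 * r),
                        slice_thickness = 2)
  net_box <- boxSet(slice_index = 1, x_start = 8, y_start = 12, x_extent = 6,
                    y_extent = 5)
  rescaled <- boxSet(slice_index = 1, x_start = 8 * r, y_start = 12 * r,
                     x_extent = 6 * r, y_extent = 5 * r)
  cu_direct <- boxToCuboid(net_box, vol_net)
  cu_rescaled <- boxToCuboid(rescaled, vol_orig)
  expect_equal(cu_rescaled[, c("origin_x", "origin_y", "origin_z",
                               "dx", "dy", "dz")],
               cu_direct[, c("origin_x", "origin_y", "origin_z",
                             "dx", "dy", "dz")])
})

test_that("network serialization round-trips with an architecture sidecar", {
  cfg <- detectorConfig("yolov4", input_size = 64)
  net <- buildYolo(cfg, seed = 9)
  prefix <- file.path(withr::local_tempdir(), "net")
  saveYolo(net, prefix)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_identical(side$csp_units, c(1L, 2L, 8L, 8L, 4L))
  expect_identical(side$csp_channels, c(128L, 128L, 256L, 512L, 1024L))
  net2 <- loadYolo(prefix)
  expect_identical(net2$heads$p3$out$w, net$heads$p3$out$w)
})
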