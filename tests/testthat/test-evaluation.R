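test_that("IoU matches pixel counting on the canonical cases", {
  expect_equal(boxIou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(boxIou(c(0, 0, 10, 10), c(20, 20, 5, 5)), 0)
  expect_equal(boxIou(c(0, 0, 10, 10), c(5, 5, 10, 10)), 25 / 175)
  expect_error(boxIou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "zero-extent")
})

test_that("IoU is symmetric and 1 only for identical boxes", {
  set.seed(12)
  for (i in 1:50) {
    a <- c(sample(0:30, 2, TRUE), sample(1:15, 2, TRUE))
    b <- c(sample(0:30, 2, TRUE), sample(1:15, 2, TRUE))
    expect_identical(boxIou(a, b), boxIou(b, a))
    expect_equal(boxIou(a, b), iou_pixel_oracle(a, b))
    expect_identical(boxIou(a, b) == 1, all(a == b))
  }
})

test_that("greedy matching handles the canonical confusion cases", {
  g <- boxSet(slice_index = c(0, 0, 1), x_start = c(0, 20, 5),
              y_start = c(0, 20, 5), x_extent = c(10, 8, 6),
              y_extent = c(10, 8, 6))
  p <- boxes(g); p$score <- c(0.9, 0.8, 0.7)
  m <- matchDetections(g, as_boxset(p))
  expect_identical(m$counts[c("tp", "fp", "fn")], c(tp = 3L, fp = 0L, fn = 0L))
  expect_equal(m$ious, c(1, 1, 1))

  # one gt, two overlapping predictions: greedy gives tp = 1, fp = 1
  g1 <- boxSet(slice_index = 0, x_start = 0, y_start = 0, x_extent = 10,
               y_extent = 10)
  p2 <- boxSet(slice_index = c(0, 0), x_start = c(0, 1), y_start = c(0, 0),
               x_extent = c(10, 10), y_extent = c(10, 10), score = c(0.9, 0.8))
  m2 <- matchDetections(g1, p2)
  expect_identical(m2$counts[c("tp", "fp")], c(tp = 1L, fp = 1L))

  # no predictions at all
  g2 <- boxSet(slice_index = c(0, 2), x_start = c(0, 0), y_start = c(0, 0),
               x_extent = c(4, 4), y_extent = c(4, 4))
  expect_identical(matchDetections(g2, boxSet())$counts[["fn"]], 2L)
})

test_that("precision and recall follow the confusion-count definitions", {
  expect_equal(precisionOf(c(tp = 3, fp = 1, fn = 0)), 0.75)
  expect_equal(recallOf(c(tp = 3, fp = 0, fn = 0)), 1)
  expect_equal(recallOf(c(tp = 2, fp = 0, fn = 6)), 0.25)
  expect_message(p <- precisionOf(c(tp = 0, fp = 0, fn = 2)), "defined as 1")
  expect_equal(p, 1)
  expect_message(r <- recallOf(c(tp = 0, fp = 3, fn = 0)), "defined as 1")
  expect_equal(r, 1)
})

test_that("the PR curve reproduces the hand-computed rankings", {
  g <- boxSet(slice_index = 0, x_start = 0, y_start = 0, x_extent = 10,
              y_extent = 10)
  hit_first <- boxSet(slice_index = c(0, 0), x_start = c(0, 30),
                      y_start = c(0, 30), x_extent = c(10, 5),
                      y_extent = c(10, 5), score = c(0.9, 0.8))
  expect_equal(prCurve(g, hit_first)@average_precision, 1)
  miss_first <- boxSet(slice_index = c(0, 0), x_start = c(30, 0),
                       y_start = c(30, 0), x_extent = c(5, 10),
                       y_extent = c(5, 10), score = c(0.9, 0.8))
  expect_equal(prCurve(g, miss_first)@average_precision, 0.5)

  g5 <- boxSet(slice_index = 0:4, x_start = rep(0, 5), y_start = rep(0, 5),
               x_extent = rep(8, 5), y_extent = rep(8, 5))
  p5 <- boxes(g5); p5$score <- seq(0.9, 0.5, by = -0.1)
  expect_equal(prCurve(g5, as_boxset(p5))@average_precision, 1)

  empty <- prCurve(g5, boxSet())
  expect_equal(empty@average_precision, 0)
  expect_equal(empty@points$recall, 0)
})

test_that("AP is invariant to monotone score rescaling and stays in [0, 1]", {
  set.seed(30)
  for (i in 1:10) {
    inst <- random_instance(1000 + i)
    pr1 <- prCurve(as_boxset(inst$gt), as_boxset(inst$pred))
    rescaled <- inst$pred
    rescaled$score <- plogis(3 * rescaled$score - 1)  # strictly monotone
    pr2 <- prCurve(as_boxset(inst$gt), as_boxset(rescaled))
    expect_equal(pr1@average_precision, pr2@average_precision, tolerance = 1e-12)
    expect_gte(pr1@average_precision, 0)
    expect_lte(pr1@average_precision, 1)
  }
})

test_that("matching never beats the optimal assignment and agrees with the oracle", {
  set.seed(55)
  for (i in 1:25) {
    inst <- random_instance(2000 + i)
    m <- matchDetections(as_boxset(inst$gt), as_boxset(inst$pred))
    o <- match_oracle(inst$gt, inst$pred)
    expect_identical(unname(m$counts[c("tp", "fp", "fn")]),
                     c(o$tp, o$fp, o$fn))
    expect_lte(m$counts[["tp"]], optimal_tp_oracle(inst$gt, inst$pred))
  }
})

test_that("IoU statistics use the sample (n - 1) convention", {
  s <- iouStats(c(0.5, 0.7))
  expect_equal(s@mean, 0.6)
  expect_equal(s@sd, sqrt(0.02), tolerance = 1e-12)  # 0.141421...
  expect_warning(one <- iouStats(0.8), "single observation")
  expect_equal(one@mean, 0.8)
  expect_equal(one@sd, 0)
  expect_equal(iouStats(rep(0.33, 5))@sd, 0)
  expect_error(iouStats(numeric()), "no matched pairs")
  expect_error(iouStats(c(0.5, 1.2)), "lie in")
})

test_that("metrics reports serialize with one PR table and one IoU block", {
  g <- boxSet(slice_index = 0:2, x_start = c(0, 10, 20), y_start = c(0, 10, 20),
              x_extent = rep(8, 3), y_extent = rep(8, 3))
  p <- boxes(g); p$score <- c(0.9, 0.8, 0.2); p$x_start[3] <- 40
  rep_ <- metricsReport(g, as_boxset(p))
  expect_identical(rep_$counts$tp, 2L)
  expect_identical(rep_$counts$fp, 1L)
  path <- withr::local_tempfile(fileext = ".json")
  writeMetricsReport(rep_, path)
  js <- jsonlite::read_json(path)
  expect_true(all(c("counts", "pr", "average_precision", "iou_mean",
                    "iou_sd") %in% names(js)))
  expect_identical(length(js$average_precision), 1L)
  p1 <- withr::local_tempfile(fileext = ".png")
  plotPrCurve(prCurve(g, as_boxset(p)), p1)
  expect_gt(file.size(p1), 0)
})
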