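test_that("the 4-by-N matrix round trip is the identity", {
  expect_identical(dim(boxesToMatrix(boxSet())@mat), c(4L, 0L))
  one <- boxSet(slice_index = 3, x_start = 10, y_start = 20,
                x_extent = 30, y_extent = 40)
  expect_identical(unname(boxesToMatrix(one)@mat[, 1]), c(10L, 20L, 30L, 40L))
  set.seed(8)
  many <- boxSet(slice_index = sample(0:5, 7, TRUE),
                 x_start = sample(0:50, 7), y_start = sample(0:50, 7),
                 x_extent = sample(1:30, 7), y_extent = sample(1:30, 7),
                 score = c(runif(5), NA, NA))
  expect_identical(boxes(matrixToBoxes(boxesToMatrix(many))), boxes(many))
})

test_that("the identity augmentation leaves image and boxes unchanged", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  b <- boxSet(slice_index = 0, x_start = 5, y_start = 8, x_extent = 10,
              y_extent = 12)
  out <- augmentFlipScale(img, b, flip = FALSE, scale = 1)
  expect_identical(out$image, img)
  expect_identical(boxes(out$boxes), boxes(b))
})

test_that("horizontal flip is an involution and follows W - x - w", {
  img <- matrix(seq_len(512 * 512), 512, 512)
  b <- boxSet(slice_index = 0, x_start = 10, y_start = 20, x_extent = 30,
              y_extent = 40)
  once <- augmentFlipScale(img, b, flip = TRUE, scale = 1)
  expect_identical(boxes(once$boxes)$x_start, 472L)  # 512 - 10 - 30
  expect_identical(boxes(once$boxes)$y_start, 20L)
  twice <- augmentFlipScale(once$image, once$boxes, flip = TRUE, scale = 1)
  expect_identical(twice$image, img)
  expect_identical(boxes(twice$boxes), boxes(b))
})

test_that("scaling multiplies box extents by s within one pixel", {
  img <- matrix(0, 128, 128)
  set.seed(21)
  for (i in 1:20) {
    s <- runif(1, 1, 1.3)
    b <- boxSet(slice_index = 0, x_start = sample(20:60, 1),
                y_start = sample(20:60, 1), x_extent = sample(5:40, 1),
                y_extent = sample(5:40, 1))
    out <- augmentFlipScale(img, b, flip = FALSE, scale = s)
    bb <- boxes(out$boxes)
    expect_equal(nrow(bb), 1L)
    expect_lte(abs(bb$x_extent - s * boxes(b)$x_extent), 1)
    expect_lte(abs(bb$y_extent - s * boxes(b)$y_extent), 1)
  }
})

test_that("drawn augmentations are seed-deterministic and never flip Y", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  b <- boxSet(slice_index = 0, x_start = 4, y_start = 6, x_extent = 8,
              y_extent = 8)
  a1 <- augmentFlipScale(img, b, seed = 7)
  a2 <- augmentFlipScale(img, b, seed = 7)
  expect_identical(a1$image, a2$image)
  expect_true(a1$params$scale >= 1 && a1$params$scale <= 1.3)
  # y_start can only move through scaling about the centre, never mirroring:
  # scaling with s = 1 must keep rows in original order for any flip draw
  a3 <- augmentFlipScale(img, b, flip = TRUE, scale = 1)
  expect_identical(a3$image[, 32:1], img)
})

test_that("shift augmentation produces the requested copies and translations", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  b <- boxSet(slice_index = 0, x_start = 10, y_start = 20, x_extent = 30,
              y_extent = 30, score = NA)
  copies <- augmentShift(img, b, n_copies = 10, max_shift = 5, seed = 3)
  expect_length(copies, 10L)
  zero <- augmentShift(img, b, n_copies = 3, max_shift = 0, seed = 3)
  for (cp in zero) {
    expect_identical(cp$image, img)
    expect_identical(boxes(cp$boxes), boxes(b))
  }
  shifted <- augmentShift(matrix(0, 64, 64), b, n_copies = 50, max_shift = 4,
                          seed = 11)
  for (cp in shifted) {
    bb <- boxes(cp$boxes)
    expect_identical(bb$x_start, 10L + cp$shift[["x"]])
    expect_identical(bb$y_start, 20L + cp$shift[["y"]])
    expect_identical(bb$x_extent, 30L)
    expect_identical(bb$y_extent, 30L)
  }
  expect_error(augmentShift(img, b, n_copies = 2, max_shift = 64), "max_shift")
})

test_that("boxes are dropped only when a transform pushes them fully outside", {
  img <- matrix(0, 32, 32)
  edge <- boxSet(slice_index = 0, x_start = 30, y_start = 30, x_extent = 2,
                 y_extent = 2)
  kept <- augmentShift(img, edge, n_copies = 1, max_shift = 0, seed = 1)
  expect_identical(nBoxes(kept[[1]]$boxes), 1L)
  # a +5 shift pushes the 2-pixel box beyond the 32-pixel image
  out <- list()
  for (seed in 1:50) {
    cp <- augmentShift(img, edge, n_copies = 1, max_shift = 5, seed = seed)[[1]]
    pushed_out <- cp$shift[["x"]] >= 2 || cp$shift[["y"]] >= 2
    expect_identical(nBoxes(cp$boxes) == 0L, pushed_out)
  }
})

test_that("the box TSV round trip is lossless and malformed lines are located", {
  b <- boxSet(slice_index = c(0, 1, 5), x_start = c(1, 2, 3),
              y_start = c(4, 5, 6), x_extent = c(7, 8, 9),
              y_extent = c(10, 11, 12), label = c("fracture", "fracture", "x"),
              score = c(NA, 0.25, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBoxes(b, path)
  expect_identical(boxes(readBoxes(path)), boxes(b))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_identical(nBoxes(readBoxes(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3\t4\t5\tok\t0.5", "1\t2\t3"), bad)
  expect_error(readBoxes(bad), "line 2")
})
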