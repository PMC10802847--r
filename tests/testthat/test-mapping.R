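test_that("pixel boxes lift to physical cuboids by spacing and thickness", {
  v <- volumeGrid(array(0, c(64, 64, 10)), pixel_spacing = c(0.5, 0.5),
                  slice_thickness = 2)
  b <- boxSet(slice_index = 7, x_start = 10, y_start = 20, x_extent = 30,
              y_extent = 40)
  cu <- boxToCuboid(b, v)
  expect_equal(unlist(cu[1, c("origin_x", "origin_y", "origin_z")]),
               c(origin_x = 5, origin_y = 10, origin_z = 14))
  expect_equal(unlist(cu[1, c("dx", "dy", "dz")]), c(dx = 15, dy = 20, dz = 2))
  # identity spacing: the cuboid equals the pixel box with dz = 1
  vi <- volumeGrid(array(0, c(64, 64, 10)))
  cui <- boxToCuboid(b, vi)
  expect_equal(unlist(cui[1, c("origin_x", "origin_y", "origin_z", "dx", "dy",
                               "dz")]),
               c(origin_x = 10, origin_y = 20, origin_z = 7, dx = 30, dy = 40,
                 dz = 1))
  expect_error(boxToCuboid(boxSet(slice_index = 0, x_start = 60, y_start = 0,
                                  x_extent = 10, y_extent = 4), v),
               "outside slice bounds")
})

test_that("the lift is exactly invertible for random boxes", {
  set.seed(17)
  v <- volumeGrid(array(0, c(128, 128, 25)), pixel_spacing = c(0.73, 0.61),
                  slice_thickness = 1.25)
  b <- boxSet(slice_index = sample(0:24, 40, TRUE),
              x_start = sample(0:90, 40, TRUE), y_start = sample(0:90, 40, TRUE),
              x_extent = sample(1:30, 40, TRUE), y_extent = sample(1:30, 40, TRUE),
              score = runif(40))
  rt <- cuboidToBox(boxToCuboid(b, v))
  expect_identical(boxes(rt)[, 1:5], boxes(b)[, 1:5])
  expect_equal(boxes(rt)$score, boxes(b)$score)
})

test_that("stacking merges adjacent overlapping boxes into one component", {
  v <- volumeGrid(array(0, c(64, 64, 10)), pixel_spacing = c(1, 1),
                  slice_thickness = 1.5)
  single <- stackMask(boxToCuboid(boxSet(slice_index = 2, x_start = 5,
                                         y_start = 5, x_extent = 4,
                                         y_extent = 4), v))
  expect_identical(unique(cuboids(single)$component), 1L)
  vox <- voxelizeMask(single, dim(voxels(v)))
  expect_equal(maskVolume(vox), 4 * 4 * 1.5)

  two <- boxSet(slice_index = c(3, 4), x_start = c(10, 10), y_start = c(12, 12),
                x_extent = c(6, 6), y_extent = c(5, 5))
  stacked <- voxelizeMask(stackMask(boxToCuboid(two, v)), dim(voxels(v)))
  expect_identical(unique(cuboids(stacked)$component), 1L)
  expect_equal(maskVolume(stacked), 2 * 6 * 5 * 1.5)  # 2 x box area x t

  apart <- boxSet(slice_index = c(0, 8), x_start = c(1, 40), y_start = c(1, 40),
                  x_extent = c(4, 4), y_extent = c(4, 4))
  comps <- cuboids(stackMask(boxToCuboid(apart, v), merge_gap = 0))$component
  expect_length(unique(comps), 2L)
})

test_that("a single-slice detector miss does not split a fracture component", {
  v <- volumeGrid(array(0, c(32, 32, 12)))
  gapped <- boxSet(slice_index = c(3, 5), x_start = c(8, 8), y_start = c(8, 8),
                   x_extent = c(6, 6), y_extent = c(6, 6))
  expect_length(unique(cuboids(stackMask(boxToCuboid(gapped, v),
                                         merge_gap = 1))$component), 1L)
  expect_length(unique(cuboids(stackMask(boxToCuboid(gapped, v),
                                         merge_gap = 0))$component), 2L)
})

test_that("voxelized volume is conserved for pairwise-disjoint cuboids", {
  set.seed(23)
  v <- volumeGrid(array(0, c(64, 64, 12)), pixel_spacing = c(0.8, 0.8),
                  slice_thickness = 1.2)
  # place disjoint boxes on distinct slices
  b <- boxSet(slice_index = 0:9, x_start = sample(0:40, 10),
              y_start = sample(0:40, 10), x_extent = sample(2:12, 10, TRUE),
              y_extent = sample(2:12, 10, TRUE))
  m3 <- voxelizeMask(stackMask(boxToCuboid(b, v)), dim(voxels(v)))
  cu <- cuboids(m3)
  expect_equal(maskVolume(m3), sum(cu$dx * cu$dy * cu$dz))
})

test_that("the overlay writes a deterministic scene and never mutates inputs", {
  ph <- small_fracture_phantom(seed = 3)
  mask <- thresholdBone(ph$volume)
  mesh <- capMesh(extractSurface(mask), mask)
  det <- detectRule(ph$volume)
  m3 <- voxelizeMask(stackMask(boxToCuboid(det, ph$volume)),
                     dim(voxels(ph$volume)))
  mesh_before <- meshVertices(mesh)
  cu_before <- cuboids(m3)
  d <- withr::local_tempdir()
  p1 <- overlayScene(mesh, m3, file.path(d, "s1"))
  p2 <- overlayScene(mesh, m3, file.path(d, "s2"))
  expect_true(all(file.exists(p1)))
  expect_identical(meshVertices(mesh), mesh_before)
  expect_identical(cuboids(m3), cu_before)
  expect_identical(readBin(p1[2], "raw", file.size(p1[2])),
                   readBin(p2[2], "raw", file.size(p2[2])))
  gltf <- jsonlite::read_json(p1[1])
  expect_length(gltf$meshes, 1L + length(unique(cuboids(m3)$component)))
  expect_identical(gltf$asset$version, "2.0")
})

test_that("an empty mask renders the mesh only; fractures appear as red components", {
  ph <- small_fracture_phantom(seed = 4)
  mask <- thresholdBone(ph$volume)
  mesh <- capMesh(extractSurface(mask), mask)
  d <- withr::local_tempdir()
  empty <- stackMask(boxToCuboid(boxSet(), ph$volume))
  p <- overlayScene(mesh, empty, file.path(d, "empty"))
  expect_length(jsonlite::read_json(p[1])$meshes, 1L)

  # one fracture: the red component's bounding box contains the centroid of
  # the generator's disrupted voxels
  det <- detectRule(ph$volume)
  m3 <- stackMask(boxToCuboid(det, ph$volume))
  cu <- cuboids(m3)
  idx <- which(ph$disrupted == 1L, arr.ind = TRUE)
  centroid <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1, mean(idx[, 3]) - 1)
  sp <- c(pixelSpacing(ph$volume), sliceThickness(ph$volume))
  cmm <- centroid * c(sp[1], sp[2], sp[3])
  expect_true(any(
    cmm[1] >= cu$origin_x & cmm[1] <= cu$origin_x + cu$dx &
    cmm[2] >= cu$origin_y & cmm[2] <= cu$origin_y + cu$dy &
    cmm[3] >= cu$origin_z - cu$dz & cmm[3] <= cu$origin_z + 2 * cu$dz))
})

test_that("two separated fractures give two red components", {
  ph <- generatePhantom(phantomSpec(shape = c(96, 96, 20), radius_outer = 18,
                                    radius_inner = 12, noise_sd = 0,
    fractures = list(
      list(slices = c(2, 4), type = "gap", angle = 0, width = 70),
      list(slices = c(14, 16), type = "gap", angle = 180, width = 70))))
  det <- detectRule(ph$volume)
  m3 <- stackMask(boxToCuboid(det, ph$volume))
  expect_length(unique(cuboids(m3)$component), 2L)
})

test_that("meshes and masks from different series cannot be overlaid", {
  ph1 <- small_fracture_phantom(seed = 5)
  ph2 <- generatePhantom(phantomSpec(shape = c(96, 96, 12), radius_outer = 17,
                                     radius_inner = 11, noise_sd = 0))
  mask1 <- thresholdBone(ph1$volume)
  mesh1 <- capMesh(extractSurface(mask1), mask1)
  m3 <- stackMask(boxToCuboid(boxSet(slice_index = 0, x_start = 0, y_start = 0,
                                     x_extent = 2, y_extent = 2), ph2$volume))
  expect_error(overlayScene(mesh1, m3, tempfile()), "coordinate-frame mismatch")
})
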