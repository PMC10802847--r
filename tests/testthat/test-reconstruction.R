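test_that("HU thresholding keeps the closed 1150-1250 band", {
  v <- volumeGrid(array(c(1200, 1100, -1000, 1150, 1250, 1251), c(1, 6, 1)))
  m <- voxels(thresholdBone(v))
  expect_identical(as.vector(m), c(1L, 0L, 0L, 1L, 1L, 0L))
  air <- volumeGrid(array(-1000, c(8, 8, 3)))
  expect_equal(sum(voxels(thresholdBone(air))), 0)
  expect_error(thresholdBone(v, 1250, 1150), "reversed bounds")
})

test_that("widening the HU interval never removes foreground voxels", {
  set.seed(3)
  v <- volumeGrid(array(runif(8^3, 1000, 1400), c(8, 8, 8)))
  narrow <- voxels(thresholdBone(v, 1150, 1250))
  wide <- voxels(thresholdBone(v, 1100, 1300))
  expect_true(all(wide[narrow == 1L] == 1L))
})

test_that("a solid cube meshes watertight with near-analytic volume", {
  cube <- array(0L, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- 1L
  bm <- boneMask(cube, spacing = c(1, 1, 1))
  mesh <- extractSurface(bm)
  expect_true(isWatertight(mesh))
  expect_lt(abs(meshVolume(mesh) - 1000) / 1000, 0.05)
  # voxel-count/volume consistency within 10% for a >= 10^3 voxel blob
  expect_lt(abs(meshVolume(mesh) - sum(cube) * 1) / sum(cube), 0.10)
})

test_that("a single voxel yields a small closed component of Euler characteristic 2", {
  sv <- array(0L, c(3, 3, 3))
  sv[2, 2, 2] <- 1L
  mesh <- extractSurface(boneMask(sv, c(1, 1, 1)), min_component = 1)
  expect_true(isWatertight(mesh))
  expect_identical(meshEuler(mesh), 2L)
})

test_that("an empty mask is an error", {
  expect_error(extractSurface(boneMask(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "no bone found")
})

test_that("small components are filtered with a message", {
  m <- array(0L, c(16, 16, 4))
  m[4:12, 4:12, 1:4] <- 1L   # large block
  m[15, 15, 1] <- 1L         # single-voxel speck
  expect_message(mesh <- extractSurface(boneMask(m, c(1, 1, 1))),
                 "dropping 1 component")
  expect_true(isWatertight(capMesh(mesh, boneMask(m, c(1, 1, 1)))))
})

test_that("a tube spanning the full slice range caps to a watertight mesh", {
  ph <- small_fracture_phantom(seed = 2)
  mask <- thresholdBone(ph$volume)
  open_mesh <- extractSurface(mask)
  expect_false(isWatertight(open_mesh))  # open at the axial ends
  capped <- capMesh(open_mesh, mask)
  expect_true(isWatertight(capped))
  expect_gte(meshVolume(capped), meshVolume(open_mesh) * 0.99)
})

test_that("capping an already-closed mesh adds no faces", {
  blob <- array(0L, c(10, 10, 10))
  blob[3:8, 3:8, 3:8] <- 1L
  bm <- boneMask(blob, c(1, 1, 1))
  mesh <- extractSurface(bm)
  capped <- capMesh(mesh, bm)
  expect_identical(meshFaces(capped), meshFaces(mesh))
  expect_identical(meshVertices(capped), meshVertices(mesh))
})

test_that("an interior slab touching the first slice is capped on that plane", {
  slab <- array(0L, c(12, 12, 6))
  slab[3:10, 3:10, 1:3] <- 1L  # touches the first slice plane only
  bm <- boneMask(slab, c(1, 1, 1))
  open_mesh <- extractSurface(bm)
  expect_false(isWatertight(open_mesh))
  capped <- capMesh(open_mesh, bm)
  expect_true(isWatertight(capped))
  # cap vertices sit on the z = -0.5 plane (half a voxel before slice 0)
  expect_equal(min(meshVertices(capped)[, 3]), -0.5)
})

test_that("capMesh refuses a mesh from a different mask", {
  a <- boneMask(array(1L, c(4, 4, 4)), c(1, 1, 1))
  b <- boneMask(array(1L, c(5, 5, 5)), c(1, 1, 1))
  mesh <- extractSurface(a, min_component = 1)
  expect_error(capMesh(mesh, b), "not derived")
})

test_that("mesh and mask exports write valid files", {
  blob <- array(0L, c(8, 8, 8))
  blob[3:6, 3:6, 3:6] <- 1L
  bm <- boneMask(blob, c(0.5, 0.5, 1))
  mesh <- extractSurface(bm)
  d <- withr::local_tempdir()
  writePLY(mesh, file.path(d, "m.ply"))
  writePLY(mesh, file.path(d, "mb.ply"), binary = TRUE)
  writeSTL(mesh, file.path(d, "m.stl"))
  writeSTL(mesh, file.path(d, "mb.stl"), binary = TRUE)
  ply <- readLines(file.path(d, "m.ply"), n = 20)
  expect_identical(ply[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(meshVertices(mesh))),
                        ply)))
  stl <- readLines(file.path(d, "m.stl"))
  expect_identical(sum(grepl("^facet", stl)), nrow(meshFaces(mesh)))
  nii <- file.path(d, "mask.nii.gz")
  writeMaskNifti(bm, nii)
  back <- RNifti::readNifti(nii)
  expect_equal(sum(back), sum(blob))
  expect_equal(RNifti::pixdim(back), c(0.5, 0.5, 1))
})
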