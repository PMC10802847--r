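test_that("an empty directory yields a 'no series found' error", {
  d <- withr::local_tempdir()
  expect_error(readDicomSeries(d), "no series found")
  expect_error(readDicomSeries(file.path(d, "missing")), "no series found")
})

test_that("write/read round trip preserves voxels exactly and metadata", {
  set.seed(42)
  v <- volumeGrid(array(sample(-1024:2000, 512 * 512 * 5, replace = TRUE),
                        c(512, 512, 5)),
                  pixel_spacing = c(0.8, 0.8), slice_thickness = 1.0)
  d <- withr::local_tempdir()
  files <- writeDicomSeries(v, d)
  expect_length(files, 5L)
  v2 <- readDicomSeries(d)
  expect_identical(dim(voxels(v2)), c(512L, 512L, 5L))
  expect_identical(voxels(v2), voxels(v))
  expect_equal(sliceMeta(v2), sliceMeta(v), tolerance = 1e-9)
})

test_that("rescale slope/intercept recover HU from stored values", {
  stored <- matrix(c(0L, 24L, 1024L, 2224L), 2, 2)
  v <- volumeGrid(array(stored - 1024, c(2, 2, 1)),
                  rescale_slope = 1, rescale_intercept = -1024)
  d <- withr::local_tempdir()
  writeDicomSeries(v, d)
  expect_equal(voxels(readDicomSeries(d))[, , 1], stored - 1024)
})

test_that("a one-slice volume writes exactly one file", {
  v <- volumeGrid(array(0, c(8, 8, 1)))
  d <- withr::local_tempdir()
  writeDicomSeries(v, d)
  expect_length(list.files(d), 1L)
})

test_that("heterogeneous series and bad meta are refused", {
  d <- withr::local_tempdir()
  writeDicomSeries(volumeGrid(array(0, c(8, 8, 1)), pixel_spacing = c(1, 1)), d)
  # second slice with different spacing, different index so both files remain
  v2 <- volumeGrid(array(0, c(8, 8, 1)), pixel_spacing = c(2, 2),
                   slice_index = 1L)
  writeDicomSeries(v2, d)
  expect_error(readDicomSeries(d), "heterogeneous series")
  expect_error(volumeGrid(array(0, c(4, 4, 3)), slice_index = c(0, 1)),
               "slice_index length")
})

test_that("missing spacing tags raise 'incomplete header', missing rescale warns", {
  d <- withr::local_tempdir()
  # hand-build a file lacking PixelSpacing via the writer's own primitives
  pix <- writeBin(rep(0L, 16), raw(), size = 2L, endian = "little")
  els <- c(
    fracture3d:::.dcm_us(0x0028, 0x0010, 4L),
    fracture3d:::.dcm_us(0x0028, 0x0011, 4L),
    fracture3d:::.dcm_element(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(raw(128L), charToRaw("DICM"), els), file.path(d, "bad.dcm"))
  expect_error(readDicomSeries(d), "incomplete header")

  d2 <- withr::local_tempdir()
  els2 <- c(
    fracture3d:::.dcm_str(0x0018, 0x0050, "DS", "1"),
    fracture3d:::.dcm_us(0x0028, 0x0010, 4L),
    fracture3d:::.dcm_us(0x0028, 0x0011, 4L),
    fracture3d:::.dcm_str(0x0028, 0x0030, "DS", "1\\1"),
    fracture3d:::.dcm_element(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(raw(128L), charToRaw("DICM"), els2), file.path(d2, "nores.dcm"))
  expect_warning(v <- readDicomSeries(d2), "rescale tags absent")
  expect_equal(voxels(v)[1, 1, 1], 0)  # slope 1, intercept 0 assumed
})

test_that("pydicom reads the series back with matching geometry and pixels", {
  v <- volumeGrid(array(sample(-1000:1500, 16 * 16 * 2, replace = TRUE),
                        c(16, 16, 2)),
                  pixel_spacing = c(0.7, 0.9), slice_thickness = 2.5)
  d <- withr::local_tempdir()
  writeDicomSeries(v, d)
  script <- sprintf(paste0(
    "import pydicom, glob, sys\n",
    "fs = sorted(glob.glob('%s/*.dcm'))\n",
    "tot = 0.0\n",
    "for f in fs:\n",
    "    ds = pydicom.dcmread(f)\n",
    "    tot += float((ds.pixel_array * ds.RescaleSlope + ds.RescaleIntercept).sum())\n",
    "ds = pydicom.dcmread(fs[0])\n",
    "print(ds.Rows, ds.Columns, float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1]),",
    " float(ds.SliceThickness), tot)\n"), normalizePath(d))
  out <- system2("python", c("-"), input = script, stdout = TRUE)
  vals <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  # pydicom reports PixelSpacing as (row, column) spacing
  expect_equal(vals, c(16, 16, 0.9, 0.7, 2.5, sum(voxels(v))))
})

test_that("PNG export windows, clamps and counts slices correctly", {
  d <- withr::local_tempdir()
  # uniform slice at the window midpoint -> 128 under round-half-away
  v <- volumeGrid(array(0, c(4, 4, 1)))
  volumeToPng(v, d, window = c(-1000, 1000))
  expect_equal(unique(as.vector(png::readPNG(file.path(d, "slice_0000.png")))),
               128 / 255)
  # everything at the lower clamp -> all zero
  d2 <- withr::local_tempdir()
  volumeToPng(volumeGrid(array(-1000, c(4, 4, 1))), d2, window = c(-1000, 1000))
  expect_true(all(png::readPNG(file.path(d2, "slice_0000.png")) == 0))
  # one PNG per slice, names lexically sortable in slice order
  d3 <- withr::local_tempdir()
  v3 <- volumeGrid(array(rep(c(-500, 0, 500), each = 16), c(4, 4, 3)))
  volumeToPng(v3, d3, window = c(-1000, 1000))
  files <- list.files(d3)
  expect_identical(files, sort(files))
  expect_length(files, 3L)
  means <- vapply(file.path(d3, files),
                  function(f) mean(png::readPNG(f)), numeric(1))
  expect_true(all(diff(means) > 0))  # monotone in HU
  expect_error(volumeToPng(v3, d3, window = c(10, 10)), "degenerate window")
})
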