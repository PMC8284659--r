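test_that("container constructors enforce their invariants", {
  expect_error(movie_stack(array(0, c(1, 8, 8)), 0.1, 1), "T >= 2")
  expect_error(movie_stack(array(0, c(3, 8, 8)), -1, 1), "positive")
  expect_error(axon_trace(rbind(c(0, 0), c(0, 0)), 0.1), "distinct")
  expect_error(axon_trace(matrix(c(0, 0), 1, 2), 0.1), ">= 2 vertices")
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1)), "curl"), ">= 3")
  ## a bow-tie self-intersects
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "simple")
  expect_error(image2d(matrix(NA_real_, 2, 2), 0.1), "finite")
})

test_that("stack write/read round-trips integer and float data", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "mov.tif")
  frames <- array(sample(0:4095, 3 * 8 * 8, TRUE), c(3, 8, 8))
  write_stack(movie_stack(frames, 0.1, 1), f)
  rt <- read_stack(f)
  expect_identical(rt$frames, frames + 0)   # integer data exact
  expect_equal(rt$pixel_size_um, 0.1)
  expect_equal(rt$frame_interval_s, 1)

  frames2 <- array(rnorm(3 * 8 * 8, 100, 20), c(3, 8, 8))
  write_stack(movie_stack(frames2, 0.2, 2), f)
  rt2 <- read_stack(f)
  expect_lt(max(abs(rt2$frames - frames2)), 1e-4)   # float32 storage
})

test_that("stack writing is deterministic byte for byte", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.tif"); f2 <- file.path(dir, "b.tif")
  frames <- array(runif(2 * 8 * 8) * 500, c(2, 8, 8))
  write_stack(movie_stack(frames, 0.1, 1), f1)
  write_stack(movie_stack(frames, 0.1, 1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("single-page movies and missing calibration are rejected", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "one.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), f)
  expect_error(read_stack(f, 0.1, 1), "T >= 2")
  f2 <- file.path(dir, "two.tif")
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.5, 8, 8)), f2)
  expect_error(read_stack(f2), "calibration")
  expect_error(read_image(f, pixel_size_um = NULL), "calibration")
  ## sidecar calibration is honoured
  m <- read_stack(f2, pixel_size_um = 0.1, frame_interval_s = 2)
  expect_equal(m$pixel_size_um, 0.1)
})

test_that("ROI JSON dialect round-trips traces and polygons exactly", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rois.json")
  tr <- axon_trace(rbind(c(0, 0), c(3, 4), c(7.5, 4.25)), 0.1)
  pg <- polygon_roi(rbind(c(1, 1), c(4, 1), c(4, 5)), "swelling")
  write_rois(list(tr), list(pg), f)
  rt <- read_rois(f)
  expect_equal(rt$traces[[1]]$vertices, tr$vertices)
  expect_equal(rt$polygons[[1]]$vertices, pg$vertices)
  expect_equal(rt$polygons[[1]]$label, "swelling")
  expect_equal(rt$traces[[1]]$pixel_size_um, 0.1)
})

test_that("ROI CSV dialect reads one vertex per row", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rois.csv")
  df <- data.frame(roi_id = c(1, 1, 2, 2, 2), type = c("trace", "trace",
                   rep("polygon", 3)), label = c("", "", rep("curl", 3)),
                   x = c(0, 3, 1, 4, 4), y = c(0, 4, 1, 1, 5))
  write.csv(df, f, row.names = FALSE)
  rt <- read_rois(f, pixel_size_um = 0.2)
  expect_length(rt$traces, 1)
  expect_length(rt$polygons, 1)
  expect_equal(unname(rt$traces[[1]]$vertices[2, ]), c(3, 4))
  expect_error(read_rois(f), "calibration")
})

## Minimal ImageJ .roi writer used only as a test fixture
write_imagej_roi <- function(path, type, xs, ys) {
  left <- min(xs); top <- min(ys)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")            # version
  writeBin(as.raw(c(type, 0)), con)                        # type byte
  writeBin(as.integer(c(top, left, max(ys) + 1, max(xs) + 1,
                        length(xs))), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                              # pad header
  writeBin(as.integer(xs - left), con, size = 2, endian = "big")
  writeBin(as.integer(ys - top), con, size = 2, endian = "big")
}

test_that("ImageJ .roi import converts polyline and freehand types", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "trace.roi")
  write_imagej_roi(f, 5L, c(10, 20, 30), c(5, 9, 5))       # polyline
  rt <- read_rois(f, pixel_size_um = 0.1)
  expect_length(rt$traces, 1)
  ## ImageJ pixel-corner origin shifts by -0.5 px
  expect_equal(unname(rt$traces[[1]]$vertices[1, ]), c(9.5, 4.5))

  f2 <- file.path(dir, "poly.roi")
  write_imagej_roi(f2, 7L, c(1, 8, 8, 1), c(1, 1, 6, 6))   # freehand
  rt2 <- read_rois(f2, pixel_size_um = 0.1)
  expect_length(rt2$polygons, 1)

  f3 <- file.path(dir, "oval.roi")
  write_imagej_roi(f3, 2L, c(1, 8), c(1, 6))               # oval
  expect_error(read_rois(f3, pixel_size_um = 0.1), "oval")
})
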