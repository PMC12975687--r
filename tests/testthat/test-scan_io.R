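test_that("TIFF round trip preserves pixels, bit depth and channel count", {
  img <- uniform_scan(12345, n = 16)
  f <- withr::local_tempfile(fileext = ".tif")
  write_scan(img, f)
  back <- read_scan(f, dpi = 300)
  expect_identical(back$bit_depth, 16L)
  expect_identical(back$channels, 1L)
  expect_equal(back$dpi, 300)
  expect_equal(back$pixels, img$pixels)

  rgb <- scan_image(array(c(matrix(100, 8, 8), matrix(200, 8, 8),
                            matrix(50, 8, 8)), c(8, 8, 3)), dpi = 300)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_scan(rgb, f2)
  back2 <- read_scan(f2, dpi = 300)
  expect_identical(back2$channels, 3L)
})

test_that("read_scan rejects unreadable files and requires a dpi", {
  junk <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(1:64), junk)
  expect_error(read_scan(junk), "unreadable scan")
  expect_error(read_scan(tempfile()), "unreadable")

  img <- uniform_scan(10, n = 8)
  f <- withr::local_tempfile(fileext = ".tif")
  write_scan(img, f)  # writer emits no resolution tags
  expect_error(read_scan(f), "dpi")
})

test_that("extract_red_channel keeps the R plane and rejects odd layouts", {
  r <- matrix(100, 6, 6); g <- matrix(7, 6, 6); b <- matrix(3, 6, 6)
  rgb <- scan_image(array(c(r, g, b), c(6, 6, 3)), dpi = 300)
  red <- extract_red_channel(rgb)
  expect_identical(red$channels, 1L)
  expect_true(all(red$pixels == 100))

  mono <- uniform_scan(42, n = 6)
  expect_identical(extract_red_channel(mono)$pixels, mono$pixels)

  four <- scan_image(array(1, c(6, 6, 4)), dpi = 300)
  expect_error(extract_red_channel(four), "1 or 3 channels")
})

test_that("roi_stats matches the exhaustive pixel-enumeration oracle", {
  set.seed(11)
  px <- matrix(sample.int(60000, 40 * 40, replace = TRUE), 40, 40)
  img <- scan_image(px, dpi = 300)
  pitch <- 25.4 / 300
  # 1-mm ROI at several centres, including off-pixel-centre positions
  for (c_mm in list(c(20, 20) * pitch, c(19.5, 20.25) * pitch,
                    c(17.3, 22.8) * pitch)) {
    st <- roi_stats(img, roi_circle(c_mm[1], c_mm[2], 1))
    bf <- brute_force_roi(px, 300, c_mm[1], c_mm[2], 1)
    expect_identical(st$n_pixels, bf$n_pixels)
    expect_equal(st$mean_pv, bf$mean_pv)
    expect_equal(st$sd_pv, bf$sd_pv)
  }
})

test_that("uniform image gives sd zero; split image averages the halves", {
  img <- uniform_scan(500, n = 30)
  st <- roi_stats(img, roi_circle(1.2, 1.2, 1))
  expect_equal(st$mean_pv, 500)
  expect_identical(st$sd_pv, 0)

  a <- 1000; b <- 3000
  px <- cbind(matrix(a, 40, 20), matrix(b, 40, 20))
  img2 <- scan_image(px, dpi = 300)
  pitch <- 25.4 / 300
  c_mm <- c(19.5, 20) * pitch  # centred on the a/b boundary
  st2 <- roi_stats(img2, roi_circle(c_mm[1], c_mm[2], 1))
  bf <- brute_force_roi(px, 300, c_mm[1], c_mm[2], 1)
  expect_equal(st2$mean_pv, bf$mean_pv)
  expect_lt(abs(st2$mean_pv - (a + b) / 2), abs(b - a) * 0.15)
})

test_that("roi_stats is translation-equivariant and monotone in diameter", {
  set.seed(7)
  base <- matrix(sample.int(1000, 24 * 24, replace = TRUE), 24, 24)
  pitch <- 25.4 / 300
  img <- scan_image(base, dpi = 300)
  st0 <- roi_stats(img, roi_circle(10 * pitch, 10 * pitch, 1))
  for (shift in list(c(1, 0), c(0, 2), c(3, 2))) {
    shifted <- base[c((1 + shift[2]):24, 1:shift[2]),
                    c((1 + shift[1]):24, 1:shift[1]), drop = FALSE]
    # shifting image content one way equals shifting the ROI the other way
    img_s <- scan_image(shifted, dpi = 300)
    st_s <- roi_stats(img_s, roi_circle((10 - shift[1]) * pitch,
                                        (10 - shift[2]) * pitch, 1))
    expect_equal(st_s$mean_pv, st0$mean_pv)
    expect_identical(st_s$n_pixels, st0$n_pixels)
  }

  ns <- vapply(seq(0.2, 1.0, by = 0.1), function(d) {
    roi_stats(img, roi_circle(12 * pitch, 12 * pitch, d))$n_pixels
  }, integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("out-of-bounds and empty ROIs are rejected", {
  img <- uniform_scan(5, n = 10)
  expect_error(roi_stats(img, roi_circle(0, 0, 1)), "outside image")
  expect_error(roi_stats(img, roi_circle(100, 100, 1)), "outside image")
  # tiny circle between pixel centres contains none
  pitch <- 25.4 / 300
  expect_error(roi_stats(img, roi_circle(4.5 * pitch, 4.5 * pitch,
                                         0.1 * pitch)),
               "no pixel centers")
})

test_that("ROI tables read from CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("center_x_mm,center_y_mm,diameter_mm,label",
               "1.0,2.0,1.0,p1", "3.0,4.0,1.0,p2"), f)
  rois <- read_roi_table(f)
  expect_length(rois, 2)
  expect_equal(rois[[2]]$center_x_mm, 3)
  expect_error(read_roi_table({
    g <- withr::local_tempfile(fileext = ".csv")
    writeLines("x,y\n1,2", g); g
  }), "columns")
})
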