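test_that("image read/write round-trips 8-bit values and converts RGB by luminance", {
  img <- matrix(c(0, 128, 255, 64) / 255, 2, 2, byrow = TRUE)
  f <- tmp_png(img)
  back <- read_gray(f)
  expect_equal(back, img)

  f2 <- tempfile(fileext = ".tif")
  write_gray(img, f2)
  expect_equal(read_gray(f2), img)

  rgb <- array(0, c(2, 2, 3))
  rgb[, , 1] <- 1   # pure red
  f3 <- tempfile(fileext = ".png")
  png::writePNG(rgb, f3)
  lum <- read_gray(f3)
  expect_equal(lum[1, 1], round(0.299 * 255) / 255, tolerance = 1 / 255)

  expect_error(read_gray(tempfile()), "does not exist")
})

test_that("bit-plane codec matches binary expansion and round-trips all 256 values", {
  st <- bitplane_decompose(matrix(170 / 255, 1, 1))   # 10101010
  expect_equal(vapply(st$planes, function(p) p[1, 1], 1),
               c(-1, 1, -1, 1, -1, 1, -1, 1))
  expect_true(all(vapply(bitplane_decompose(matrix(0, 1, 1))$planes,
                         function(p) p[1, 1], 1) == -1))
  expect_true(all(vapply(bitplane_decompose(matrix(1, 1, 1))$planes,
                         function(p) p[1, 1], 1) == 1))
  only_msb <- bitplane_decompose(matrix(128 / 255, 1, 1))
  expect_equal(bitplane_recompose(only_msb)[1, 1], 128 / 255)

  vals <- (0:255) / 255
  img <- matrix(vals, 16, 16)
  expect_equal(bitplane_recompose(bitplane_decompose(img)), img)

  bad <- bitplane_decompose(img)
  bad$planes[[3]][1, 1] <- 0
  expect_error(bitplane_recompose(bad), "-1 or \\+1")
})

test_that("partition tiles the padded image exactly and reassembles bit-exactly", {
  set.seed(42)
  img <- matrix(runif(220 * 200), 220, 200)
  g <- partition_grid(img, 22, 20)
  expect_length(g$patches, 440)
  expect_equal(c(g$patch_h, g$patch_w), c(10, 10))
  expect_identical(assemble_patches(g, lapply(seq_len(440), get_patch,
                                              grid = g)), img)

  img2 <- matrix(runif(100 * 100), 100, 100)
  g2 <- partition_grid(img2, 3, 3)
  expect_equal(dim(g2$padded), c(102, 102))
  expect_equal(c(g2$patch_h, g2$patch_w), c(34, 34))
  expect_identical(assemble_patches(g2, lapply(1:9, get_patch, grid = g2)),
                   img2)

  g3 <- partition_grid(img2, 1, 1)
  expect_identical(get_patch(g3, 1), img2)

  expect_error(partition_grid(matrix(0.5, 2, 2), 3, 3), "exceeds")
})

test_that("patch normalization z-scores, rescales to [0,1] and inverts", {
  two <- matrix(c(0, 1), 1, 2)
  np <- normalize_patch(two)
  expect_equal(np$patch, two)   # two-point z-score + min-max is the identity

  const <- matrix(0.5, 3, 3)
  nc <- normalize_patch(const)
  expect_identical(nc$patch, const)
  expect_identical(nc$norm$var, 0)
  expect_true(nc$norm$degenerate)
  expect_identical(denormalize_patch(nc$patch, nc$norm), const)

  set.seed(7)
  for (i in 1:20) {
    p <- matrix(runif(30), 5, 6)
    np <- normalize_patch(p)
    z <- np$patch * (np$norm$zmax - np$norm$zmin) + np$norm$zmin
    expect_equal(var(as.vector(z)), 1, tolerance = 1e-9)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(denormalize_patch(np$patch, np$norm), p, tolerance = 1e-9)
    expect_true(min(np$patch) >= 0 && max(np$patch) <= 1)
  }
})

test_that("ON/OFF ternary code uses tertile thresholds and is monotone", {
  p <- matrix(c(0.1, 0.5, 0.9), 1, 3)
  expect_equal(as.vector(onoff_encode(p)), c(-1L, 0L, 1L))
  expect_true(all(onoff_encode(matrix(0, 2, 2)) == -1L))
  expect_equal(onoff_encode(matrix(1 / 3, 1, 1))[1, 1], 0L)  # half-open lower
  expect_equal(onoff_encode(matrix(2 / 3, 1, 1))[1, 1], 1L)

  set.seed(11)
  x <- sort(runif(50))
  codes <- as.vector(onoff_encode(matrix(x, 1, 50)))
  expect_true(all(diff(codes) >= 0))
})

test_that("ON/OFF training vectors are bipolar, one per patch", {
  set.seed(3)
  img <- matrix(runif(220 * 200), 220, 200)
  v <- onoff_training_vectors(img)
  expect_equal(dim(v), c(440, 32))
  expect_true(all(v == 1 | v == -1))
  expect_error(onoff_training_vectors(img, 220, 200, 32), "pixels")
})
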